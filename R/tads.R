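#' Resolve the TAD hierarchy
#'
#' TAD callers that report two hierarchy levels sometimes emit the same
#' interval as both a primary (level-1) and a secondary (level-2) TAD; an
#' exact duplicate across levels collapses to a single level-1 record. A
#' TAD strictly nested within another keeps level 2; non-nested TADs are
#' level 1.
#'
#' @param tads data.frame: chrom, start, end, level (1 or 2).
#' @return resolved data.frame with the same columns, deduplicated.
#' @export
resolve_tad_hierarchy <- function(tads) {
  if (!nrow(tads)) return(tads[, c("chrom", "start", "end", "level")])
  key <- paste(tads$chrom, tads$start, tads$end, sep = "\r")
  lvl <- tapply(tads$level, key, min)   # duplicate across levels -> primary
  parts <- strsplit(names(lvl), "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1),
                    start = as.numeric(vapply(parts, `[`, "", 2)),
                    end = as.numeric(vapply(parts, `[`, "", 3)),
                    level = as.integer(lvl), stringsAsFactors = FALSE)
  # re-derive nesting: contained in a larger interval -> secondary
  gr <- .to_grl(out[, c("chrom", "start", "end")])
  within <- GenomicRanges::countOverlaps(gr, gr, type = "within") > 1
  out$level <- ifelse(within, 2L, 1L)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract TAD boundaries
#'
#' Both the leftmost and rightmost points of every primary and secondary
#' TAD count as boundaries; positions shared between adjacent or nested
#' TADs are reported once per chromosome.
#'
#' @param tads resolved TAD data.frame.
#' @return data.frame: chrom, pos (sorted, unique per chromosome), with a
#'   `levels` attribute-free provenance column listing contributing levels.
#' @export
extract_tad_boundaries <- function(tads) {
  if (!nrow(tads)) {
    return(data.frame(chrom = character(), pos = numeric(),
                      stringsAsFactors = FALSE))
  }
  pts <- data.frame(chrom = rep(tads$chrom, 2),
                    pos = c(tads$start, tads$end),
                    level = rep(tads$level, 2), stringsAsFactors = FALSE)
  key <- paste(pts$chrom, pts$pos, sep = "\r")
  lv <- tapply(pts$level, key, function(l) paste(sort(unique(l)), collapse = ","))
  parts <- strsplit(names(lv), "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1),
                    pos = as.numeric(vapply(parts, `[`, "", 2)),
                    levels = as.character(lv), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count boundaries per hierarchy level
#'
#' Two tallies are reported because "boundary count per level" is
#' ambiguous: `unique_positions` counts distinct boundary positions to
#' which a level contributes; `endpoints` counts raw TAD endpoints
#' (2 per TAD) at that level.
#'
#' @param tads resolved TAD data.frame.
#' @export
tad_boundary_counts <- function(tads) {
  out <- lapply(c(1L, 2L), function(l) {
    sub <- tads[tads$level == l, , drop = FALSE]
    b <- extract_tad_boundaries(sub)
    data.frame(level = l, n_tads = nrow(sub), unique_positions = nrow(b),
               endpoints = 2L * nrow(sub))
  })
  do.call(rbind, out)
}

#' Insulation-score boundary caller
#'
#' A deliberately simple domain-boundary caller used to exercise the
#' pipeline on synthetic matrices: the insulation score of bin i is the
#' mean contact count in the `window_bins` x `window_bins` square
#' straddling i (upstream rows x downstream columns); boundaries are
#' local minima of the log2 mean-normalised score whose prominence
#' (lowest flanking maximum minus the minimum, within `window_bins`)
#' exceeds `delta_threshold`.
#'
#' @param mat a `contact_matrix` (raw counts).
#' @param window_bins half-window in bins (default 5).
#' @param delta_threshold minimum normalised prominence (default 0.2).
#' @return data.frame: chrom, pos (bp of the bin edge at the minimum),
#'   bin, score, prominence.
#' @export
insulation_boundaries <- function(mat, window_bins = 5, delta_threshold = 0.2) {
  stopifnot(inherits(mat, "contact_matrix"))
  m <- mat$counts
  n <- nrow(m)
  w <- as.integer(window_bins)
  ins <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w - 1 > n) next
    ins[i] <- mean(m[(i - w):(i - 1), i:(i + w - 1)])
  }
  ok <- is.finite(ins) & ins > 0
  if (!any(ok)) {
    return(data.frame(chrom = character(), pos = numeric(), bin = integer(),
                      score = numeric(), prominence = numeric(),
                      stringsAsFactors = FALSE))
  }
  z <- log2(ins / mean(ins[ok]))
  res <- list()
  for (i in which(ok)) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    neigh <- c(z[lo], z[hi])
    neigh <- neigh[is.finite(neigh)]
    if (length(neigh) && any(z[i] > neigh)) next     # not a local minimum
    if (is.finite(z[max(1, i - 1)]) && z[max(1, i - 1)] == z[i] && i > 1) next # plateau: keep leftmost
    left <- z[max(1, i - w):i]; right <- z[i:min(n, i + w)]
    prom <- min(max(left, na.rm = TRUE), max(right, na.rm = TRUE)) - z[i]
    if (is.finite(prom) && prom >= delta_threshold) {
      res[[length(res) + 1]] <- data.frame(
        chrom = mat$chrom, pos = (i - 1) * mat$bin_size, bin = i - 1L,
        score = z[i], prominence = prom, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(chrom = character(), pos = numeric(), bin = integer(),
                      score = numeric(), prominence = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(res, make.row.names = FALSE))
}

#' Read / write TAD tables (TSV: chrom, start, end, level)
#' @param path file path
#' @export
read_tads <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_tads
#' @param tads TAD data.frame
#' @export
write_tads <- function(tads, path) {
  utils::write.table(tads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
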