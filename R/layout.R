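#' Genome layout: the coordinate frame for the whole pipeline
#'
#' Holds chromosome names and lengths, hardmasked intervals (excluded from
#' null models and statistics) and the set of excluded chromosomes (sex
#' chromosomes in the stickleback analyses: chrIX, chrXIX, chrY).
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp), in
#'   assembly order.
#' @param masked optional interval data.frame of hardmasked regions.
#' @param excluded_chromosomes character vector of chromosome names dropped
#'   from all statistics and null models.
#' @return an object of class `genome_layout`.
#' @export
genome_layout <- function(chromosomes, masked = NULL,
                          excluded_chromosomes = character()) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(chromosomes$name)) stop("duplicated chromosome names")
  if (is.null(masked)) masked <- empty_intervals()
  validate_intervals(masked)
  if (nrow(masked)) {
    idx <- match(masked$chrom, chromosomes$name)
    if (anyNA(idx)) stop("masked interval on unknown chromosome")
    if (any(masked$end > chromosomes$length[idx])) {
      stop("masked interval extends beyond its chromosome")
    }
  }
  excluded_chromosomes <- as.character(excluded_chromosomes)
  if (!all(excluded_chromosomes %in% chromosomes$name)) {
    stop("excluded_chromosomes must be a subset of chromosome names")
  }
  structure(list(chromosomes = chromosomes,
                 masked = interval_union(masked),
                 excluded_chromosomes = excluded_chromosomes),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$chromosomes), "chromosomes,",
      format(sum(x$chromosomes$length), big.mark = ","), "bp;",
      nrow(x$masked), "masked intervals;",
      length(x$excluded_chromosomes), "excluded chromosomes\n")
  invisible(x)
}

chrom_lengths <- function(layout) {
  stats::setNames(layout$chromosomes$length, layout$chromosomes$name)
}

#' Names of chromosomes entering the analysis
#' @param layout a genome_layout
#' @export
active_chromosomes <- function(layout) {
  setdiff(layout$chromosomes$name, layout$excluded_chromosomes)
}

#' Full extent of the non-excluded chromosomes as intervals
#' @param layout a genome_layout
#' @export
genome_intervals <- function(layout) {
  keep <- layout$chromosomes$name %in% active_chromosomes(layout)
  ch <- layout$chromosomes[keep, , drop = FALSE]
  if (!nrow(ch)) return(empty_intervals())
  intervals(ch$name, 0, ch$length)
}

#' The allowed set for null models: non-excluded genome minus masks
#' @param layout a genome_layout
#' @param use_mask drop masked intervals (default TRUE)?
#' @export
allowed_intervals <- function(layout, use_mask = TRUE) {
  g <- genome_intervals(layout)
  if (use_mask && nrow(layout$masked)) g <- interval_setdiff(g, layout$masked)
  g
}

#' Remove masked regions from an interval set
#' @param x interval data.frame
#' @param layout a genome_layout
#' @export
subtract_masks <- function(x, layout) {
  interval_setdiff(x, layout$masked)
}

#' Tile the non-excluded chromosomes with fixed-size windows
#'
#' The last window on each chromosome is truncated at the chromosome end,
#' never dropped: downstream minimum-site thresholds already guard short
#' windows.
#'
#' @param layout a genome_layout
#' @param size window size in bp (the analyses use 25,000)
#' @return interval data.frame of windows
#' @export
make_windows <- function(layout, size = 25000) {
  stopifnot(size > 0)
  keep <- layout$chromosomes$name %in% active_chromosomes(layout)
  ch <- layout$chromosomes[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(ch)), function(i) {
    starts <- seq(0, ch$length[i] - 1, by = size)
    data.frame(chrom = ch$name[i], start = starts,
               end = pmin(starts + size, ch$length[i]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) empty_intervals() else res
}
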