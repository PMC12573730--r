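#' Parse a structural-variant VCF from whole-genome alignment
#'
#' Reads the SV dialect produced by whole-genome aligners/SV callers where
#' the ID column classifies records: IDs of the form `INV<number>` are
#' inversions, `SYNAL<number>` are colinear (syntenic) alignment blocks.
#' All other records are ignored. Reference-genome coordinates come from
#' POS and INFO/END; query-genome coordinates, when present, from the
#' INFO keys ChrB/StartB/EndB.
#'
#' @param path path to the VCF file.
#' @param min_length keep inversions with reference span >= `min_length` bp.
#' @param layout optional `genome_layout`; records on its excluded
#'   chromosomes are dropped.
#' @return list with elements `inversions` (data.frame: id, chrom, start,
#'   end, qry_chrom, qry_start, qry_end, length; 0-based half-open),
#'   `colinear` (interval data.frame) and `n_rejected` (INV records with
#'   END <= POS, dropped with a warning).
#' @export
parse_sv_vcf <- function(path, min_length = 0, layout = NULL) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body_idx) {
    if (length(strsplit(lines[i], "\t", fixed = TRUE)[[1]]) < 8) {
      stop("malformed VCF line ", i, " in ", path, call. = FALSE)
    }
  }
  empty <- list(inversions = .empty_inversions(), colinear = empty_intervals(),
                n_rejected = 0L)
  if (!length(body_idx)) return(empty)

  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info_end <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "END")))
  qry_chrom <- vcfR::extract.info(vcf, "ChrB")
  qry_start <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "StartB")))
  qry_end <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "EndB")))

  id <- fix[, "ID"]
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  keep_chrom <- if (is.null(layout)) rep(TRUE, length(id)) else
    chrom %in% active_chromosomes(layout)

  is_inv <- grepl("^INV[0-9]+$", id) & keep_chrom
  is_syn <- grepl("^SYNAL[0-9]+$", id) & keep_chrom

  bad <- is_inv & (is.na(info_end) | info_end <= pos)
  n_rejected <- sum(bad)
  if (n_rejected) {
    warning(n_rejected, " INV record(s) with END <= POS rejected", call. = FALSE)
  }
  is_inv <- is_inv & !bad

  inv <- .empty_inversions()
  if (any(is_inv)) {
    inv <- data.frame(id = id[is_inv], chrom = chrom[is_inv],
                      start = pos[is_inv] - 1, end = info_end[is_inv],
                      qry_chrom = if (all(is.na(qry_chrom[is_inv]))) chrom[is_inv]
                                  else qry_chrom[is_inv],
                      qry_start = ifelse(is.na(qry_start[is_inv]),
                                         pos[is_inv] - 1, qry_start[is_inv] - 1),
                      qry_end = ifelse(is.na(qry_end[is_inv]),
                                       info_end[is_inv], qry_end[is_inv]),
                      stringsAsFactors = FALSE)
    inv$length <- inv$end - inv$start
    inv <- inv[inv$length >= min_length, , drop = FALSE]
    rownames(inv) <- NULL
  }

  syn <- empty_intervals()
  syn_ok <- is_syn & !is.na(info_end) & info_end > pos
  if (any(syn_ok)) {
    syn <- intervals(chrom[syn_ok], pos[syn_ok] - 1, info_end[syn_ok])
  }
  list(inversions = inv, colinear = syn, n_rejected = n_rejected)
}

.empty_inversions <- function() {
  data.frame(id = character(), chrom = character(), start = numeric(),
             end = numeric(), qry_chrom = character(), qry_start = numeric(),
             qry_end = numeric(), length = numeric(), stringsAsFactors = FALSE)
}

#' Restrict to large inversions
#'
#' The headline analyses use inversions larger than the TAD bin size
#' (25 kbp). "Larger than" is read strictly (`length > min_bp`); set
#' `strict = FALSE` to include ties at exactly `min_bp`.
#'
#' @param inversions inversion data.frame from [parse_sv_vcf()].
#' @param min_bp size threshold in bp.
#' @param strict if TRUE keep length > min_bp, else length >= min_bp.
#' @export
filter_inversions <- function(inversions, min_bp = 25000, strict = TRUE) {
  keep <- if (strict) inversions$length > min_bp else inversions$length >= min_bp
  inversions[keep, , drop = FALSE]
}

#' Partition the genome into inverted / colinear / unassigned
#'
#' Inverted bases win over colinear: any base covered by an inversion is
#' classified inverted even if a syntenic block also covers it (breakpoints
#' stay per-event, classification is per-base). Bases covered by neither
#' class are unassigned and contribute to no windowed statistic.
#'
#' @param inversions inversion data.frame (reference-frame intervals used).
#' @param colinear interval data.frame of syntenic alignment blocks.
#' @param layout a `genome_layout`; the partition is clipped to its
#'   non-excluded chromosomes.
#' @return object of class `region_partition` with interval sets
#'   `inverted`, `colinear`, `unassigned`.
#' @export
region_partition <- function(inversions, colinear, layout) {
  genome <- genome_intervals(layout)
  inv_iv <- if (nrow(inversions))
    intervals(inversions$chrom, inversions$start, inversions$end)
  else empty_intervals()
  inverted <- interval_intersect(interval_union(inv_iv), genome)
  col <- interval_setdiff(interval_intersect(interval_union(colinear), genome),
                          inverted)
  unassigned <- interval_setdiff(interval_setdiff(genome, inverted), col)
  structure(list(inverted = inverted, colinear = col, unassigned = unassigned),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("region_partition: inverted", format(interval_width(x$inverted), big.mark = ","),
      "bp; colinear", format(interval_width(x$colinear), big.mark = ","),
      "bp; unassigned", format(interval_width(x$unassigned), big.mark = ","), "bp\n")
  invisible(x)
}

#' Classify windows by region
#'
#' A window wholly inside one class yields one row; a window containing
#' both inverted and colinear bases yields one row per class present, each
#' carrying the bp actually covered by that class (`effective_span`), so
#' that FST and dxy can be computed separately for the two region classes
#' within the same window. Bases in neither class yield nothing.
#'
#' @param windows interval data.frame from [make_windows()].
#' @param partition a `region_partition`.
#' @return data.frame: chrom, start, end, region_class, effective_span.
#' @export
classify_windows <- function(windows, partition) {
  validate_intervals(windows)
  out <- lapply(c("inverted", "colinear"), function(cls) {
    set <- partition[[cls]]
    if (!nrow(set) || !nrow(windows)) return(NULL)
    h <- .harmonize(.to_grl(windows), .to_grl(set))
    wgr <- h[[1]]; sgr <- h[[2]]
    hits <- GenomicRanges::findOverlaps(wgr, sgr)
    if (!length(hits)) return(NULL)
    qi <- S4Vectors::queryHits(hits)
    ov <- GenomicRanges::pintersect(wgr[qi], sgr[S4Vectors::subjectHits(hits)])
    span <- tapply(GenomicRanges::width(ov), qi, sum)
    widx <- as.integer(names(span))
    data.frame(chrom = windows$chrom[widx], start = windows$start[widx],
               end = windows$end[widx], region_class = cls,
               effective_span = as.numeric(span), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      region_class = character(), effective_span = numeric(),
                      stringsAsFactors = FALSE)
  }
  res <- res[order(res$chrom, res$start, res$region_class), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Inversion breakpoints in a chosen coordinate frame
#'
#' Each inversion contributes two breakpoints: the start and end of its
#' interval in the reference (`ref`) or query (`qry`) assembly frame.
#'
#' @param inversions inversion data.frame.
#' @param frame `"ref"` or `"qry"`.
#' @return data.frame: chrom, pos, inversion_id, side ("start"/"end").
#' @export
breakpoints_of <- function(inversions, frame = c("ref", "qry")) {
  frame <- match.arg(frame)
  if (!nrow(inversions)) {
    return(data.frame(chrom = character(), pos = numeric(),
                      inversion_id = character(), side = character(),
                      stringsAsFactors = FALSE))
  }
  if (frame == "ref") {
    ch <- inversions$chrom; s <- inversions$start; e <- inversions$end
  } else {
    ch <- inversions$qry_chrom; s <- inversions$qry_start; e <- inversions$qry_end
  }
  data.frame(chrom = rep(ch, 2), pos = c(s, e),
             inversion_id = rep(inversions$id, 2),
             side = rep(c("start", "end"), each = nrow(inversions)),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED (0-based half-open), optional name column
#' @param x interval data.frame; a `name` column is written when present.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end", intersect("name", names(x)))
  utils::write.table(x[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (first three or four columns)
#' @param path BED path.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  x[, seq_len(min(4, ncol(x))), drop = FALSE]
}
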