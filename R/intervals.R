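#' Build an interval table
#'
#' Intervals are the package's universal coordinate currency: a data.frame
#' with columns `chrom`, `start`, `end` in 0-based half-open coordinates
#' (`start <= pos < end`). VCF (1-based) and BED (0-based) inputs are
#' converted at the I/O boundary so that all internal arithmetic uses a
#' single convention.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like vectors, 0-based half-open.
#' @return a data.frame with columns chrom, start, end.
#' @export
intervals <- function(chrom = character(), start = integer(), end = integer()) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) && any(x$start < 0 | x$end <= x$start)) {
    stop("invalid interval: need 0 <= start < end", call. = FALSE)
  }
  invisible(x)
}

empty_intervals <- function() intervals()

## IRanges does the set algebra; the +1/-0 shifts below are the single
## place where 0-based half-open meets 1-based closed.
.to_grl <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

# binary GRanges ops warn when the two sides carry disjoint chromosome
# sets; give both the union of seqlevels first
.harmonize <- function(x, y) {
  sl <- union(GenomeInfoDb::seqlevels(x), GenomeInfoDb::seqlevels(y))
  GenomeInfoDb::seqlevels(x) <- sl
  GenomeInfoDb::seqlevels(y) <- sl
  list(x, y)
}

# overlapsAny with harmonized seqlevels (for point-in-set queries)
overlaps_any_points <- function(query, subject) {
  h <- .harmonize(query, subject)
  IRanges::overlapsAny(h[[1]], h[[2]])
}

.from_gr <- function(gr) {
  if (length(gr) == 0L) return(empty_intervals())
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             stringsAsFactors = FALSE)
}

#' Union (merge overlapping/adjacent) intervals
#' @param x interval data.frame
#' @return merged interval data.frame, sorted by (chrom, start)
#' @export
interval_union <- function(x) {
  validate_intervals(x)
  if (!nrow(x)) return(empty_intervals())
  .from_gr(GenomicRanges::reduce(.to_grl(x)))
}

#' Intersection of two interval sets
#' @param x,y interval data.frames
#' @export
interval_intersect <- function(x, y) {
  validate_intervals(x); validate_intervals(y)
  if (!nrow(x) || !nrow(y)) return(empty_intervals())
  h <- .harmonize(.to_grl(x), .to_grl(y))
  .from_gr(GenomicRanges::intersect(h[[1]], h[[2]]))
}

#' Set difference x \ y of two interval sets
#' @param x,y interval data.frames
#' @export
interval_setdiff <- function(x, y) {
  validate_intervals(x); validate_intervals(y)
  if (!nrow(x)) return(empty_intervals())
  if (!nrow(y)) return(interval_union(x))
  h <- .harmonize(.to_grl(x), .to_grl(y))
  .from_gr(GenomicRanges::setdiff(h[[1]], h[[2]]))
}

#' Total length (bp) covered by an interval set
#'
#' Overlaps are collapsed before summing, so duplicated intervals do not
#' double-count.
#' @param x interval data.frame
#' @export
interval_width <- function(x) {
  u <- interval_union(x)
  if (!nrow(u)) return(0)
  sum(u$end - u$start)
}
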