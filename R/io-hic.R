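#' Write / read a contact matrix as sparse text
#'
#' The minimal interchange dialect: a 3-column table (bin_i, bin_j,
#' count; 0-based upper-triangle bins) plus a bins table (chrom, start,
#' end), convertible to standard cooler/hic tooling.
#'
#' @param mat a `contact_matrix`.
#' @param path output path for the sparse triples.
#' @param bins_path output path for the bins table.
#' @export
write_contact_matrix <- function(mat, path, bins_path) {
  stopifnot(inherits(mat, "contact_matrix"))
  m <- mat$counts
  ut <- which(upper.tri(m, diag = TRUE) & m > 0, arr.ind = TRUE)
  sp <- data.frame(bin_i = ut[, 1] - 1L, bin_j = ut[, 2] - 1L,
                   count = m[ut])
  utils::write.table(sp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  n <- nrow(m)
  bins <- data.frame(chrom = mat$chrom, start = (seq_len(n) - 1) * mat$bin_size,
                     end = seq_len(n) * mat$bin_size)
  utils::write.table(bins, bins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @param min_nonzero passed to [contact_matrix()].
#' @export
read_contact_matrix <- function(path, bins_path, min_nonzero = 10) {
  sp <- utils::read.table(path, header = TRUE, sep = "\t")
  bins <- utils::read.table(bins_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  n <- nrow(bins)
  m <- matrix(0, n, n)
  m[cbind(sp$bin_i + 1L, sp$bin_j + 1L)] <- sp$count
  m[cbind(sp$bin_j + 1L, sp$bin_i + 1L)] <- sp$count
  contact_matrix(m, bins$chrom[1], bins$end[1] - bins$start[1],
                 min_nonzero = min_nonzero)
}

#' Write / read a per-bin GC track as BEDGraph
#' @param gc data.frame: chrom, start, end, gc.
#' @param path file path.
#' @export
write_gc_bedgraph <- function(gc, path) {
  utils::write.table(gc[, c("chrom", "start", "end", "gc")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_gc_bedgraph
#' @export
read_gc_bedgraph <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x) <- c("chrom", "start", "end", "gc")
  x
}
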