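#' TPM normalisation
#'
#' TPM_g = (count_g / length_g in kb) / sum_h(count_h / length_h in kb) * 1e6
#' per sample; columns sum to one million by construction.
#'
#' @param counts matrix genes x samples of read counts.
#' @param lengths_bp per-gene lengths in bp (> 0).
#' @return matrix of TPM values.
#' @export
tpm <- function(counts, lengths_bp) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths_bp) == nrow(counts))
  if (any(lengths_bp <= 0)) stop("gene length must be > 0", call. = FALSE)
  rate <- counts / (lengths_bp / 1000)
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Assign genes to compartments
#'
#' A gene wholly inside A (or B) segments gets that label; genes
#' overlapping both compartments ("spanning" a boundary) are flagged and
#' excluded from the expression comparison, as are genes overlapping
#' neither.
#'
#' @param genes data.frame: gene_id, chrom, start, end (0-based half-open).
#' @param segments compartment segments (from [compartment_segments()]).
#' @return genes with a `compartment` column: "A", "B", "spanning" or NA.
#' @export
assign_genes_compartments <- function(genes, segments) {
  gr <- .to_grl(genes[, c("chrom", "start", "end")])
  comp <- rep(NA_character_, nrow(genes))
  hitA <- hitB <- rep(FALSE, nrow(genes))
  a <- segments[segments$label == "A", , drop = FALSE]
  b <- segments[segments$label == "B", , drop = FALSE]
  if (nrow(a)) hitA <- overlaps_any_points(gr, .to_grl(a))
  if (nrow(b)) hitB <- overlaps_any_points(gr, .to_grl(b))
  comp[hitA & !hitB] <- "A"
  comp[hitB & !hitA] <- "B"
  comp[hitA & hitB] <- "spanning"
  genes$compartment <- comp
  genes
}

#' Compare expression between A and B compartments
#'
#' TPM per sample, averaged over samples per gene; genes assigned to A or
#' B by containment (spanning genes removed); Brunner-Munzel test of
#' A-gene versus B-gene mean TPM (relative effect = probability that an
#' A gene out-expresses a B gene).
#'
#' @param genes data.frame: gene_id, chrom, start, end, length_bp.
#' @param counts matrix genes x samples (rows in `genes` order).
#' @param segments compartment segments.
#' @return list(genes = per-gene table with mean_tpm and compartment,
#'   test = `rank_test`, n_A, n_B, n_spanning).
#' @export
assign_and_compare_expression <- function(genes, counts, segments) {
  stopifnot(nrow(genes) == nrow(counts))
  tp <- tpm(counts, genes$length_bp)
  genes$mean_tpm <- rowMeans(tp)
  genes <- assign_genes_compartments(genes, segments)
  a <- genes$mean_tpm[!is.na(genes$compartment) & genes$compartment == "A"]
  b <- genes$mean_tpm[!is.na(genes$compartment) & genes$compartment == "B"]
  test <- if (length(a) >= 2 && length(b) >= 2) brunner_munzel(b, a) else NULL
  list(genes = genes, test = test, n_A = length(a), n_B = length(b),
       n_spanning = sum(genes$compartment == "spanning", na.rm = TRUE))
}
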