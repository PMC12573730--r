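#' Site-filter configuration
#'
#' Mirrors the variant-filtering regime of the study: site quality >= 30,
#' per-genotype depth >= 10 and genotype quality >= 30 (failing genotypes
#' are set missing at read time), per-group missingness <= 20%
#' ("max-missing 0.8"), a mean-depth cap of mean + 4*sqrt(mean) computed
#' from the data when not supplied, biallelic non-indel sites only. In
#' ABBA-BABA mode the outgroup must additionally be fully genotyped and
#' the minor allele count must be >= 1.
#'
#' @param min_site_q minimum site QUAL.
#' @param min_dp minimum per-genotype depth.
#' @param min_gq minimum per-genotype quality.
#' @param max_missing_fraction maximum fraction of missing genotypes per group.
#' @param max_mean_dp site mean-depth cap; NULL = mean + 4*sqrt(mean) of the data.
#' @param biallelic_only keep at most two alleles.
#' @param drop_indels drop indel records.
#' @param require_outgroup_complete ABBA mode: outgroup fully genotyped.
#' @param min_minor_allele_count ABBA mode: minimum minor allele count.
#' @export
filter_config <- function(min_site_q = 30, min_dp = 10, min_gq = 30,
                          max_missing_fraction = 0.2, max_mean_dp = NULL,
                          biallelic_only = TRUE, drop_indels = TRUE,
                          require_outgroup_complete = TRUE,
                          min_minor_allele_count = 1) {
  cfg <- list(min_site_q = min_site_q, min_dp = min_dp, min_gq = min_gq,
              max_missing_fraction = max_missing_fraction,
              max_mean_dp = max_mean_dp, biallelic_only = biallelic_only,
              drop_indels = drop_indels,
              require_outgroup_complete = require_outgroup_complete,
              min_minor_allele_count = min_minor_allele_count)
  stopifnot(all(vapply(cfg[c(1:4, 9)], function(v) is.numeric(v) && v >= 0,
                       logical(1))))
  structure(cfg, class = "filter_config")
}

.group_names <- c("P1", "P2", "P3", "OUT")

#' Build a site table from a genotype matrix
#'
#' Collapses per-individual diploid genotypes (0/1/2 = derived-allele dose,
#' NA = missing) into per-group genotyped allele counts `n_<g>`, derived
#' allele counts `c_<g>` and heterozygote counts `h_<g>` for groups
#' P1/P2/P3/OUT -- the substrate for FST, dxy and the D statistic.
#'
#' @param chrom,pos site coordinates (pos 0-based).
#' @param gt numeric matrix sites x samples with values 0, 1, 2 or NA.
#' @param groups named list mapping group name -> column indices (or names)
#'   of `gt`.
#' @param is_snp logical vector (default: derived allele seen somewhere).
#' @return data.frame site table.
#' @export
site_table <- function(chrom, pos, gt, groups, is_snp = NULL) {
  stopifnot(is.matrix(gt), all(.group_names %in% names(groups)))
  out <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                    stringsAsFactors = FALSE)
  for (g in .group_names) {
    m <- gt[, groups[[g]], drop = FALSE]
    ok <- !is.na(m)
    out[[paste0("n_", g)]] <- 2 * rowSums(ok)
    out[[paste0("c_", g)]] <- rowSums(m, na.rm = TRUE)
    out[[paste0("h_", g)]] <- rowSums(m == 1, na.rm = TRUE)
  }
  if (is.null(is_snp)) {
    tot_c <- rowSums(out[paste0("c_", .group_names)])
    tot_n <- rowSums(out[paste0("n_", .group_names)])
    is_snp <- tot_c > 0 & tot_c < tot_n
  }
  out$is_snp <- is_snp
  out
}

#' Read an all-sites genotype VCF into a site table
#'
#' Genotypes failing the per-genotype depth/quality thresholds of `config`
#' are set missing before counting (the usual variant-toolkit semantics);
#' site-level QC fields (QUAL, mean depth, allele number, indel flag) are
#' carried along for [apply_site_filters()].
#'
#' @param path VCF path (plain text or bgzipped).
#' @param groups named list mapping P1/P2/P3/OUT to sample names.
#' @param config a [filter_config()].
#' @return site table with QC columns.
#' @export
read_sites_vcf <- function(path, groups, config = filter_config()) {
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_chr <- vcfR::extract.gt(vcf, element = "GT")
  dose <- .gt_to_dose(gt_chr)
  fmt <- strsplit(vcf@gt[1, "FORMAT"], ":", fixed = TRUE)[[1]]
  if ("DP" %in% fmt) {
    dp <- suppressWarnings(apply(vcfR::extract.gt(vcf, element = "DP"), 2, as.numeric))
    dp <- matrix(dp, nrow = nrow(dose))
    dose[!is.na(dp) & dp < config$min_dp] <- NA
    mean_dp <- rowMeans(dp, na.rm = TRUE)
  } else mean_dp <- rep(NA_real_, nrow(dose))
  if ("GQ" %in% fmt) {
    gq <- suppressWarnings(apply(vcfR::extract.gt(vcf, element = "GQ"), 2, as.numeric))
    gq <- matrix(gq, nrow = nrow(dose))
    dose[!is.na(gq) & gq < config$min_gq] <- NA
  }
  idx <- lapply(groups, function(s) match(s, colnames(gt_chr)))
  st <- site_table(fix[, "CHROM"], as.numeric(fix[, "POS"]) - 1, dose, idx)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  alt[is.na(alt)] <- ""
  n_alt <- ifelse(alt == "" | alt == ".", 0L,
                  lengths(strsplit(alt, ",", fixed = TRUE)))
  st$qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  st$mean_dp <- mean_dp
  st$n_alleles <- 1L + n_alt
  alt1 <- sub(",.*", "", alt)
  st$is_indel <- nchar(ref) != 1L | (n_alt > 0 & nchar(alt1) != 1L)
  st
}

.gt_to_dose <- function(gt_chr) {
  d <- matrix(NA_real_, nrow(gt_chr), ncol(gt_chr),
              dimnames = dimnames(gt_chr))
  d[gt_chr %in% c("0/0", "0|0")] <- 0
  d[gt_chr %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  d[gt_chr %in% c("1/1", "1|1")] <- 2
  d
}

#' Apply site-level filters
#'
#' `fst_dxy` mode keeps biallelic non-indel sites (variant and invariant)
#' passing site quality, mean-depth cap and per-group missingness;
#' `abba` mode additionally requires a fully genotyped outgroup and a
#' minor allele count >= `min_minor_allele_count` over all genotyped
#' alleles. Excluded chromosomes are removed in both modes when a layout
#' is given.
#'
#' @param sites site table (sorted by chrom, pos).
#' @param config a [filter_config()].
#' @param mode `"fst_dxy"` or `"abba"`.
#' @param layout optional `genome_layout` supplying excluded chromosomes.
#' @return filtered site table.
#' @export
apply_site_filters <- function(sites, config = filter_config(),
                               mode = c("fst_dxy", "abba"), layout = NULL) {
  mode <- match.arg(mode)
  o <- order(sites$chrom, sites$pos)
  if (is.unsorted(o)) stop("site table must be sorted by (chrom, pos)", call. = FALSE)
  keep <- rep(TRUE, nrow(sites))
  if (!is.null(layout)) keep <- keep & sites$chrom %in% active_chromosomes(layout)
  if (!is.null(sites$qual)) {
    keep <- keep & (is.na(sites$qual) | sites$qual >= config$min_site_q)
  }
  if (!is.null(sites$mean_dp) && any(!is.na(sites$mean_dp))) {
    cap <- config$max_mean_dp
    if (is.null(cap)) {
      m <- mean(sites$mean_dp, na.rm = TRUE)
      cap <- m + 4 * sqrt(m)
    }
    keep <- keep & (is.na(sites$mean_dp) | sites$mean_dp <= cap)
  }
  if (config$drop_indels && !is.null(sites$is_indel)) keep <- keep & !sites$is_indel
  if (config$biallelic_only && !is.null(sites$n_alleles)) {
    keep <- keep & sites$n_alleles <= 2
  }
  # per-group missingness against the fullest genotyping seen for the group
  for (g in .group_names) {
    n <- sites[[paste0("n_", g)]]
    full <- max(n, 0)
    if (full > 0) keep <- keep & (1 - n / full) <= config$max_missing_fraction
  }
  if (mode == "abba") {
    if (config$require_outgroup_complete) {
      keep <- keep & sites$n_OUT == max(sites$n_OUT, 0)
    }
    tot_c <- rowSums(sites[paste0("c_", .group_names)])
    tot_n <- rowSums(sites[paste0("n_", .group_names)])
    mac <- pmin(tot_c, tot_n - tot_c)
    keep <- keep & mac >= config$min_minor_allele_count
  }
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate sites with their region class
#'
#' @param sites site table.
#' @param partition a `region_partition`.
#' @return site table with a `region_class` column ("inverted",
#'   "colinear" or NA for unassigned bases).
#' @export
annotate_sites_region <- function(sites, partition) {
  cls <- rep(NA_character_, nrow(sites))
  if (nrow(sites)) {
    pts <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
    for (k in c("inverted", "colinear")) {
      set <- partition[[k]]
      if (!nrow(set)) next
      hit <- overlaps_any_points(pts, .to_grl(set))
      cls[hit & is.na(cls)] <- k
    }
  }
  sites$region_class <- cls
  sites
}
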