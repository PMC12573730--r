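# Shared in-code fixtures.

empty_inv_df <- function() {
  data.frame(id = character(), chrom = character(), start = numeric(),
             end = numeric(), qry_chrom = character(), qry_start = numeric(),
             qry_end = numeric(), length = numeric(), stringsAsFactors = FALSE)
}

two_chrom_layout <- function(len = 1e6) {
  genome_layout(data.frame(name = c("chr1", "chr2"), length = c(len, len)))
}

# a minimal SV VCF in the aligner dialect
write_fixture_sv_vcf <- function(path, records) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, records), path)
  path
}

# site table built directly from explicit per-group counts; each argument
# is a vector over sites (n = genotyped alleles, c = derived count,
# h = heterozygote count).
counts_site_table <- function(chrom = "chr1", pos = NULL, n = 20, c2, c3,
                              h2 = NULL, h3 = NULL, c1 = NULL, c4 = NULL,
                              is_snp = NULL) {
  m <- length(c2)
  if (is.null(pos)) pos <- seq_len(m) * 10
  rep_n <- function(x) if (length(x) == 1) rep(x, m) else x
  # default het counts: minimum consistent with the allele count
  defh <- function(cc, nn) pmin(cc, nn - cc) %% 2 + 0 * cc
  n <- rep_n(n)
  c1 <- if (is.null(c1)) rep(0, m) else rep_n(c1)
  c4 <- if (is.null(c4)) rep(0, m) else rep_n(c4)
  h2 <- if (is.null(h2)) defh(c2, n) else rep_n(h2)
  h3 <- if (is.null(h3)) defh(c3, n) else rep_n(h3)
  if (is.null(is_snp)) is_snp <- (c1 + c2 + c3 + c4) > 0
  data.frame(chrom = chrom, pos = pos,
             n_P1 = n, c_P1 = c1, h_P1 = defh(c1, n),
             n_P2 = n, c_P2 = c2, h_P2 = h2,
             n_P3 = n, c_P3 = c3, h_P3 = h3,
             n_OUT = 2, c_OUT = c4, h_OUT = 0,
             is_snp = is_snp, stringsAsFactors = FALSE)
}

# random small site table via genotype draws (gives consistent h counts)
random_site_table <- function(n_sites = 40, n_ind = 8, seed = 1) {
  set.seed(seed)
  groups <- list(P1 = 1:n_ind, P2 = n_ind + 1:n_ind,
                 P3 = 2 * n_ind + 1:n_ind, OUT = 3 * n_ind + 1)
  p <- matrix(stats::runif(n_sites * 4, 0.05, 0.95), n_sites, 4)
  gt <- matrix(NA_real_, n_sites, 3 * n_ind + 1)
  for (g in 1:3) {
    for (j in groups[[g]]) {
      gt[, j] <- stats::rbinom(n_sites, 1, p[, g]) + stats::rbinom(n_sites, 1, p[, g])
    }
  }
  gt[, 3 * n_ind + 1] <- stats::rbinom(n_sites, 1, p[, 4]) + stats::rbinom(n_sites, 1, p[, 4])
  site_table("chr1", seq_len(n_sites) * 7, gt, groups)
}
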