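#' Weir-Cockerham (1984) variance components for biallelic SNPs
#'
#' Computes the two-population components a (among populations),
#' b (among individuals within populations) and c (within individuals)
#' for each site, from per-group genotyped allele counts, derived allele
#' counts and heterozygote counts. Sites monomorphic across both groups
#' or with fewer than two genotyped individuals in either group yield NA
#' components and are skipped by the window estimator.
#'
#' @param sites site table (needs n_/c_/h_ columns for `pop1` and `pop2`).
#' @param pop1,pop2 group names (default P2 vs P3, the sympatric pair).
#' @return data.frame with columns a, b, c (one row per site).
#' @export
wc_components <- function(sites, pop1 = "P2", pop2 = "P3") {
  n1 <- sites[[paste0("n_", pop1)]] / 2   # individuals
  n2 <- sites[[paste0("n_", pop2)]] / 2
  p1 <- sites[[paste0("c_", pop1)]] / sites[[paste0("n_", pop1)]]
  p2 <- sites[[paste0("c_", pop2)]] / sites[[paste0("n_", pop2)]]
  h1 <- sites[[paste0("h_", pop1)]] / n1  # observed het proportion
  h2 <- sites[[paste0("h_", pop2)]] / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  bad <- !is.finite(pbar) | pbar <= 0 | pbar >= 1 | n1 < 2 | n2 < 2
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  data.frame(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham FST (ratio of sums)
#'
#' @param sites site table restricted to one window-class cell (SNPs only
#'   are used; invariant sites contribute nothing).
#' @param pop1,pop2 group names.
#' @param min_snps minimum usable SNPs for a defined value (default 25).
#' @return list(fst, n_snps); fst is NA when undefined.
#' @export
wc_fst_window <- function(sites, pop1 = "P2", pop2 = "P3", min_snps = 25) {
  comp <- wc_components(sites[sites$is_snp, , drop = FALSE], pop1, pop2)
  ok <- stats::complete.cases(comp)
  n_snps <- sum(ok)
  den <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  fst <- if (n_snps >= min_snps && den > 0) sum(comp$a[ok]) / den else NA_real_
  list(fst = fst, n_snps = n_snps)
}

#' Windowed dxy (average pairwise divergence, all-sites denominator)
#'
#' Numerator: per site, the number of between-group allele pairs that
#' differ, c1*(n2-c2) + (n1-c1)*c2; denominator: n1*n2 summed over the
#' same genotyped sites. Invariant sites contribute 0 to the numerator
#' but their full n1*n2 to the denominator, which is why an all-sites
#' input is required.
#'
#' @param sites site table restricted to one window-class cell.
#' @param pop1,pop2 group names.
#' @param min_sites minimum genotyped sites for a defined value (2500).
#' @return list(dxy, n_sites); dxy is NA when undefined.
#' @export
dxy_window <- function(sites, pop1 = "P2", pop2 = "P3", min_sites = 2500) {
  n1 <- sites[[paste0("n_", pop1)]]; c1 <- sites[[paste0("c_", pop1)]]
  n2 <- sites[[paste0("n_", pop2)]]; c2 <- sites[[paste0("c_", pop2)]]
  ok <- n1 > 0 & n2 > 0
  n_sites <- sum(ok)
  num <- sum(c1[ok] * (n2[ok] - c2[ok]) + (n1[ok] - c1[ok]) * c2[ok])
  den <- sum(n1[ok] * n2[ok])
  dxy <- if (n_sites >= min_sites && den > 0) num / den else NA_real_
  list(dxy = dxy, n_sites = n_sites)
}

#' Windowed FST and dxy over classified windows
#'
#' Sites are assigned to fixed windows by position and to a region class
#' by the partition; a window containing both classes is evaluated once
#' per class over its class-restricted sites, with the minimum-SNP and
#' minimum-site thresholds applied to each cell separately.
#'
#' @param sites site table with `region_class` (see
#'   [annotate_sites_region()]), already filtered.
#' @param window_bp window size (25,000).
#' @param pop1,pop2 group names.
#' @param min_snps,min_sites definition thresholds (25 SNPs / 2500 sites).
#' @return data.frame: chrom, start, end, region_class, n_snps, n_sites,
#'   fst, dxy.
#' @export
window_stats <- function(sites, window_bp = 25000, pop1 = "P2", pop2 = "P3",
                         min_snps = 25, min_sites = 2500) {
  sites <- sites[!is.na(sites$region_class), , drop = FALSE]
  if (!nrow(sites)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      region_class = character(), n_snps = integer(),
                      n_sites = integer(), fst = numeric(), dxy = numeric(),
                      stringsAsFactors = FALSE))
  }
  win <- floor(sites$pos / window_bp)
  key <- paste(sites$chrom, win, sites$region_class, sep = "\r")
  n1 <- sites[[paste0("n_", pop1)]]; c1 <- sites[[paste0("c_", pop1)]]
  n2 <- sites[[paste0("n_", pop2)]]; c2 <- sites[[paste0("c_", pop2)]]
  comp <- wc_components(sites, pop1, pop2)
  snp_ok <- sites$is_snp & stats::complete.cases(comp)
  geno_ok <- n1 > 0 & n2 > 0
  m <- cbind(a = ifelse(snp_ok, comp$a, 0),
             abc = ifelse(snp_ok, comp$a + comp$b + comp$c, 0),
             n_snps = as.numeric(snp_ok),
             num = ifelse(geno_ok, c1 * (n2 - c2) + (n1 - c1) * c2, 0),
             den = ifelse(geno_ok, n1 * n2, 0),
             n_sites = as.numeric(geno_ok))
  agg <- rowsum(m, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1)
  wstart <- as.numeric(vapply(parts, `[`, "", 2)) * window_bp
  cls <- vapply(parts, `[`, "", 3)
  fst <- ifelse(agg[, "n_snps"] >= min_snps & agg[, "abc"] > 0,
                agg[, "a"] / agg[, "abc"], NA_real_)
  dxy <- ifelse(agg[, "n_sites"] >= min_sites & agg[, "den"] > 0,
                agg[, "num"] / agg[, "den"], NA_real_)
  out <- data.frame(chrom = chrom, start = wstart, end = wstart + window_bp,
                    region_class = cls, n_snps = as.integer(agg[, "n_snps"]),
                    n_sites = as.integer(agg[, "n_sites"]),
                    fst = as.numeric(fst), dxy = as.numeric(dxy),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$region_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ABBA-BABA D statistic with block-jackknife significance
#'
#' With per-site derived-allele frequencies p1..p4 for (P1, P2, P3,
#' outgroup), abba = (1-p1) p2 p3 (1-p4) and baba = p1 (1-p2) p3 (1-p4);
#' D = sum(abba - baba) / sum(abba + baba). The Z score and p-value come
#' from a weighted delete-one jackknife over contiguous SNP blocks.
#'
#' @param sites site table filtered in abba mode; if `region_class` is
#'   given, restricted to that class first.
#' @param region_class optional "inverted" or "colinear".
#' @param n_blocks jackknife blocks (default 20).
#' @return object of class `dstat_result`.
#' @export
d_statistic <- function(sites, region_class = NULL, n_blocks = 20) {
  if (!is.null(region_class)) {
    sites <- sites[!is.na(sites$region_class) &
                     sites$region_class == region_class, , drop = FALSE]
  }
  ok <- sites$n_P1 > 0 & sites$n_P2 > 0 & sites$n_P3 > 0 & sites$n_OUT > 0
  sites <- sites[ok, , drop = FALSE]
  p1 <- sites$c_P1 / sites$n_P1; p2 <- sites$c_P2 / sites$n_P2
  p3 <- sites$c_P3 / sites$n_P3; p4 <- sites$c_OUT / sites$n_OUT
  abba <- (1 - p1) * p2 * p3 * (1 - p4)
  baba <- p1 * (1 - p2) * p3 * (1 - p4)
  tot <- sum(abba + baba)
  if (nrow(sites) == 0L || tot == 0) {
    res <- list(D = NA_real_, Z = NA_real_, p = NA_real_,
                n_sites_used = nrow(sites), sum_abba = sum(abba),
                sum_baba = sum(baba), region_class = region_class,
                jackknife = NULL)
    class(res) <- "dstat_result"
    return(res)
  }
  blk <- contiguous_blocks(nrow(sites), n_blocks)
  num_b <- as.numeric(rowsum(abba - baba, blk))
  den_b <- as.numeric(rowsum(abba + baba, blk))
  jk <- block_jackknife(num_b, den_b)
  res <- list(D = jk$estimate, Z = jk$z, p = jk$p_two_sided,
              n_sites_used = nrow(sites), sum_abba = sum(abba),
              sum_baba = sum(baba), region_class = region_class,
              jackknife = jk)
  class(res) <- "dstat_result"
  res
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("ABBA-BABA%s: D = %.4g, Z = %.3g, p = %.4g (%d sites; ABBA %.4g, BABA %.4g)\n",
              if (is.null(x$region_class)) "" else paste0(" [", x$region_class, "]"),
              x$D, x$Z, x$p, x$n_sites_used, x$sum_abba, x$sum_baba))
  invisible(x)
}

#' Compare a windowed statistic between region classes
#'
#' Brunner-Munzel test of inverted-region window values against
#' colinear-region values (relative effect = probability that an inverted
#' window exceeds a colinear one), plus per-class means and medians.
#'
#' @param wstats output of [window_stats()].
#' @param metric `"fst"` or `"dxy"`.
#' @return list(test = `rank_test`, summary = per-class data.frame).
#' @export
compare_region_stats <- function(wstats, metric = c("fst", "dxy")) {
  metric <- match.arg(metric)
  vals <- split(wstats[[metric]], wstats$region_class)
  vals <- lapply(vals, function(v) v[!is.na(v)])
  for (cls in c("inverted", "colinear")) {
    if (length(vals[[cls]]) < 2) {
      stop("fewer than 2 defined ", metric, " windows in class '", cls, "'",
           call. = FALSE)
    }
  }
  test <- brunner_munzel(vals$colinear, vals$inverted)
  summary <- data.frame(
    region_class = c("inverted", "colinear"),
    n_windows = c(length(vals$inverted), length(vals$colinear)),
    mean = c(mean(vals$inverted), mean(vals$colinear)),
    median = c(stats::median(vals$inverted), stats::median(vals$colinear)),
    stringsAsFactors = FALSE)
  list(test = test, summary = summary, metric = metric)
}
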