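# Independent oracles: deliberately naive transcriptions and brute-force
# enumerations, kept free of any package internals they are used to check.

# Weir & Cockerham (1984) two-population theta, per-SNP loop over the
# printed component formulas; returns ratio of sums over usable SNPs.
oracle_wc_fst <- function(sites, pop1 = "P2", pop2 = "P3") {
  num <- 0; den <- 0
  for (i in seq_len(nrow(sites))) {
    if (!sites$is_snp[i]) next
    n1 <- sites[[paste0("n_", pop1)]][i] / 2
    n2 <- sites[[paste0("n_", pop2)]][i] / 2
    if (n1 < 2 || n2 < 2) next
    p1 <- sites[[paste0("c_", pop1)]][i] / (2 * n1)
    p2 <- sites[[paste0("c_", pop2)]][i] / (2 * n2)
    h1 <- sites[[paste0("h_", pop1)]][i] / n1
    h2 <- sites[[paste0("h_", pop2)]][i] / n2
    r <- 2
    nbar <- (n1 + n2) / 2
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    if (pbar <= 0 || pbar >= 1) next
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# dxy by brute force: loop over all between-group allele pairs per site.
oracle_dxy <- function(sites, pop1 = "P2", pop2 = "P3") {
  diff <- 0; pairs <- 0
  for (i in seq_len(nrow(sites))) {
    n1 <- sites[[paste0("n_", pop1)]][i]
    n2 <- sites[[paste0("n_", pop2)]][i]
    c1 <- sites[[paste0("c_", pop1)]][i]
    c2 <- sites[[paste0("c_", pop2)]][i]
    if (n1 == 0 || n2 == 0) next
    al1 <- c(rep(1, c1), rep(0, n1 - c1))
    al2 <- c(rep(1, c2), rep(0, n2 - c2))
    for (x in al1) for (y in al2) {
      pairs <- pairs + 1
      if (x != y) diff <- diff + 1
    }
  }
  diff / pairs
}

# Exhaustive permutation two-sided p for the two-sample relative effect:
# enumerate every split of the pooled sample into groups of the original
# sizes; statistic is |p_hat - 0.5| with p_hat from midranks.
oracle_relative_effect <- function(x, y) {
  r <- rank(c(x, y))
  ry <- r[length(x) + seq_along(y)]
  (mean(ry) - (length(y) + 1) / 2) / length(x)
}

oracle_bm_permutation_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  obs <- abs(oracle_relative_effect(x, y) - 0.5)
  splits <- utils::combn(length(pooled), nx)
  stat <- apply(splits, 2, function(ix) {
    abs(oracle_relative_effect(pooled[ix], pooled[-ix]) - 0.5)
  })
  mean(stat >= obs - 1e-12)
}

# Monte-Carlo estimate of the fraction of uniform points within `radius`
# of a boundary, with its binomial standard error.
oracle_mc_overlap <- function(boundaries, radius, allowed, n = 1e5) {
  w <- allowed$end - allowed$start
  cum <- cumsum(w)
  u <- stats::runif(n, 0, sum(w))
  i <- findInterval(u, cum, left.open = TRUE) + 1L
  chrom <- allowed$chrom[i]
  pos <- allowed$start[i] + (u - c(0, cum)[i])
  hit <- logical(n)
  for (ch in unique(chrom)) {
    b <- sort(boundaries$pos[boundaries$chrom == ch])
    j <- chrom == ch
    if (!length(b)) next
    k <- findInterval(pos[j], b)
    lo <- pmax(k, 1L); hi <- pmin(k + 1L, length(b))
    hit[j] <- pmin(abs(pos[j] - b[lo]), abs(pos[j] - b[hi])) <= radius
  }
  p <- mean(hit)
  list(p = p, se = sqrt(p * (1 - p) / n))
}

# Independent Balding-Nichols benchmark: fresh frequency and genotype
# draws (not via the package generator), WC theta via the oracle above.
oracle_bn_benchmark <- function(F, n_windows = 200, snps = 60, n_ind = 10) {
  vals <- vapply(seq_len(n_windows), function(w) {
    a <- stats::runif(snps, 0.05, 0.95)
    rbn <- function(a) if (F <= 0) a else
      stats::rbeta(length(a), a * (1 - F) / F, (1 - a) * (1 - F) / F)
    p1 <- rbn(a); p2 <- rbn(a)
    draw <- function(p) {
      a1 <- matrix(stats::rbinom(snps * n_ind, 1, p), snps, n_ind)
      a2 <- matrix(stats::rbinom(snps * n_ind, 1, p), snps, n_ind)
      list(c = rowSums(a1 + a2), h = rowSums(a1 != a2), n = rep(2 * n_ind, snps))
    }
    g1 <- draw(p1); g2 <- draw(p2)
    sites <- data.frame(n_P2 = g1$n, c_P2 = g1$c, h_P2 = g1$h,
                        n_P3 = g2$n, c_P3 = g2$c, h_P3 = g2$h,
                        is_snp = g1$c + g2$c > 0 & g1$c + g2$c < g1$n + g2$n)
    oracle_wc_fst(sites)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}
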