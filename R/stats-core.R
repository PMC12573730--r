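#' Brunner-Munzel rank test
#'
#' Nonparametric two-sample test of the relative effect
#' p = P(X < Y) + 0.5 P(X = Y), robust to unequal variances and ties.
#' Midranks are taken over the pooled sample; the test statistic is
#' W = n_x n_y (Rbar_y - Rbar_x) / ((n_x + n_y) * sqrt(n_x S2_x + n_y S2_y))
#' with the per-sample rank variances S2, and the two-sided p-value comes
#' from a t distribution with Satterthwaite degrees of freedom.
#'
#' Fully tied input (every pooled value identical) is a degenerate but
#' legitimate case on small runs and returns statistic 0, p = 1,
#' relative effect 0.5 rather than an error.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return object of class `rank_test` with fields statistic, df,
#'   p_two_sided, relative_effect, n_x, n_y.
#' @export
brunner_munzel <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  pooled <- c(x, y)
  r <- rank(pooled)            # midranks
  rx <- r[seq_len(nx)]; ry <- r[nx + seq_len(ny)]
  rbx <- mean(rx); rby <- mean(ry)
  rel <- (rby - (ny + 1) / 2) / nx
  # within-sample midranks
  rwx <- rank(x); rwy <- rank(y)
  s2x <- sum((rx - rwx - rbx + (nx + 1) / 2)^2) / (nx - 1)
  s2y <- sum((ry - rwy - rby + (ny + 1) / 2)^2) / (ny - 1)
  vsum <- nx * s2x + ny * s2y
  if (vsum <= 0) {
    # zero rank variance: all values tied (p = 1) or complete separation
    # (statistic diverges, p = 0); anything else is a genuine degeneracy
    res <- if (isTRUE(all.equal(rel, 0.5))) {
      list(statistic = 0, df = nx + ny - 2, p_two_sided = 1,
           relative_effect = 0.5, n_x = nx, n_y = ny)
    } else if (rel %in% c(0, 1)) {
      list(statistic = if (rel == 1) Inf else -Inf, df = nx + ny - 2,
           p_two_sided = 0, relative_effect = rel, n_x = nx, n_y = ny)
    } else {
      stop("zero pooled rank variance with unequal samples; ",
           "Brunner-Munzel statistic undefined", call. = FALSE)
    }
    class(res) <- "rank_test"
    return(res)
  }
  w <- nx * ny * (rby - rbx) / ((nx + ny) * sqrt(vsum))
  df <- vsum^2 / ((nx * s2x)^2 / (nx - 1) + (ny * s2y)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(w), df)
  res <- list(statistic = w, df = df, p_two_sided = p,
              relative_effect = rel, n_x = nx, n_y = ny)
  class(res) <- "rank_test"
  res
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Brunner-Munzel: W = %.4g, df = %.2f, p = %.4g, P(X<Y)+0.5P(X=Y) = %.4f\n",
              x$statistic, x$df, x$p_two_sided, x$relative_effect))
  invisible(x)
}

#' One-sample goodness-of-fit chi-square for a binomial proportion
#'
#' Tests observed count k out of n against expected probability p, df = 1.
#' Reports both the plain Pearson statistic and the Yates
#' continuity-corrected one; results with an expected cell count below 1
#' are flagged (but still computed).
#'
#' @param k observed count (0 <= k <= n).
#' @param n number of trials.
#' @param p expected probability (0 < p < 1).
#' @return object of class `gof_test`.
#' @export
chi_square_gof <- function(k, n, p) {
  stopifnot(n >= 1, k >= 0, k <= n, p > 0, p < 1)
  e1 <- n * p; e2 <- n * (1 - p)
  chi2_plain <- (k - e1)^2 / e1 + ((n - k) - e2)^2 / e2
  d <- max(abs(k - e1) - 0.5, 0)      # Yates: shrink deviation by 0.5
  chi2_yates <- d^2 / e1 + d^2 / e2
  res <- list(chi2_plain = chi2_plain, chi2_yates = chi2_yates, df = 1L,
              p_plain = stats::pchisq(chi2_plain, 1, lower.tail = FALSE),
              p_yates = stats::pchisq(chi2_yates, 1, lower.tail = FALSE),
              observed_k = k, n = n, expected_p = p,
              low_expected_count = (e1 < 1 || e2 < 1))
  class(res) <- "gof_test"
  res
}

#' @export
print.gof_test <- function(x, ...) {
  cat(sprintf("GOF chi-square: k = %d/%d vs p = %.4f; chi2 = %.4g (p = %.4g), Yates %.4g (p = %.4g)%s\n",
              x$observed_k, x$n, x$expected_p, x$chi2_plain, x$p_plain,
              x$chi2_yates, x$p_yates,
              if (x$low_expected_count) " [low expected count]" else ""))
  invisible(x)
}

#' Weighted delete-one block jackknife for a ratio of sums
#'
#' Estimates theta = sum(num) / sum(den) over genomic blocks and its
#' standard error by the delete-one jackknife for ratio estimators with
#' unequal block sizes (blocks weighted by their share of the denominator,
#' after Busing et al. 1999), the standard procedure for D-statistic
#' standard errors over linked sites. Z = theta / SE; two-sided normal p.
#'
#' If every leave-one-out estimate is identical the SE is zero and the
#' result is flagged degenerate with z = +/-Inf, p = 0.
#'
#' @param block_numerators,block_denominators numeric vectors, one entry
#'   per contiguous block (>= 2 blocks; denominators sum > 0).
#' @return object of class `jackknife_result` with estimate, se, z,
#'   p_two_sided, n_blocks, degenerate.
#' @export
block_jackknife <- function(block_numerators, block_denominators) {
  num <- as.numeric(block_numerators); den <- as.numeric(block_denominators)
  g <- length(num)
  stopifnot(g >= 2, length(den) == g, sum(den) > 0)
  tot_n <- sum(num); tot_d <- sum(den)
  if (any(tot_d - den <= 0)) {
    stop("leave-one-out denominator is zero; cannot jackknife", call. = FALSE)
  }
  theta <- tot_n / tot_d
  loo <- (tot_n - num) / (tot_d - den)
  m <- den                      # block weights: denominator share
  n <- tot_d
  h <- n / m
  theta_j <- g * theta - sum((1 - m / n) * loo)
  tau <- h * theta - (h - 1) * loo    # weighted pseudovalues
  var_j <- sum((tau - theta_j)^2 / (h - 1)) / g
  se <- sqrt(max(var_j, 0))
  degenerate <- se == 0
  z <- if (degenerate) {
    if (theta == 0) 0 else sign(theta) * Inf
  } else theta / se
  p <- if (degenerate) {
    if (theta == 0) 1 else 0
  } else 2 * stats::pnorm(-abs(z))
  res <- list(estimate = theta, se = se, z = z, p_two_sided = p,
              n_blocks = g, degenerate = degenerate)
  class(res) <- "jackknife_result"
  res
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("block jackknife (%d blocks): estimate = %.4g, SE = %.4g, Z = %.3g, p = %.4g%s\n",
              x$n_blocks, x$estimate, x$se, x$z, x$p_two_sided,
              if (x$degenerate) " [degenerate: zero jackknife variance]" else ""))
  invisible(x)
}

#' Permutation/Monte-Carlo p-value with the add-one estimator
#'
#' p = (1 + number of null draws at least as extreme) / (M + 1), which can
#' never return 0 and is exact for permutation nulls.
#'
#' @param observed observed statistic.
#' @param null_draws numeric vector of statistics under the null (M >= 1).
#' @param tail `"ge"` (upper) or `"le"` (lower).
#' @export
permutation_pvalue <- function(observed, null_draws, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  stopifnot(length(null_draws) >= 1)
  k <- if (tail == "ge") sum(null_draws >= observed) else sum(null_draws <= observed)
  (1 + k) / (length(null_draws) + 1)
}

#' Split sites into contiguous blocks of (near-)equal count
#'
#' Used to form jackknife blocks: `n` sites in order are cut into
#' `n_blocks` contiguous runs whose sizes differ by at most one.
#'
#' @param n number of sites.
#' @param n_blocks number of blocks (capped at n).
#' @return integer vector of block ids (1..n_blocks) of length n.
#' @export
contiguous_blocks <- function(n, n_blocks = 20) {
  n_blocks <- max(2L, min(as.integer(n_blocks), as.integer(n)))
  sort(rep_len(seq_len(n_blocks), n))
}
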