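#' Binned intra-chromosomal contact matrix
#'
#' @param counts symmetric non-negative square matrix of binned contacts.
#' @param chrom chromosome name.
#' @param bin_size bin size in bp.
#' @param bin_mask logical per-bin validity; NULL = mask bins with fewer
#'   than `min_nonzero` nonzero contacts (low-coverage bins distort
#'   balancing and correlation).
#' @param min_nonzero coverage threshold used when `bin_mask` is NULL.
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, chrom, bin_size, bin_mask = NULL,
                           min_nonzero = 10) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(counts))) {
    stop("contact matrix must be symmetric", call. = FALSE)
  }
  if (is.null(bin_mask)) bin_mask <- rowSums(counts > 0) >= min_nonzero
  structure(list(counts = counts, chrom = chrom, bin_size = bin_size,
                 bin_mask = bin_mask), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins of %s bp (%d masked), %.3g total counts\n",
              x$chrom, nrow(x$counts), format(x$bin_size, big.mark = ","),
              sum(!x$bin_mask), sum(x$counts)))
  invisible(x)
}

#' Knight-Ruiz matrix balancing
#'
#' Finds a positive diagonal scaling D such that all unmasked row (and,
#' by symmetry, column) sums of D M D are equal, using the Knight-Ruiz
#' inner-outer Newton iteration. Masked bins are excluded and returned
#' with NA scaling and NA rows/columns.
#'
#' @param mat a `contact_matrix`.
#' @param tol relative convergence tolerance on row sums (default 1e-6).
#' @param max_iter maximum outer iterations.
#' @return list(matrix = balanced `contact_matrix`, scaling = per-bin
#'   vector d, iterations).
#' @export
kr_balance <- function(mat, tol = 1e-6, max_iter = 1000) {
  stopifnot(inherits(mat, "contact_matrix"))
  keep <- mat$bin_mask
  a <- mat$counts[keep, keep, drop = FALSE]
  n <- nrow(a)
  if (n == 0L) stop("no unmasked bins to balance", call. = FALSE)
  if (any(rowSums(a) == 0)) {
    stop("unmasked bin with all-zero row; mask it before balancing",
         call. = FALSE)
  }
  x <- .kr_newton(a, tol, max_iter)
  b <- a * tcrossprod(x)
  # normalise so balanced row sums equal 1
  rs <- rowSums(b)
  resid <- max(abs(rs - mean(rs))) / mean(rs)
  if (resid > tol * 10) {
    stop(sprintf("KR balancing did not converge: residual %.3g", resid),
         call. = FALSE)
  }
  scale_all <- rep(NA_real_, length(keep))
  scale_all[keep] <- x / sqrt(mean(rs))
  out <- matrix(NA_real_, length(keep), length(keep))
  out[keep, keep] <- b / mean(rs)
  bal <- mat
  bal$counts <- out
  list(matrix = bal, scaling = scale_all, iterations = attr(x, "iterations"))
}

# Knight-Ruiz balancing: inexact Newton with conjugate-gradient inner
# solves, transcribed from the published bnewt pseudocode. `a` is the
# symmetric non-negative matrix restricted to bins with positive row sums;
# on success x satisfies x * (a %*% x) ~= 1 within tol (2-norm).
.kr_newton <- function(a, tol, max_iter) {
  n <- nrow(a)
  e <- rep(1, n)
  x <- e
  delta <- 0.1; Delta <- 3
  g <- 0.9; etamax <- 0.1
  eta <- etamax; stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.vector(a %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rho_km2 <- rho_km1
  rout <- rho_km1; rold <- rout
  it <- 0
  while (rout > rt && it < max_iter) {
    it <- it + 1
    k <- 0; y <- e
    innertol <- max(eta^2 * rout, rt)
    Z <- p <- NULL
    while (rho_km1 > innertol && k < 10 * n) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(a %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
    }
    x <- x * y
    v <- x * as.vector(a %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rho_km2 <- rho_km1
    rout <- rho_km1
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta; eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / max(res_norm, 1e-300))
  }
  if (rout > rt) {
    stop(sprintf("KR balancing did not converge in %d iterations: residual %.3g",
                 max_iter, sqrt(rout)), call. = FALSE)
  }
  attr(x, "iterations") <- it
  x
}

#' Observed-over-expected normalisation
#'
#' Divides each entry of a (balanced) matrix by the mean of its |i-j|
#' diagonal over unmasked pairs, removing the genomic distance-decay so
#' that the compartment plaid dominates the correlation structure.
#' Diagonals whose mean is zero or that have no unmasked pairs yield NA.
#'
#' @param mat a `contact_matrix` (typically the balanced one).
#' @return a `contact_matrix` holding the O/E matrix.
#' @export
observed_over_expected <- function(mat) {
  stopifnot(inherits(mat, "contact_matrix"))
  m <- mat$counts
  n <- nrow(m)
  keep <- mat$bin_mask
  d <- abs(row(m) - col(m))
  use <- outer(keep, keep, "&") & !is.na(m)
  mu <- vapply(0:(n - 1), function(k) {
    v <- m[d == k & use]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  expct <- matrix(mu[d + 1], n, n)
  oe <- ifelse(use & !is.na(expct) & expct > 0, m / expct, NA_real_)
  out <- mat
  out$counts <- oe
  out
}

#' Aggregate a contact matrix to a coarser bin size
#'
#' Sums counts over `factor` x `factor` blocks (e.g., 25-kb TAD-resolution
#' bins to 100-kb compartment-resolution bins). A coarse bin is masked
#' only if all its fine bins are masked.
#'
#' @param mat a `contact_matrix` of raw counts.
#' @param factor integer aggregation factor.
#' @export
aggregate_bins <- function(mat, factor) {
  stopifnot(inherits(mat, "contact_matrix"), factor >= 1)
  n <- nrow(mat$counts)
  grp <- (seq_len(n) - 1) %/% factor + 1
  agg <- rowsum(t(rowsum(mat$counts, grp)), grp)
  mask <- as.vector(rowsum(as.numeric(mat$bin_mask), grp)) > 0
  contact_matrix(as.matrix(agg), mat$chrom, mat$bin_size * factor,
                 bin_mask = mask)
}

#' A/B compartment track from the leading eigenvector
#'
#' Computes the Pearson correlation matrix of the O/E matrix over
#' unmasked bins, takes the leading eigenvector, orients it per
#' chromosome so that its correlation with GC content is positive
#' (A compartments are GC-rich), and labels bins A (score > 0) or
#' B (score < 0); masked bins are labelled undefined (NA). If the
#' GC correlation is exactly zero the orientation is undecidable and
#' the whole chromosome is labelled undefined.
#'
#' @param oe O/E `contact_matrix`.
#' @param gc numeric per-bin GC fraction.
#' @return object of class `compartment_track`: data.frame with chrom,
#'   start, end, score, label.
#' @export
compartment_pc1 <- function(oe, gc) {
  stopifnot(inherits(oe, "contact_matrix"))
  n <- nrow(oe$counts)
  stopifnot(length(gc) == n)
  keep <- oe$bin_mask
  m <- oe$counts[keep, keep, drop = FALSE]
  # bins left with NA entries or zero variance cannot enter the correlation
  ok <- apply(m, 1, function(r) all(is.finite(r)) && stats::sd(r) > 0)
  if (any(!ok)) {
    warning(sum(!ok), " degenerate bin(s) masked before correlation",
            call. = FALSE)
    keep[keep][!ok] <- FALSE
    m <- m[ok, ok, drop = FALSE]
  }
  if (nrow(m) < 10) stop("need >= 10 unmasked bins for compartment analysis",
                         call. = FALSE)
  cm <- stats::cor(m)
  ev <- eigen(cm, symmetric = TRUE)
  v <- ev$vectors[, 1]
  score <- rep(NA_real_, n)
  score[keep] <- v
  r_gc <- suppressWarnings(stats::cor(score[keep], gc[keep]))
  if (is.na(r_gc) || r_gc == 0) {
    score[] <- NA_real_
  } else if (r_gc < 0) {
    score <- -score
  }
  label <- ifelse(is.na(score), NA_character_,
                  ifelse(score > 0, "A", ifelse(score < 0, "B", NA_character_)))
  track <- data.frame(chrom = oe$chrom,
                      start = (seq_len(n) - 1) * oe$bin_size,
                      end = seq_len(n) * oe$bin_size,
                      score = score, label = label, stringsAsFactors = FALSE)
  structure(track, class = c("compartment_track", "data.frame"),
            bin_size = oe$bin_size)
}

#' Compartment segments and A/B boundaries
#'
#' Merges maximal runs of same-label bins into segments. A boundary is
#' emitted at a bin edge where the label changes between two *defined*
#' bins; undefined (masked) bins break segments without emitting a
#' boundary, since a boundary needs both sides observed.
#'
#' @param track a `compartment_track` (or the same columns rbind-ed over
#'   chromosomes).
#' @return list(segments = data.frame(chrom, start, end, label),
#'   boundaries = data.frame(chrom, pos)).
#' @export
compartment_segments <- function(track) {
  segs <- list(); bnds <- list()
  for (ch in unique(track$chrom)) {
    t1 <- track[track$chrom == ch, , drop = FALSE]
    t1 <- t1[order(t1$start), , drop = FALSE]
    lab <- t1$label
    r <- rle(ifelse(is.na(lab), "\r", lab))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    def <- r$values != "\r"
    if (any(def)) {
      segs[[ch]] <- data.frame(chrom = ch, start = t1$start[starts[def]],
                               end = t1$end[ends[def]], label = r$values[def],
                               stringsAsFactors = FALSE)
    }
    # boundary: consecutive runs both defined, adjacent bins
    if (length(r$values) > 1) {
      i <- which(def[-length(def)] & def[-1] &
                   r$values[-length(r$values)] != r$values[-1])
      if (length(i)) {
        bnds[[ch]] <- data.frame(chrom = ch, pos = t1$start[starts[i + 1]],
                                 stringsAsFactors = FALSE)
      }
    }
  }
  list(segments = if (length(segs)) do.call(rbind, c(segs, make.row.names = FALSE))
         else data.frame(chrom = character(), start = numeric(),
                         end = numeric(), label = character()),
       boundaries = if (length(bnds)) do.call(rbind, c(bnds, make.row.names = FALSE))
         else data.frame(chrom = character(), pos = numeric()))
}
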