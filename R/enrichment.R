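#' Distance from each breakpoint to the nearest boundary
#'
#' For every inversion breakpoint, the minimum absolute distance to a
#' boundary on the same chromosome, also expressed in bins
#' (distance / bin_size). Breakpoints on chromosomes without any boundary
#' have no defined distance and are excluded with a warning (and counted).
#'
#' @param breakpoints data.frame: chrom, pos (from [breakpoints_of()]).
#' @param boundaries data.frame: chrom, pos (TAD or compartment
#'   boundaries); ordering and duplication are irrelevant.
#' @param bin_size bp per bin for the bin-distance column (25,000 for
#'   TADs, 100,000 for compartments).
#' @return object of class `breakpoint_distances`: data.frame chrom, pos,
#'   nearest_boundary, distance_bp, distance_bins; attribute `n_excluded`.
#' @export
distance_table <- function(breakpoints, boundaries, bin_size) {
  stopifnot(bin_size > 0)
  res <- breakpoints
  res$nearest_boundary <- NA_real_
  res$distance_bp <- NA_real_
  for (ch in unique(breakpoints$chrom)) {
    b <- sort(unique(boundaries$pos[boundaries$chrom == ch]))
    i <- which(breakpoints$chrom == ch)
    if (!length(b)) next
    idx <- findInterval(breakpoints$pos[i], b)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(b))
    d_lo <- abs(breakpoints$pos[i] - b[lo])
    d_hi <- abs(breakpoints$pos[i] - b[hi])
    res$nearest_boundary[i] <- ifelse(d_lo <= d_hi, b[lo], b[hi])
    res$distance_bp[i] <- pmin(d_lo, d_hi)
  }
  n_excl <- sum(is.na(res$distance_bp))
  if (n_excl) {
    warning(n_excl, " breakpoint(s) on chromosomes without boundaries excluded",
            call. = FALSE)
    res <- res[!is.na(res$distance_bp), , drop = FALSE]
  }
  res$distance_bins <- res$distance_bp / bin_size
  rownames(res) <- NULL
  structure(res, class = c("breakpoint_distances", "data.frame"),
            n_excluded = n_excl)
}

#' Expected fraction of random points within `radius` of a boundary
#'
#' The analytic random-placement expectation: the union of
#' [b - radius, b + radius] over all boundaries, clipped to chromosome
#' ends and intersected with the allowed set, divided by the allowed
#' length. This is the probability that a uniformly placed point lands
#' within `radius` of some boundary.
#'
#' @param boundaries data.frame: chrom, pos.
#' @param radius bp radius ("within 1 bin" = 25,000).
#' @param layout a `genome_layout` (for chromosome ends).
#' @param allowed interval data.frame; defaults to the non-excluded,
#'   unmasked genome.
#' @export
expected_overlap_fraction <- function(boundaries, radius, layout,
                                      allowed = allowed_intervals(layout)) {
  stopifnot(nrow(allowed) > 0)
  tot <- interval_width(allowed)
  if (!nrow(boundaries)) return(0)
  len <- chrom_lengths(layout)
  s <- pmax(boundaries$pos - radius, 0)
  e <- pmin(boundaries$pos + radius, len[boundaries$chrom])
  ok <- e > s
  cov <- interval_intersect(intervals(boundaries$chrom[ok], s[ok], e[ok]),
                            allowed)
  interval_width(cov) / tot
}

# uniform points on an interval set; returns data.frame(chrom, pos)
sample_allowed_points <- function(n, allowed) {
  w <- allowed$end - allowed$start
  cum <- cumsum(w)
  u <- stats::runif(n, 0, cum[length(cum)])
  i <- findInterval(u, cum, left.open = TRUE) + 1L
  data.frame(chrom = allowed$chrom[i],
             pos = allowed$start[i] + (u - c(0, cum)[i]),
             stringsAsFactors = FALSE)
}

# fast "within radius of a boundary" test on a concatenated coordinate:
# chromosomes are laid end to end with > 2*radius padding so no proximity
# leaks across chromosome edges.
.within_radius_counter <- function(boundaries, allowed, radius) {
  chroms <- unique(allowed$chrom)
  pad <- 2 * radius + 1
  offs <- cumsum(c(0, vapply(chroms, function(ch)
    max(allowed$end[allowed$chrom == ch], 0) + pad, numeric(1))))
  names(offs) <- c(chroms, ".end")
  b <- sort(boundaries$pos + offs[boundaries$chrom])
  function(chrom, pos) {
    if (!length(b)) return(rep(FALSE, length(pos)))
    g <- pos + offs[chrom]
    idx <- findInterval(g, b)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(b))
    pmin(abs(g - b[lo]), abs(g - b[hi])) <= radius
  }
}

#' Breakpoint-boundary enrichment test
#'
#' Counts breakpoints within `radius` of the nearest boundary, compares
#' the observed fraction with the analytic random-placement expectation
#' via a df-1 goodness-of-fit chi-square, and computes a permutation
#' p-value by re-placing the same number of points uniformly on the
#' allowed set `n_perm` times (upper tail, add-one estimator).
#'
#' "Within 1 bin" is distance <= radius inclusive (`inclusive = FALSE`
#' for the strict reading).
#'
#' @param breakpoints data.frame chrom, pos.
#' @param boundaries data.frame chrom, pos.
#' @param radius bp radius (25,000).
#' @param layout a `genome_layout`.
#' @param allowed allowed interval set for the null (default: unmasked,
#'   non-excluded genome).
#' @param n_perm number of permutation draws (default 999).
#' @param inclusive count distance == radius as within (default TRUE).
#' @param boundary_kind,inversion_set bookkeeping labels carried into the
#'   result.
#' @return object of class `enrichment_result`.
#' @export
enrichment_test <- function(breakpoints, boundaries, radius, layout,
                            allowed = allowed_intervals(layout),
                            n_perm = 999, inclusive = TRUE,
                            boundary_kind = "TAD", inversion_set = "all") {
  dt <- distance_table(breakpoints, boundaries, bin_size = max(radius, 1))
  n <- nrow(dt)
  if (n < 1) stop("no breakpoints with defined distances", call. = FALSE)
  k <- if (inclusive) sum(dt$distance_bp <= radius) else sum(dt$distance_bp < radius)
  p_exp <- expected_overlap_fraction(boundaries, radius, layout, allowed)
  gof <- if (p_exp > 0 && p_exp < 1) chi_square_gof(k, n, p_exp) else NULL
  perm_p <- NA_real_
  if (n_perm >= 1) {
    counter <- .within_radius_counter(boundaries, allowed, radius)
    pts <- sample_allowed_points(n * n_perm, allowed)
    hits <- counter(pts$chrom, pts$pos)
    null_k <- as.numeric(rowsum(as.numeric(hits),
                                rep(seq_len(n_perm), each = n)))
    perm_p <- permutation_pvalue(k, null_k, tail = "ge")
  }
  res <- list(n = n, k = k, observed_fraction = k / n,
              expected_fraction = p_exp, gof = gof, perm_p = perm_p,
              radius = radius, boundary_kind = boundary_kind,
              inversion_set = inversion_set,
              n_excluded = attr(dt, "n_excluded"), distances = dt)
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment [%s boundaries, %s inversions]: observed %d/%d = %.1f%% vs expected %.1f%% (radius %s bp)\n",
              x$boundary_kind, x$inversion_set, x$k, x$n,
              100 * x$observed_fraction, 100 * x$expected_fraction,
              format(x$radius, big.mark = ",")))
  if (!is.null(x$gof)) {
    cat(sprintf("  chi2 = %.4g (p = %.4g), Yates %.4g (p = %.4g)\n",
                x$gof$chi2_plain, x$gof$p_plain, x$gof$chi2_yates, x$gof$p_yates))
  }
  if (!is.na(x$perm_p)) cat(sprintf("  permutation p = %.4g\n", x$perm_p))
  invisible(x)
}

#' Run the full enrichment suite
#'
#' 2 inversion sets (all, > `min_inversion_bp`) x 2 boundary kinds
#' (TAD, A/B compartment) x 2 coordinate frames (ref, qry) = 8 cells,
#' all at the same radius. A cell whose inversion set is empty is
#' reported as not computable; the others are unaffected.
#'
#' @param inversions inversion data.frame.
#' @param tad_boundaries,ab_boundaries boundary data.frames (chrom, pos)
#'   per frame: named lists with elements `ref` and `qry` (a plain
#'   data.frame is reused for both frames).
#' @param layout a `genome_layout`.
#' @param radius bp radius (default 25,000).
#' @param min_inversion_bp size threshold for the large-inversion set.
#' @param n_perm permutation draws per cell.
#' @param inclusive see [enrichment_test()].
#' @return data.frame with one row per cell plus a `results` attribute
#'   holding the `enrichment_result` objects.
#' @export
run_enrichment_suite <- function(inversions, tad_boundaries, ab_boundaries,
                                 layout, radius = 25000,
                                 min_inversion_bp = 25000, n_perm = 999,
                                 inclusive = TRUE) {
  per_frame <- function(b) if (is.data.frame(b)) list(ref = b, qry = b) else b
  tadb <- per_frame(tad_boundaries); abb <- per_frame(ab_boundaries)
  sets <- list(all = inversions,
               gt_25kb = filter_inversions(inversions, min_inversion_bp))
  rows <- list(); objs <- list()
  for (frame in c("ref", "qry")) {
    for (kind in c("TAD", "AB_compartment")) {
      bnd <- if (kind == "TAD") tadb[[frame]] else abb[[frame]]
      for (set_name in names(sets)) {
        id <- paste(frame, kind, set_name, sep = ".")
        inv <- sets[[set_name]]
        if (!nrow(inv)) {
          rows[[id]] <- data.frame(frame = frame, boundary_kind = kind,
                                   inversion_set = set_name, n = 0L, k = NA_integer_,
                                   observed_fraction = NA_real_,
                                   expected_fraction = NA_real_,
                                   chi2 = NA_real_, p_chi2 = NA_real_,
                                   perm_p = NA_real_, stringsAsFactors = FALSE)
          next
        }
        bp <- breakpoints_of(inv, frame)
        r <- enrichment_test(bp, bnd, radius, layout, n_perm = n_perm,
                             inclusive = inclusive, boundary_kind = kind,
                             inversion_set = set_name)
        objs[[id]] <- r
        rows[[id]] <- data.frame(frame = frame, boundary_kind = kind,
                                 inversion_set = set_name, n = r$n, k = r$k,
                                 observed_fraction = r$observed_fraction,
                                 expected_fraction = r$expected_fraction,
                                 chi2 = if (is.null(r$gof)) NA_real_ else r$gof$chi2_plain,
                                 p_chi2 = if (is.null(r$gof)) NA_real_ else r$gof$p_plain,
                                 perm_p = r$perm_p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "results") <- objs
  out
}
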