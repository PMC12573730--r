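test_that("site filters implement the missingness, outgroup and MAC rules", {
  st <- counts_site_table(c2 = c(5, 5, 0), c3 = c(2, 2, 0), n = 20)
  st$is_snp <- c(TRUE, TRUE, FALSE)
  # 3 of 10 P2 samples missing = 30% > 20% -> dropped
  st$n_P2[1] <- 14
  out <- apply_site_filters(st, filter_config(), "fst_dxy")
  expect_equal(out$pos, c(20, 30))
  # invariant genotyped site retained in fst_dxy mode
  expect_true(any(!out$is_snp))
  # abba mode: missing outgroup genotype drops the site outright
  st2 <- counts_site_table(c2 = c(5, 5), c3 = c(2, 2), n = 20)
  st2$n_OUT[1] <- 0
  out2 <- apply_site_filters(st2, filter_config(), "abba")
  expect_equal(out2$pos, 20)
  # mac >= 1: a site where every genotyped allele is derived fails
  st3 <- counts_site_table(c2 = 20, c3 = 20, c1 = 20, n = 20)
  st3$c_OUT <- 2
  expect_equal(nrow(apply_site_filters(st3, filter_config(), "abba")), 0)
  # unsorted input errors
  st4 <- counts_site_table(c2 = c(1, 1), c3 = c(1, 1))[2:1, ]
  expect_error(apply_site_filters(st4), "sorted")
})

test_that("site filters honour QC columns and excluded chromosomes", {
  st <- counts_site_table(c2 = rep(5, 4), c3 = rep(2, 4), n = 20)
  st$qual <- c(60, 10, 60, 60)        # below minQ 30
  st$mean_dp <- c(30, 30, 500, 30)    # above the mean + 4*sqrt(mean) cap
  st$is_indel <- c(FALSE, FALSE, FALSE, TRUE)
  out <- apply_site_filters(st, filter_config(), "fst_dxy")
  expect_equal(out$pos, 10)
  lay <- genome_layout(data.frame(name = c("chr1", "chrIX"), length = c(1e6, 1e6)),
                       excluded_chromosomes = "chrIX")
  st5 <- counts_site_table(chrom = c("chr1", "chrIX"), c2 = c(5, 5), c3 = c(2, 2))
  expect_equal(apply_site_filters(st5, layout = lay)$chrom, "chr1")
})

test_that("windowed FST is 1 at fixed differences and ~0 under panmixia", {
  fixed <- counts_site_table(c2 = rep(0, 30), c3 = rep(20, 30), n = 20,
                             h2 = 0, h3 = 0)
  expect_equal(wc_fst_window(fixed)$fst, 1)
  # both groups drawn from one panmictic pool
  set.seed(23)
  means <- replicate(200, {
    p <- runif(30, 0.1, 0.9)
    draw <- function() {
      a1 <- matrix(rbinom(30 * 10, 1, p), 30); a2 <- matrix(rbinom(30 * 10, 1, p), 30)
      list(c = rowSums(a1 + a2), h = rowSums(a1 != a2))
    }
    g2 <- draw(); g3 <- draw()
    st <- counts_site_table(c2 = g2$c, c3 = g3$c, h2 = g2$h, h3 = g3$h, n = 20)
    st$is_snp <- TRUE
    wc_fst_window(st, min_snps = 1)$fst
  })
  expect_lt(abs(mean(means, na.rm = TRUE)), 0.02)
})

test_that("windowed FST equals the independent component transcription and re-chunking", {
  st <- random_site_table(60, n_ind = 8, seed = 5)
  got <- wc_fst_window(st, min_snps = 1)$fst
  expect_equal(got, oracle_wc_fst(st), tolerance = 1e-12)
  # ratio-of-sums is invariant to chunking the SNPs arbitrarily
  comp <- wc_components(st[st$is_snp, ])
  ok <- complete.cases(comp)
  expect_equal(got, sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok]))
  expect_lt(got, 1 + 1e-12)
})

test_that("dxy counts fixed differences against an all-sites denominator", {
  # 2500 sites: 25 fixed differences, the rest invariant, full genotyping
  c2 <- c(rep(20, 25), rep(0, 2475))
  c3 <- rep(0, 2500)
  st <- counts_site_table(c2 = c2, c3 = c3, n = 20, h2 = 0, h3 = 0)
  expect_equal(dxy_window(st)$dxy, 0.01)
  # identical monomorphic frequencies give zero
  st0 <- counts_site_table(c2 = rep(0, 2500), c3 = rep(0, 2500))
  expect_equal(dxy_window(st0)$dxy, 0)
  # brute-force allele-pair oracle on a small random window
  str <- random_site_table(25, n_ind = 4, seed = 9)
  expect_equal(dxy_window(str, min_sites = 1)$dxy, oracle_dxy(str),
               tolerance = 1e-12)
  # invariance to REF/ALT relabeling at every site
  flip <- str
  for (g in c("P1", "P2", "P3", "OUT")) {
    flip[[paste0("c_", g)]] <- flip[[paste0("n_", g)]] - flip[[paste0("c_", g)]]
  }
  expect_equal(dxy_window(flip, min_sites = 1)$dxy,
               dxy_window(str, min_sites = 1)$dxy)
})

test_that("window thresholds gate FST and dxy definitions", {
  st <- random_site_table(30, seed = 13)
  st$region_class <- "colinear"
  ws <- window_stats(st, window_bp = 1000, min_snps = 25, min_sites = 2500)
  expect_true(all(is.na(ws$fst[ws$n_snps < 25])))
  expect_true(all(is.na(ws$dxy[ws$n_sites < 2500])))
})

test_that("D statistic obeys its symmetry contracts", {
  # p1 == p2 at every site -> D = 0
  st <- counts_site_table(c2 = c(4, 8, 12), c3 = c(6, 10, 2),
                          c1 = c(4, 8, 12), n = 20)
  st$c_OUT <- 0
  d <- d_statistic(st, n_blocks = 2)
  expect_equal(d$D, 0)
  # ABBA-only pattern -> D = 1
  st2 <- counts_site_table(c2 = rep(20, 10), c3 = rep(20, 10),
                           c1 = rep(0, 10), n = 20)
  expect_equal(d_statistic(st2, n_blocks = 2)$D, 1)
  # swapping P1 and P2 flips the sign
  st3 <- random_site_table(50, seed = 17)
  swapped <- st3
  for (f in c("n_", "c_", "h_")) {
    tmp <- swapped[[paste0(f, "P1")]]
    swapped[[paste0(f, "P1")]] <- swapped[[paste0(f, "P2")]]
    swapped[[paste0(f, "P2")]] <- tmp
  }
  d3 <- d_statistic(st3, n_blocks = 5)
  d3s <- d_statistic(swapped, n_blocks = 5)
  expect_equal(d3$D, -d3s$D, tolerance = 1e-12)
  # no informative sites -> undefined
  st4 <- counts_site_table(c2 = 0, c3 = 0)
  expect_true(is.na(d_statistic(st4)$D))
})

test_that("region comparison reports the rank test and per-class summaries", {
  ws <- data.frame(region_class = rep(c("inverted", "colinear"), each = 5),
                   fst = c(rep(0.9, 5), rep(0.5, 5)),
                   dxy = NA_real_)
  cmp <- compare_region_stats(ws, "fst")
  expect_equal(cmp$test$relative_effect, 1)
  expect_equal(cmp$summary$mean[cmp$summary$region_class == "inverted"], 0.9)
  ws2 <- ws[c(1, 6:10), ]
  expect_error(compare_region_stats(ws2, "fst"), "inverted")
})

test_that("region comparison p-values are uniform under identical distributions", {
  set.seed(31)
  ps <- replicate(400, {
    ws <- data.frame(region_class = rep(c("inverted", "colinear"), each = 25),
                     fst = rnorm(50), dxy = NA_real_)
    compare_region_stats(ws, "fst")$test$p_two_sided
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
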