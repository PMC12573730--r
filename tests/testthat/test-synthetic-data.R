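test_that("the generator is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 99, n_chromosomes = 1, chrom_length = 2e6,
                           snps_per_window = 5, invariant_per_window = 2,
                           genes_per_compartment = 20)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$structure$tads, b$structure$tads)
  expect_identical(a$inversions, b$inversions)
  expect_identical(a$genotypes$sites, b$genotypes$sites)
  expect_identical(a$contacts[["chr1"]]$counts, b$contacts[["chr1"]]$counts)
  expect_identical(a$expression$counts, b$expression$counts)
})

test_that("primary TADs tile chromosomes and match the configured mean size", {
  cfg <- simulation_config(seed = 12, n_chromosomes = 8, chrom_length = 2.1e7)
  st <- simulate_structure(cfg)
  prim <- st$tads[st$tads$level == 1, ]
  spans <- tapply(prim$end - prim$start, prim$chrom, sum)
  expect_true(all(spans == 2.1e7))
  expect_gt(nrow(prim), 400)
  expect_lt(abs(mean(prim$end - prim$start) - cfg$tad_size_mean),
            0.1 * cfg$tad_size_mean)
  # secondaries nest inside a primary
  sec <- st$tads[st$tads$level == 2, ]
  res <- resolve_tad_hierarchy(st$tads)
  expect_equal(sum(res$level == 2), nrow(sec))
})

test_that("inversion placement respects beta at both extremes", {
  cfg1 <- simulation_config(seed = 4, n_chromosomes = 2, chrom_length = 4e6,
                            beta = 1)
  st <- simulate_structure(cfg1)
  inv1 <- simulate_inversions(st, cfg1)
  bp <- breakpoints_of(inv1$inversions, "ref")
  dt <- distance_table(bp, inv1$tad_boundaries, 25000)
  expect_equal(mean(dt$distance_bp == 0), 1)
  # beta = 0: observed ~= expected over replicates (null identity)
  cfg0 <- simulation_config(seed = 4, n_chromosomes = 2, chrom_length = 4e6,
                            beta = 0, n_inversions = 12)
  st0 <- simulate_structure(cfg0)
  exp_frac <- expected_overlap_fraction(
    extract_tad_boundaries(st0$tads), 25000, st0$layout)
  obs <- vapply(1:40, function(s) {
    c2 <- cfg0; c2$seed <- 1000 + s
    iv <- simulate_inversions(st0, c2)
    bp <- breakpoints_of(iv$inversions, "ref")
    dt <- distance_table(bp, extract_tad_boundaries(st0$tads), 25000)
    mean(dt$distance_bp <= 25000)
  }, numeric(1))
  n_bp <- 24 * 40
  se <- sqrt(exp_frac * (1 - exp_frac) / n_bp)
  expect_lt(abs(mean(obs) - exp_frac), 3 * se + 0.02)
})

test_that("SV VCF output round-trips losslessly", {
  cfg <- simulation_config(seed = 31, n_chromosomes = 2, chrom_length = 3e6)
  st <- simulate_structure(cfg)
  inv <- simulate_inversions(st, cfg)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(inv$inversions, inv$colinear, st$layout, f)
  p <- parse_sv_vcf(f)
  expect_equal(p$inversions$id, inv$inversions$id)
  expect_equal(p$inversions$start, inv$inversions$start)
  expect_equal(p$inversions$end, inv$inversions$end)
  expect_equal(p$inversions$qry_start, inv$inversions$qry_start)
  expect_equal(p$colinear$start, inv$colinear$start)
  expect_equal(p$colinear$end, inv$colinear$end)
})

test_that("genotype output round-trips through the all-sites VCF reader", {
  cfg <- simulation_config(seed = 32, n_chromosomes = 1, chrom_length = 1e6,
                           snps_per_window = 6, invariant_per_window = 3,
                           missing_rate = 0.08)
  st <- simulate_structure(cfg)
  inv <- simulate_inversions(st, cfg)
  g <- simulate_genotypes(st, inv$inversions, cfg)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_sites_vcf(g$gt, g$sites$chrom, g$sites$pos, g$samples, f)
  back <- read_sites_vcf(f, lapply(g$groups, function(i) g$samples[i]))
  for (col in c("pos", "n_P1", "c_P1", "n_P2", "c_P2", "h_P2", "n_P3",
                "c_P3", "h_P3", "n_OUT", "c_OUT", "is_snp")) {
    expect_equal(back[[col]], g$sites[[col]], info = col)
  }
})

test_that("site counts per window match the configuration exactly", {
  cfg <- simulation_config(seed = 33, n_chromosomes = 1, chrom_length = 5e5,
                           snps_per_window = 7, invariant_per_window = 4)
  st <- simulate_structure(cfg)
  g <- simulate_genotypes(st, empty_inv_df(), cfg)
  per_win <- table(floor(g$sites$pos / 25000))
  expect_equal(length(per_win), 20)
  expect_true(all(per_win == cfg$snps_per_window + cfg$invariant_per_window))
})

test_that("no introgression means no genome-wide D signal", {
  cfg <- simulation_config(seed = 34, n_chromosomes = 1, chrom_length = 9e6,
                           alpha = 0, n_inversions = 0,
                           invariant_per_window = 0)
  st <- simulate_structure(cfg)
  g <- simulate_genotypes(st, empty_inv_df(), cfg)
  ab <- apply_site_filters(g$sites, filter_config(), "abba")
  expect_gt(nrow(ab), 20000)
  d <- d_statistic(ab)
  expect_lt(abs(d$D), 0.05)
  expect_lt(abs(d$Z), 3)
})

test_that("a flat contact model yields O/E near one", {
  cfg <- simulation_config(seed = 35, n_chromosomes = 1, chrom_length = 4e6,
                           tau = 0, kappa = 0, depth = 2e6)
  st <- simulate_structure(cfg)
  cm <- simulate_contact_matrix(st, cfg, "chr1")
  oe <- observed_over_expected(kr_balance(cm)$matrix)
  vals <- oe$counts[is.finite(oe$counts)]
  expect_lt(abs(mean(vals) - 1), 0.02)
})

test_that("expression simulation marks spanning genes and powers the A/B test", {
  cfg <- simulation_config(seed = 36, n_chromosomes = 2, chrom_length = 4e6,
                           genes_per_compartment = 200)
  st <- simulate_structure(cfg)
  ex <- simulate_expression(st, cfg)
  expect_true(any(ex$genes$true_compartment == "spanning"))
  segs <- compartment_segments(structure(st$compartments,
                                         class = c("compartment_track", "data.frame")))
  r <- assign_and_compare_expression(ex$genes, ex$counts, segs$segments)
  # planted spanning genes are recovered as spanning
  planted <- ex$genes$true_compartment == "spanning"
  expect_true(all(r$genes$compartment[planted] == "spanning"))
  # 2x mean multiplier: the rank test rejects decisively
  expect_lt(r$test$p_two_sided, 0.01)
  expect_gt(r$test$relative_effect, 0.5)
})

test_that("the A/B expression test holds its size when the multiplier is one", {
  set.seed(37)
  rej <- replicate(150, {
    a <- rnbinom(120, size = 3, mu = 200)
    b <- rnbinom(120, size = 3, mu = 200)
    brunner_munzel(b, a)$p_two_sided < 0.05
  })
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.11)
})
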