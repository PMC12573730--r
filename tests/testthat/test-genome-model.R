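test_that("interval algebra behaves as set arithmetic", {
  expect_error(intervals("chr1", 10, 10), "invalid interval")
  expect_error(intervals("chr1", -1, 10), "invalid interval")
  x <- intervals("chr1", 0, 100)
  out <- interval_setdiff(x, intervals("chr1", 40, 60))
  expect_equal(out$start, c(0, 60))
  expect_equal(out$end, c(40, 100))
  expect_equal(interval_setdiff(x, intervals("chr1", 0, 100))$start, numeric(0))
  # duplication does not double-count width
  expect_equal(interval_width(rbind(x, x)), 100)
})

test_that("window tiling truncates the last window and skips excluded chromosomes", {
  lay <- genome_layout(data.frame(name = "chr1", length = 60000))
  w <- make_windows(lay, 25000)
  expect_equal(w$start, c(0, 25000, 50000))
  expect_equal(w$end, c(25000, 50000, 60000))
  lay1 <- genome_layout(data.frame(name = "chr1", length = 25000))
  expect_equal(nrow(make_windows(lay1, 25000)), 1)
  lay2 <- genome_layout(data.frame(name = c("c1", "c2"), length = c(50000, 50000)))
  expect_equal(nrow(make_windows(lay2, 25000)), 4)
  lay3 <- genome_layout(data.frame(name = c("c1", "chrY"), length = c(50000, 50000)),
                        excluded_chromosomes = "chrY")
  expect_equal(unique(make_windows(lay3, 25000)$chrom), "c1")
})

test_that("masks are subtracted from intervals and the allowed set", {
  lay <- genome_layout(data.frame(name = "chr1", length = 1000),
                       masked = intervals("chr1", 40, 60))
  out <- subtract_masks(intervals("chr1", 0, 100), lay)
  expect_equal(out$start, c(0, 60))
  expect_equal(interval_width(allowed_intervals(lay)), 980)
  # interval fully masked vanishes
  expect_equal(nrow(subtract_masks(intervals("chr1", 45, 55), lay)), 0)
  # no masks: identity
  lay0 <- genome_layout(data.frame(name = "chr1", length = 1000))
  expect_equal(subtract_masks(intervals("chr1", 5, 10), lay0),
               intervals("chr1", 5, 10))
})

test_that("genome_layout validates its invariants", {
  expect_error(genome_layout(data.frame(name = "c", length = 0)), "> 0")
  expect_error(genome_layout(data.frame(name = "c", length = 10),
                             masked = intervals("c", 5, 20)), "beyond")
  expect_error(genome_layout(data.frame(name = "c", length = 10),
                             excluded_chromosomes = "zz"), "subset")
})

test_that("SV VCF parsing selects by ID prefix and applies the span filter", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_sv_vcf(f, c(
    "chr1\t1001\tINV1\tN\t<INV>\t.\tPASS\tEND=11000",
    "chr1\t20001\tSYNAL1\tN\t<SYN>\t.\tPASS\tEND=50000",
    "chr1\t60001\tDUP3\tN\t<DUP>\t.\tPASS\tEND=61000",
    "chr2\t1\tINV2\tN\t<INV>\t.\tPASS\tEND=30000"))
  p <- parse_sv_vcf(f)
  expect_equal(p$inversions$id, c("INV1", "INV2"))
  expect_equal(nrow(p$colinear), 1)
  expect_equal(p$inversions$length, c(10000, 30000))
  # threshold: spans {10 kb, 30 kb} with min_length 25 kb keeps >= only
  p2 <- parse_sv_vcf(f, min_length = 25000)
  expect_equal(p2$inversions$id, "INV2")
  # strict "larger than" drops a tie at exactly the threshold
  inv <- data.frame(id = c("INV1", "INV2", "INV3"), chrom = "chr1",
                    start = c(0, 0, 0), end = c(10000, 30000, 25000),
                    length = c(10000, 30000, 25000))
  expect_equal(filter_inversions(inv, 25000, strict = TRUE)$id, "INV2")
  expect_equal(filter_inversions(inv, 25000, strict = FALSE)$id,
               c("INV2", "INV3"))
})

test_that("SV VCF parsing handles empty bodies, bad records and excluded chromosomes", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_sv_vcf(f, character(0))
  p <- parse_sv_vcf(f)
  expect_equal(nrow(p$inversions), 0)
  expect_equal(nrow(p$colinear), 0)

  write_fixture_sv_vcf(f, c(
    "chr1\t5000\tINV1\tN\t<INV>\t.\tPASS\tEND=4000",
    "chr1\t9001\tINV2\tN\t<INV>\t.\tPASS\tEND=12000"))
  expect_warning(p2 <- parse_sv_vcf(f), "rejected")
  expect_equal(p2$n_rejected, 1)
  expect_equal(p2$inversions$id, "INV2")

  write_fixture_sv_vcf(f, c(
    "chrY\t100\tINV1\tN\t<INV>\t.\tPASS\tEND=500",
    "chr1\t100\tINV2\tN\t<INV>\t.\tPASS\tEND=500"))
  lay <- genome_layout(data.frame(name = c("chr1", "chrY"),
                                  length = c(1e6, 1e6)),
                       excluded_chromosomes = "chrY")
  expect_equal(parse_sv_vcf(f, layout = lay)$inversions$id, "INV2")

  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS", "chr1\t1\tbad"), f)
  expect_error(parse_sv_vcf(f), "malformed VCF line 3")
})

test_that("window classification splits mixed windows and conserves bases", {
  lay <- two_chrom_layout(1e5)
  inv <- data.frame(id = "INV1", chrom = "chr1", start = 10000, end = 25000,
                    qry_chrom = "chr1", qry_start = 10000, qry_end = 25000,
                    length = 15000)
  part <- region_partition(inv, intervals("chr1", 0, 10000), lay)
  w <- intervals("chr1", 0, 25000)
  cw <- classify_windows(w, part)
  expect_equal(nrow(cw), 2)
  expect_equal(cw$effective_span[cw$region_class == "colinear"], 10000)
  expect_equal(cw$effective_span[cw$region_class == "inverted"], 15000)
  # fully colinear window
  part2 <- region_partition(inv[0, ], intervals("chr1", 0, 25000), lay)
  cw2 <- classify_windows(w, part2)
  expect_equal(cw2$region_class, "colinear")
  expect_equal(cw2$effective_span, 25000)
  # window covered by neither class yields nothing
  expect_equal(nrow(classify_windows(intervals("chr2", 0, 25000), part)), 0)
})

test_that("classification conserves bases over a random partition", {
  set.seed(42)
  lay <- two_chrom_layout(5e5)
  for (rep in 1:5) {
    s <- sort(sample(0:490000, 4))
    inv <- data.frame(id = paste0("INV", 1:2), chrom = "chr1",
                      start = s[c(1, 3)], end = s[c(2, 4)],
                      qry_chrom = "chr1", qry_start = s[c(1, 3)],
                      qry_end = s[c(2, 4)], length = s[c(2, 4)] - s[c(1, 3)])
    inv <- inv[inv$length > 0, ]
    col <- intervals("chr1", c(0, s[2]), c(s[1], 500000))
    part <- region_partition(inv, col, lay)
    wins <- make_windows(lay, 25000)
    cw <- classify_windows(wins, part)
    covered <- interval_width(rbind(part$inverted, part$colinear))
    expect_equal(sum(cw$effective_span), covered)
    # partition round-trip: INV bases all inverted, no SYNAL-only base inverted
    expect_equal(interval_width(interval_setdiff(
      intervals(inv$chrom, inv$start, inv$end), part$inverted)), 0)
    expect_equal(interval_width(interval_intersect(part$colinear,
                                                   part$inverted)), 0)
  }
})

test_that("breakpoints come in pairs and are frame-consistent", {
  expect_equal(nrow(breakpoints_of(empty_inv_df())), 0)
  inv1 <- data.frame(id = "INV1", chrom = "chr1", start = 100, end = 900,
                     qry_chrom = "chrA", qry_start = 50, qry_end = 850,
                     length = 800)
  bp <- breakpoints_of(inv1, "ref")
  expect_setequal(bp$pos, c(100, 900))
  bq <- breakpoints_of(inv1, "qry")
  expect_setequal(bq$pos, c(50, 850))
  expect_equal(unique(bq$chrom), "chrA")
  inv16 <- do.call(rbind, replicate(16, inv1, simplify = FALSE))
  inv16$id <- paste0("INV", 1:16)
  expect_equal(nrow(breakpoints_of(inv16, "ref")), 32)
  expect_equal(nrow(breakpoints_of(inv16, "ref")),
               nrow(breakpoints_of(inv16, "qry")))
})
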