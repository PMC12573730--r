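# small symmetric positive test matrix with decaying off-diagonals
decay_matrix <- function(n, gamma = 1, scale = 100) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  scale * (1 + d)^(-gamma)
}

# independent doubly-stochastic balancer: plain Sinkhorn iteration
sinkhorn_balance <- function(a, iters = 5000) {
  x <- rep(1, nrow(a))
  for (i in seq_len(iters)) x <- x / sqrt(rowSums(a * tcrossprod(x)))
  x
}

test_that("KR balancing equalises row sums and fixes balanced input", {
  m <- decay_matrix(40)
  cm <- contact_matrix(m, "chr1", 25000, bin_mask = rep(TRUE, 40))
  bal <- kr_balance(cm)
  rs <- rowSums(bal$matrix$counts)
  expect_lt(sd(rs) / mean(rs), 1e-6)
  # feeding the balanced matrix back: scaling ~ all ones
  bal2 <- kr_balance(contact_matrix(bal$matrix$counts, "chr1", 25000,
                                    bin_mask = rep(TRUE, 40)))
  expect_lt(max(abs(bal2$scaling - 1)), 1e-5)
})

test_that("KR recovers a known diagonal scaling up to a scalar", {
  set.seed(41)
  a0 <- decay_matrix(30)
  x <- sinkhorn_balance(a0)                     # independent oracle
  a_bal <- a0 * tcrossprod(x)                   # balanced ground truth
  d <- runif(30, 0.2, 5)
  obs <- a_bal * tcrossprod(1 / d)              # corrupt with known D
  bal <- kr_balance(contact_matrix(obs, "chr1", 25000,
                                   bin_mask = rep(TRUE, 30)))
  rec <- bal$matrix$counts
  ratio <- rec / a_bal
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 1e-4)
})

test_that("KR refuses an unmasked all-zero row and scalar input scaling cancels", {
  m <- decay_matrix(20)
  m[5, ] <- 0; m[, 5] <- 0
  expect_error(kr_balance(contact_matrix(m, "chr1", 25000,
                                         bin_mask = rep(TRUE, 20))),
               "all-zero row")
  # masked, it balances the rest and leaves NA at the masked bin
  mask <- rep(TRUE, 20); mask[5] <- FALSE
  bal <- kr_balance(contact_matrix(m, "chr1", 25000, bin_mask = mask))
  expect_true(is.na(bal$scaling[5]))
  expect_true(all(is.na(bal$matrix$counts[5, ])))
  # multiplying input by a positive scalar leaves the balanced matrix alone
  m2 <- decay_matrix(25)
  b1 <- kr_balance(contact_matrix(m2, "c", 1, bin_mask = rep(TRUE, 25)))
  b2 <- kr_balance(contact_matrix(7 * m2, "c", 1, bin_mask = rep(TRUE, 25)))
  expect_equal(b1$matrix$counts, b2$matrix$counts, tolerance = 1e-6)
})

test_that("observed/expected flattens an exact decay and scales a doubled entry", {
  m <- decay_matrix(30)
  cm <- contact_matrix(m, "chr1", 25000, bin_mask = rep(TRUE, 30))
  oe <- observed_over_expected(cm)
  expect_equal(max(abs(oe$counts - 1)), 0, tolerance = 1e-12)
  m2 <- m
  m2[3, 10] <- m2[10, 3] <- 2 * m2[3, 10]
  oe2 <- observed_over_expected(contact_matrix(m2, "chr1", 25000,
                                               bin_mask = rep(TRUE, 30)))
  # the doubled entry sits ~2x its diagonal's level (diagonal mean shifts a bit)
  expect_gt(oe2$counts[3, 10], 1.8)
  # fully masked matrix yields no defined O/E entries
  oe3 <- observed_over_expected(contact_matrix(m, "chr1", 25000,
                                               bin_mask = rep(FALSE, 30)))
  expect_true(all(is.na(oe3$counts)))
})

test_that("compartment PC1 separates a two-block plaid and follows GC orientation", {
  n <- 20
  blocks <- rep(c(1, -1), each = n / 2)
  plaid <- 1 + 0.5 * outer(blocks, blocks)
  cm <- contact_matrix(plaid * 50, "chr1", 1e5, bin_mask = rep(TRUE, n))
  oe <- observed_over_expected(cm)
  gc <- ifelse(blocks > 0, 0.45, 0.40)
  tr <- compartment_pc1(oe, gc)
  expect_true(all(tr$label[1:10] == "A"))
  expect_true(all(tr$label[11:20] == "B"))
  # flipped GC flips the labels
  tr2 <- compartment_pc1(oe, rev(gc))
  expect_true(all(tr2$label[1:10] == "B"))
  # score invariant (after orientation) to scalar input scaling
  oe_scaled <- oe
  oe_scaled$counts <- oe$counts * 3
  tr3 <- compartment_pc1(oe_scaled, gc)
  expect_equal(tr3$score, tr$score, tolerance = 1e-9)
})

test_that("compartment segments merge runs and break at undefined bins", {
  track <- data.frame(chrom = "chr1",
                      start = (0:3) * 1e5, end = (1:4) * 1e5,
                      score = c(1, 1, -1, -1),
                      label = c("A", "A", "B", "B"))
  seg <- compartment_segments(track)
  expect_equal(nrow(seg$segments), 2)
  expect_equal(seg$segments$end[1], 2e5)
  expect_equal(seg$boundaries$pos, 2e5)
  # all same label: no boundary
  track$label <- "A"
  expect_equal(nrow(compartment_segments(track)$boundaries), 0)
  # undefined bin between A and B: segments split, no boundary emitted
  track2 <- data.frame(chrom = "chr1", start = (0:2) * 1e5,
                       end = (1:3) * 1e5, score = c(1, NA, -1),
                       label = c("A", NA, "B"))
  seg2 <- compartment_segments(track2)
  expect_equal(nrow(seg2$segments), 2)
  expect_equal(nrow(seg2$boundaries), 0)
})

test_that("TAD hierarchy resolution collapses duplicates and keeps nesting", {
  tads <- data.frame(chrom = "chr1",
                     start = c(0, 0, 50000),
                     end = c(300000, 300000, 150000),
                     level = c(1L, 2L, 2L))
  res <- resolve_tad_hierarchy(tads)
  expect_equal(nrow(res), 2)
  expect_equal(res$level[res$start == 0], 1L)
  expect_equal(res$level[res$start == 50000], 2L)
  expect_equal(nrow(resolve_tad_hierarchy(tads[0, ])), 0)
})

test_that("TAD boundaries take both endpoints of both levels, deduplicated", {
  one <- data.frame(chrom = "chr1", start = 1e5, end = 4e5, level = 1L)
  expect_equal(extract_tad_boundaries(one)$pos, c(1e5, 4e5))
  adj <- data.frame(chrom = "chr1", start = c(0, 3e5), end = c(3e5, 5e5),
                    level = 1L)
  expect_equal(extract_tad_boundaries(adj)$pos, c(0, 3e5, 5e5))
  nest <- rbind(adj, data.frame(chrom = "chr1", start = 1e5, end = 2e5,
                                level = 2L))
  b <- extract_tad_boundaries(nest)
  expect_equal(b$pos, c(0, 1e5, 2e5, 3e5, 5e5))
  expect_lte(nrow(b), 2 * nrow(nest))
  counts <- tad_boundary_counts(nest)
  expect_equal(counts$endpoints, c(4L, 2L))
})

test_that("insulation caller finds a block boundary and stays quiet on uniform input", {
  n <- 40
  m <- matrix(1, n, n)
  m[1:20, 1:20] <- 30
  m[21:40, 21:40] <- 30
  cm <- contact_matrix(m, "chr1", 25000, bin_mask = rep(TRUE, n))
  b <- insulation_boundaries(cm, window_bins = 5, delta_threshold = 0.2)
  expect_equal(b$bin, 20L)
  expect_equal(b$pos, 20 * 25000)
  uni <- contact_matrix(matrix(10, n, n), "chr1", 25000,
                        bin_mask = rep(TRUE, n))
  expect_equal(nrow(insulation_boundaries(uni, 5, 0.2)), 0)
})

test_that("TPM normalises to a million and assigns compartment genes", {
  expect_equal(as.numeric(tpm(matrix(37, 1, 1), 500)), 1e6)
  counts <- matrix(10, 5, 3)
  t5 <- tpm(counts, rep(2000, 5))
  expect_equal(unique(as.numeric(t5)), 1e6 / 5)
  set.seed(3)
  counts2 <- matrix(rpois(30, 50), 10, 3)
  expect_equal(colSums(tpm(counts2, runif(10, 500, 5000))), rep(1e6, 3),
               tolerance = 1e-9)
  expect_error(tpm(counts, rep(0, 5)), "length")
  segs <- data.frame(chrom = "chr1", start = c(0, 2e5), end = c(2e5, 4e5),
                     label = c("A", "B"))
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      start = c(1e4, 2.5e5, 1.9e5), end = c(2e4, 2.6e5, 2.1e5),
                      length_bp = c(1e4, 1e4, 2e4))
  g <- assign_genes_compartments(genes, segs)
  expect_equal(g$compartment, c("A", "B", "spanning"))
  r <- assign_and_compare_expression(genes, matrix(10, 3, 2), segs)
  expect_equal(r$n_spanning, 1)
})

test_that("contact matrices and tracks round-trip through their text formats", {
  set.seed(5)
  m <- matrix(rpois(400, 6), 20, 20)
  m <- m + t(m)
  cm <- contact_matrix(m, "chr1", 25000, min_nonzero = 1)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_contact_matrix(cm, f1, f2)
  cm2 <- read_contact_matrix(f1, f2, min_nonzero = 1)
  expect_equal(cm2$counts, cm$counts)
  expect_equal(cm2$bin_size, 25000)
  gc <- data.frame(chrom = "chr1", start = c(0, 1e5), end = c(1e5, 2e5),
                   gc = c(0.41, 0.44))
  f3 <- withr::local_tempfile()
  write_gc_bedgraph(gc, f3)
  expect_equal(read_gc_bedgraph(f3), gc)
  tads <- data.frame(chrom = "chr1", start = 0, end = 3e5, level = 1L)
  f4 <- withr::local_tempfile()
  write_tads(tads, f4)
  expect_equal(read_tads(f4), tads)
})
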