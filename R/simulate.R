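#' Simulation configuration
#'
#' Defaults describe a desk-scale stickleback-like study: three 8-Mb
#' chromosomes tiled by primary TADs averaging 330 kb (25-kb bins) with
#' about half carrying one nested secondary TAD; alternating A/B
#' compartment segments averaging ~450 kb at 100-kb resolution; GC-rich A
#' compartments; 16 inversions with breakpoints snapped to TAD boundaries
#' with probability `beta`; four population groups of 10 diploids with
#' Balding-Nichols differentiation F_inverted = 0.8 vs F_colinear = 0.3
#' and introgression alpha = 0.1 confined to colinear regions; negative
#' binomial expression counts over 7 samples with a 2x mean for A-genes.
#'
#' @param seed integer RNG seed; each stage derives a fixed offset from it.
#' @param n_chromosomes,chrom_length genome shape.
#' @param tad_bin,tad_size_mean,tad_size_sd,secondary_fraction TAD model (bp).
#' @param compartment_bin,compartment_segment_mean compartment model (bp).
#' @param gamma,tau,kappa,depth contact model: distance-decay exponent,
#'   TAD contrast, compartment plaid strength, expected contacts per
#'   chromosome.
#' @param gc_base,gc_effect,gc_sd GC track model (fractions).
#' @param n_inversions,inv_length_meanlog,inv_length_sdlog,beta inversion
#'   model; `beta` is the probability a breakpoint is placed on a TAD
#'   boundary rather than uniformly.
#' @param n_per_group,F_inverted,F_colinear,F_allopatric,alpha,
#'   snps_per_window,invariant_per_window,missing_rate popgen model.
#' @param genes_per_compartment,gene_spanning_fraction,a_multiplier,
#'   expr_base_mean,expr_dispersion,n_expr_samples expression model.
#' @param mask_n_per_chrom,mask_length hardmasked intervals emitted into
#'   the layout.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_chromosomes = 3, chrom_length = 8e6,
                              tad_bin = 25000, tad_size_mean = 330000,
                              tad_size_sd = 120000, secondary_fraction = 0.5,
                              compartment_bin = 1e5,
                              compartment_segment_mean = 450000,
                              gamma = 1.0, tau = 1.0, kappa = 0.3, depth = 5e5,
                              gc_base = 0.40, gc_effect = 0.04, gc_sd = 0.01,
                              n_inversions = 16,
                              inv_length_meanlog = log(150000),
                              inv_length_sdlog = 0.6, beta = 0.5,
                              n_per_group = 10, F_inverted = 0.8,
                              F_colinear = 0.3, F_allopatric = 0.05,
                              alpha = 0.1, snps_per_window = 60,
                              invariant_per_window = 2750,
                              missing_rate = 0,
                              genes_per_compartment = 300,
                              gene_spanning_fraction = 0.05,
                              a_multiplier = 2.0, expr_base_mean = 200,
                              expr_dispersion = 0.3, n_expr_samples = 7,
                              mask_n_per_chrom = 0, mask_length = 25000) {
  cfg <- as.list(environment())
  stopifnot(cfg$beta >= 0, cfg$beta <= 1, cfg$alpha >= 0, cfg$alpha <= 1,
            cfg$F_inverted >= 0, cfg$F_inverted < 1,
            cfg$F_colinear >= 0, cfg$F_colinear < 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$gene_spanning_fraction >= 0, cfg$gene_spanning_fraction <= 1,
            cfg$seed < 2^31)
  structure(cfg, class = "simulation_config")
}

# Balding-Nichols draw: population frequency around ancestral `a` with
# differentiation parameter F; F = 0 returns a unchanged.
rbalding_nichols <- function(a, F) {
  if (F <= 0) return(a)
  stats::rbeta(length(a), a * (1 - F) / F, (1 - a) * (1 - F) / F)
}

#' Simulate genome structure: layout, TADs, compartments, GC
#'
#' Chromosomes are tiled end-to-end by primary TADs (sizes normal around
#' `tad_size_mean`, rounded to TAD bins, minimum two bins, last one
#' truncated); a fraction carries one nested secondary TAD. Compartment
#' labels alternate A/B in segments of geometric bin counts around
#' `compartment_segment_mean`; per-bin GC is gc_base + gc_effect * 1[A]
#' + noise.
#'
#' @param config a [simulation_config()].
#' @return list(layout, tads, compartments (bin-level data.frame),
#'   gc (per compartment-bin data.frame)).
#' @export
simulate_structure <- function(config) {
  set.seed(config$seed + 11L)
  chroms <- data.frame(name = paste0("chr", seq_len(config$n_chromosomes)),
                       length = rep(config$chrom_length, config$n_chromosomes),
                       stringsAsFactors = FALSE)
  masked <- empty_intervals()
  if (config$mask_n_per_chrom > 0) {
    ms <- lapply(chroms$name, function(ch) {
      s <- sort(stats::runif(config$mask_n_per_chrom, 0,
                             config$chrom_length - config$mask_length))
      intervals(ch, s, s + config$mask_length)
    })
    masked <- interval_union(do.call(rbind, ms))
  }
  layout <- genome_layout(chroms, masked = masked)
  bin <- config$tad_bin
  tads <- list(); comp <- list(); gc <- list()
  for (ch in chroms$name) {
    L <- config$chrom_length
    # primary TAD tiling
    sizes <- numeric(0); tot <- 0
    while (tot < L) {
      s <- round(stats::rnorm(1, config$tad_size_mean, config$tad_size_sd) / bin) * bin
      s <- max(s, 2 * bin)
      sizes <- c(sizes, s); tot <- tot + s
    }
    ends <- pmin(cumsum(sizes), L)
    starts <- c(0, utils::head(ends, -1))
    keep <- ends > starts
    prim <- data.frame(chrom = ch, start = starts[keep], end = ends[keep],
                       level = 1L, stringsAsFactors = FALSE)
    sec <- NULL
    big <- which((prim$end - prim$start) >= 4 * bin)
    pick <- big[stats::runif(length(big)) < config$secondary_fraction]
    if (length(pick)) {
      w <- (prim$end[pick] - prim$start[pick]) / bin
      len2 <- pmax(2, floor(w / 2))
      off <- vapply(seq_along(pick),
                    function(i) sample.int(w[i] - len2[i] + 1, 1) - 1, numeric(1))
      sec <- data.frame(chrom = ch,
                        start = prim$start[pick] + off * bin,
                        end = prim$start[pick] + (off + len2) * bin,
                        level = 2L, stringsAsFactors = FALSE)
      # a secondary spanning the whole primary would duplicate it; drop those
      sec <- sec[!(sec$start == prim$start[pick] & sec$end == prim$end[pick]), ,
                 drop = FALSE]
    }
    tads[[ch]] <- rbind(prim, sec)
    # compartments at compartment_bin resolution
    nb <- ceiling(L / config$compartment_bin)
    mean_bins <- config$compartment_segment_mean / config$compartment_bin
    lab <- character(0)
    cur <- sample(c("A", "B"), 1)
    while (length(lab) < nb) {
      seg <- 1 + stats::rpois(1, mean_bins - 1)
      lab <- c(lab, rep(cur, seg))
      cur <- if (cur == "A") "B" else "A"
    }
    lab <- lab[seq_len(nb)]
    bs <- (seq_len(nb) - 1) * config$compartment_bin
    comp[[ch]] <- data.frame(chrom = ch, start = bs,
                             end = pmin(bs + config$compartment_bin, L),
                             label = lab, stringsAsFactors = FALSE)
    gc[[ch]] <- data.frame(chrom = ch, start = bs,
                           end = pmin(bs + config$compartment_bin, L),
                           gc = config$gc_base +
                             config$gc_effect * (lab == "A") +
                             stats::rnorm(nb, 0, config$gc_sd),
                           stringsAsFactors = FALSE)
  }
  list(layout = layout,
       tads = do.call(rbind, c(tads, make.row.names = FALSE)),
       compartments = do.call(rbind, c(comp, make.row.names = FALSE)),
       gc = do.call(rbind, c(gc, make.row.names = FALSE)))
}

#' Simulate a binned Hi-C contact matrix for one chromosome
#'
#' Expected counts mu_ij = s * (1+|i-j|)^(-gamma) * (1 + tau 1[same
#' primary TAD]) * (1 + tau/2 1[same secondary TAD]) * (1 + kappa c_i c_j)
#' with c = +1/-1 for A/B bins, scaled so the matrix total is `depth`;
#' counts are Poisson draws, symmetrised.
#'
#' @param structure output of [simulate_structure()].
#' @param config a [simulation_config()].
#' @param chrom chromosome name.
#' @return a `contact_matrix` at TAD-bin resolution.
#' @export
simulate_contact_matrix <- function(structure, config, chrom) {
  set.seed(config$seed + 13L + match(chrom, structure$layout$chromosomes$name))
  bin <- config$tad_bin
  L <- chrom_lengths(structure$layout)[[chrom]]
  n <- ceiling(L / bin)
  mid <- (seq_len(n) - 0.5) * bin
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- (1 + d)^(-config$gamma)
  tt <- structure$tads[structure$tads$chrom == chrom, , drop = FALSE]
  for (lvl in c(1L, 2L)) {
    tl <- tt[tt$level == lvl, , drop = FALSE]
    if (!nrow(tl)) next
    id <- rep(NA_integer_, n)
    for (j in seq_len(nrow(tl))) {
      id[mid > tl$start[j] & mid < tl$end[j]] <- j
    }
    same <- outer(id, id, function(x, y) !is.na(x) & !is.na(y) & x == y)
    mu <- mu * (1 + (if (lvl == 1L) config$tau else config$tau / 2) * same)
  }
  cm <- structure$compartments[structure$compartments$chrom == chrom, ,
                               drop = FALSE]
  ci <- ifelse(cm$label[findInterval(mid, cm$start)] == "A", 1, -1)
  mu <- mu * (1 + config$kappa * outer(ci, ci))
  mu <- mu * config$depth / sum(mu[upper.tri(mu, diag = TRUE)])
  counts <- matrix(0, n, n)
  ut <- upper.tri(counts, diag = TRUE)
  counts[ut] <- stats::rpois(sum(ut), mu[ut])
  counts <- counts + t(counts) - diag(diag(counts))
  contact_matrix(counts, chrom, bin)
}

#' Simulate inversions with plantable boundary enrichment
#'
#' Each inversion's start breakpoint is placed on a uniformly chosen TAD
#' boundary of its chromosome with probability `beta`, else uniformly on
#' the allowed genome; the end falls a log-normal length downstream and
#' is likewise snapped to the boundary nearest that point with
#' probability `beta`. beta = 0 is the uniform null, beta = 1 puts every
#' breakpoint on a boundary. Overlapping placements are rejected and
#' redrawn. Colinear blocks are emitted as the complement of the
#' inversions.
#'
#' @param structure output of [simulate_structure()].
#' @param config a [simulation_config()].
#' @return list(inversions (with snap provenance), colinear,
#'   tad_boundaries used for snapping).
#' @export
simulate_inversions <- function(structure, config) {
  set.seed(config$seed + 17L)
  layout <- structure$layout
  bnd <- extract_tad_boundaries(structure$tads)
  allowed <- allowed_intervals(layout)
  placed <- list()
  tries <- 0
  while (length(placed) < config$n_inversions && tries < config$n_inversions * 200) {
    tries <- tries + 1
    snap_s <- stats::runif(1) < config$beta
    if (snap_s) {
      i <- sample.int(nrow(bnd), 1)
      ch <- bnd$chrom[i]; s <- bnd$pos[i]
    } else {
      p <- sample_allowed_points(1, allowed)
      ch <- p$chrom; s <- p$pos
    }
    len <- stats::rlnorm(1, config$inv_length_meanlog, config$inv_length_sdlog)
    e0 <- s + len
    snap_e <- stats::runif(1) < config$beta
    if (snap_e) {
      bch <- bnd$pos[bnd$chrom == ch & bnd$pos != s]
      if (!length(bch)) next
      e <- bch[which.min(abs(bch - e0))]
    } else e <- e0
    L <- chrom_lengths(layout)[[ch]]
    s2 <- min(s, e); e2 <- max(s, e)
    s2 <- max(0, s2); e2 <- min(L, e2)
    if (e2 - s2 < 2 * config$tad_bin / 5) next   # degenerate placement
    clash <- any(vapply(placed, function(q)
      q$chrom == ch && s2 < q$end && q$start < e2, logical(1)))
    if (clash) next
    placed[[length(placed) + 1]] <- list(chrom = ch, start = round(s2),
                                         end = round(e2),
                                         start_snapped = snap_s,
                                         end_snapped = snap_e)
  }
  if (!length(placed)) {
    return(list(inversions = .empty_inversions(), colinear = genome_intervals(layout),
                tad_boundaries = bnd))
  }
  inv <- do.call(rbind, lapply(placed, as.data.frame))
  o <- order(inv$chrom, inv$start)
  inv <- inv[o, , drop = FALSE]
  inv <- data.frame(id = paste0("INV", seq_len(nrow(inv))),
                    chrom = inv$chrom, start = inv$start, end = inv$end,
                    qry_chrom = inv$chrom, qry_start = inv$start,
                    qry_end = inv$end, length = inv$end - inv$start,
                    start_snapped = inv$start_snapped,
                    end_snapped = inv$end_snapped, stringsAsFactors = FALSE)
  colinear <- interval_setdiff(genome_intervals(layout),
                               intervals(inv$chrom, inv$start, inv$end))
  list(inversions = inv, colinear = colinear, tad_boundaries = bnd)
}

#' Write inversions and colinear blocks as an SV-dialect VCF
#'
#' Emits the aligner/SV-caller dialect consumed by [parse_sv_vcf()]:
#' `INV<n>` records with INFO END and query coordinates
#' (ChrB/StartB/EndB), `SYNAL<n>` records for colinear blocks.
#'
#' @param inversions inversion data.frame.
#' @param colinear interval data.frame.
#' @param layout a `genome_layout` (contig headers).
#' @param path output path.
#' @export
write_sv_vcf <- function(inversions, colinear, layout, path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", layout$chromosomes$name,
                  ",length=", format(layout$chromosomes$length, scientific = FALSE, trim = TRUE), ">"),
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=ChrB,Number=1,Type=String,Description=\"Query chromosome\">",
           "##INFO=<ID=StartB,Number=1,Type=Integer,Description=\"Query start\">",
           "##INFO=<ID=EndB,Number=1,Type=Integer,Description=\"Query end\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmt_n <- function(x) format(x, scientific = FALSE, trim = TRUE)
  rows <- character(0)
  if (nrow(inversions)) {
    rows <- c(rows, sprintf(
      "%s\t%s\t%s\tN\t<INV>\t.\tPASS\tEND=%s;ChrB=%s;StartB=%s;EndB=%s",
      inversions$chrom, fmt_n(inversions$start + 1), inversions$id,
      fmt_n(inversions$end), inversions$qry_chrom,
      fmt_n(inversions$qry_start + 1), fmt_n(inversions$qry_end)))
  }
  if (nrow(colinear)) {
    rows <- c(rows, sprintf("%s\t%s\tSYNAL%d\tN\t<SYN>\t.\tPASS\tEND=%s",
                            colinear$chrom, fmt_n(colinear$start + 1),
                            seq_len(nrow(colinear)), fmt_n(colinear$end)))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Simulate four-population all-sites genotypes
#'
#' Frequency-model genotypes for P1 (allopatric), P2 (sympatric species
#' A), P3 (sympatric species B) and OUT (outgroup, fixed ancestral).
#' Per SNP: ancestral derived frequency a ~ U(0.05, 0.95); P2 and P3
#' frequencies are independent Balding-Nichols draws with the region's
#' differentiation parameter (F_inverted inside inversions, F_colinear
#' elsewhere); P1 is drawn around P2's (pre-introgression) frequency with
#' F_allopatric. Introgression: in colinear regions each P2 allele is
#' drawn from P3's frequency with probability `alpha` (sampling frequency
#' (1-alpha) p2 + alpha p3); alpha is forced to 0 inside inversions, so
#' inversions behave as barriers to gene flow. Genotypes are Binomial(2,
#' freq) per diploid; invariant sites are emitted at the configured
#' per-window density. Optional uniform genotype missingness.
#'
#' @param structure output of [simulate_structure()].
#' @param inversions inversion data.frame (reference frame).
#' @param config a [simulation_config()].
#' @param window_bp window size used to lay out sites (default tad_bin).
#' @return list(sites = site table with region_class, gt = genotype dose
#'   matrix, samples = sample-name vector, groups = group index list,
#'   truth = per-site ancestral/population frequencies).
#' @export
simulate_genotypes <- function(structure, inversions, config,
                               window_bp = config$tad_bin) {
  set.seed(config$seed + 19L)
  layout <- structure$layout
  windows <- make_windows(layout, window_bp)
  inv_set <- if (nrow(inversions))
    interval_union(intervals(inversions$chrom, inversions$start, inversions$end))
  else empty_intervals()
  nw <- nrow(windows)
  nsnp <- config$snps_per_window
  # SNP positions: uniform within each window, sorted
  rel <- matrix(stats::runif(nw * nsnp), nw, nsnp)
  rel <- t(apply(rel, 1, sort))
  pos <- as.vector(t(floor(windows$start + rel * (windows$end - windows$start))))
  chrom <- rep(windows$chrom, each = nsnp)
  n_sites <- length(pos)
  # region class per SNP
  in_inv <- rep(FALSE, n_sites)
  if (nrow(inv_set)) {
    pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, pos + 1))
    in_inv <- overlaps_any_points(pts, .to_grl(inv_set))
  }
  F_reg <- ifelse(in_inv, config$F_inverted, config$F_colinear)
  a <- stats::runif(n_sites, 0.05, 0.95)
  # per-site F: beta draws vectorise over shape parameters
  draw_bn <- function(anc, F) {
    out <- anc
    pos_f <- F > 0
    if (any(pos_f)) {
      out[pos_f] <- stats::rbeta(sum(pos_f),
                                 anc[pos_f] * (1 - F[pos_f]) / F[pos_f],
                                 (1 - anc[pos_f]) * (1 - F[pos_f]) / F[pos_f])
    }
    out
  }
  p2 <- draw_bn(a, F_reg)
  p3 <- draw_bn(a, F_reg)
  p1 <- draw_bn(p2, rep(config$F_allopatric, n_sites))
  alpha_site <- ifelse(in_inv, 0, config$alpha)
  p2_eff <- (1 - alpha_site) * p2 + alpha_site * p3
  freqs <- list(P1 = p1, P2 = p2_eff, P3 = p3, OUT = rep(0, n_sites))
  n_ind <- c(P1 = config$n_per_group, P2 = config$n_per_group,
             P3 = config$n_per_group, OUT = 1)
  gt <- NULL; samples <- character(0); groups <- list()
  for (g in .group_names) {
    k <- n_ind[[g]]
    m <- matrix(stats::rbinom(n_sites * k, 1, freqs[[g]]) +
                  stats::rbinom(n_sites * k, 1, freqs[[g]]),
                n_sites, k)
    if (config$missing_rate > 0 && g != "OUT") {
      m[matrix(stats::runif(n_sites * k) < config$missing_rate, n_sites, k)] <- NA
    }
    groups[[g]] <- ncol(gt %||% matrix(nrow = 0, ncol = 0)) + seq_len(k)
    gt <- cbind(gt, m)
    samples <- c(samples, paste0(g, "_", seq_len(k)))
  }
  colnames(gt) <- samples
  # invariant sites: no RNG needed, all groups fixed ancestral
  ninv_w <- config$invariant_per_window
  if (ninv_w > 0) {
    # evenly spaced invariant positions need no RNG
    ipos <- as.vector(t(floor(windows$start +
                              outer(windows$end - windows$start,
                                    seq_len(ninv_w) / (ninv_w + 1)))))
    ichrom <- rep(windows$chrom, each = ninv_w)
    gt_inv <- matrix(0, length(ipos), ncol(gt), dimnames = list(NULL, samples))
    gt <- rbind(gt, gt_inv)
    chrom <- c(chrom, ichrom); pos <- c(pos, ipos)
    is_snp_flag <- c(rep(TRUE, n_sites), rep(FALSE, length(ipos)))
  } else is_snp_flag <- rep(TRUE, n_sites)
  o <- order(chrom, pos)
  gt <- gt[o, , drop = FALSE]
  # label SNPs by sampled polymorphism (a drawn-monomorphic site is
  # observationally invariant), which keeps the VCF round-trip lossless
  st <- site_table(chrom[o], pos[o], gt, groups)
  st$is_snp <- st$is_snp & is_snp_flag[o]
  st$qual <- 60; st$mean_dp <- 30
  st$n_alleles <- ifelse(st$is_snp, 2L, 1L); st$is_indel <- FALSE
  if (nrow(inv_set)) {
    pts <- GenomicRanges::GRanges(st$chrom, IRanges::IRanges(st$pos + 1, st$pos + 1))
    st$region_class <- ifelse(overlaps_any_points(pts, .to_grl(inv_set)),
                              "inverted", "colinear")
  } else st$region_class <- "colinear"
  truth <- data.frame(chrom = chrom[o], pos = pos[o],
                      anc = c(a, rep(0, nrow(st) - n_sites))[o],
                      p1 = c(p1, rep(0, nrow(st) - n_sites))[o],
                      p2 = c(p2_eff, rep(0, nrow(st) - n_sites))[o],
                      p3 = c(p3, rep(0, nrow(st) - n_sites))[o])
  list(sites = st, gt = gt, samples = samples, groups = groups, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a site table's genotypes as an all-sites VCF
#'
#' GT:DP:GQ per sample (constant DP/GQ placeholders that pass the default
#' filters), QUAL 60; derived allele as ALT ("." for invariant sites).
#'
#' @param gt genotype dose matrix (sites x samples; NA = missing).
#' @param chrom,pos site coordinates (pos 0-based).
#' @param samples sample names (columns of gt).
#' @param path output path.
#' @param dp,gq constant per-genotype depth and quality to emit.
#' @export
write_sites_vcf <- function(gt, chrom, pos, samples, path, dp = 30, gq = 99) {
  stopifnot(ncol(gt) == length(samples))
  gstr <- matrix("./.:.:.", nrow(gt), ncol(gt))
  gstr[gt == 0] <- paste0("0/0:", dp, ":", gq)
  gstr[gt == 1] <- paste0("0/1:", dp, ":", gq)
  gstr[gt == 2] <- paste0("1/1:", dp, ":", gq)
  alt <- ifelse(rowSums(gt, na.rm = TRUE) > 0, "T", ".")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(chrom, format(pos + 1, scientific = FALSE, trim = TRUE), ".",
                "A", alt, "60", "PASS", ".", "GT:DP:GQ",
                apply(gstr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate expression counts over compartment-placed genes
#'
#' Genes are placed inside A/B compartment segments (a configurable
#' fraction deliberately spans a boundary to exercise the exclusion
#' rule); counts are negative binomial over `n_expr_samples` samples with
#' an `a_multiplier` mean factor for A-compartment genes.
#'
#' @param structure output of [simulate_structure()].
#' @param config a [simulation_config()].
#' @return list(genes (with true_compartment), counts matrix).
#' @export
simulate_expression <- function(structure, config) {
  set.seed(config$seed + 23L)
  segs <- compartment_segments(
    structure(structure$compartments,
              class = c("compartment_track", "data.frame")))$segments
  pick_genes <- function(lab, n) {
    s <- segs[segs$label == lab & (segs$end - segs$start) >= 20000, , drop = FALSE]
    i <- sample.int(nrow(s), n, replace = TRUE,
                    prob = s$end - s$start)
    len <- round(stats::runif(n, 1000, 8000))
    start <- floor(s$start[i] + stats::runif(n) * (s$end[i] - s$start[i] - len))
    start <- pmax(start, s$start[i])
    data.frame(chrom = s$chrom[i], start = start, end = start + len,
               true_compartment = lab, stringsAsFactors = FALSE)
  }
  n <- config$genes_per_compartment
  genes <- rbind(pick_genes("A", n), pick_genes("B", n))
  # spanning genes: straddle a label change between defined segments
  n_span <- round(config$gene_spanning_fraction * 2 * n)
  if (n_span > 0) {
    bnd <- compartment_segments(
      structure(structure$compartments,
                class = c("compartment_track", "data.frame")))$boundaries
    if (nrow(bnd)) {
      i <- sample.int(nrow(bnd), n_span, replace = TRUE)
      len <- round(stats::runif(n_span, 4000, 12000))
      genes <- rbind(genes, data.frame(chrom = bnd$chrom[i],
                                       start = bnd$pos[i] - len %/% 2,
                                       end = bnd$pos[i] + len - len %/% 2,
                                       true_compartment = "spanning",
                                       stringsAsFactors = FALSE))
    }
  }
  genes$gene_id <- paste0("gene", seq_len(nrow(genes)))
  genes$length_bp <- genes$end - genes$start
  mu_gene <- config$expr_base_mean *
    stats::rlnorm(nrow(genes), 0, 0.5) *
    ifelse(genes$true_compartment == "A", config$a_multiplier, 1)
  counts <- matrix(stats::rnbinom(nrow(genes) * config$n_expr_samples,
                                  size = 1 / config$expr_dispersion,
                                  mu = mu_gene),
                   nrow(genes), config$n_expr_samples)
  colnames(counts) <- paste0("sample", seq_len(config$n_expr_samples))
  list(genes = genes[, c("gene_id", "chrom", "start", "end", "length_bp",
                         "true_compartment")],
       counts = counts)
}

#' Simulate a full synthetic study
#'
#' Runs every generator stage under one seed and returns the inputs plus
#' the serialisable ground truth.
#'
#' @param config a [simulation_config()].
#' @param contacts simulate contact matrices (TRUE) or skip them.
#' @param genotypes simulate genotypes (TRUE) or skip them.
#' @param expression simulate expression (TRUE) or skip it.
#' @return list(config, structure, inversions, colinear, contacts,
#'   genotypes, expression, truth).
#' @export
simulate_study <- function(config = simulation_config(), contacts = TRUE,
                           genotypes = TRUE, expression = TRUE) {
  structure_ <- simulate_structure(config)
  invs <- simulate_inversions(structure_, config)
  cm <- NULL
  if (contacts) {
    cm <- lapply(active_chromosomes(structure_$layout), function(ch)
      simulate_contact_matrix(structure_, config, ch))
    names(cm) <- active_chromosomes(structure_$layout)
  }
  geno <- if (genotypes) simulate_genotypes(structure_, invs$inversions, config)
          else NULL
  expr <- if (expression) simulate_expression(structure_, config) else NULL
  truth <- list(
    tads = structure_$tads,
    compartments = structure_$compartments,
    inversions = invs$inversions,
    migration = list(alpha_colinear = config$alpha, alpha_inverted = 0,
                     F_inverted = config$F_inverted,
                     F_colinear = config$F_colinear),
    expression = if (is.null(expr)) NULL else
      expr$genes[, c("gene_id", "true_compartment")])
  list(config = config, structure = structure_, inversions = invs$inversions,
       colinear = invs$colinear, tad_boundaries = invs$tad_boundaries,
       contacts = cm, genotypes = geno, expression = expr, truth = truth)
}
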