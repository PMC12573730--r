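#' Pipeline configuration
#'
#' Either a `simulate` block (overrides for [simulation_config()]) or an
#' `inputs` block with paths to on-disk data (as written by
#' [cmd_simulate()] or by external tools in the same dialects), never
#' both. Remaining fields control window size, definition thresholds and
#' the enrichment test.
#'
#' @param simulate named list of [simulation_config()] overrides, or NULL.
#' @param inputs named list of input paths, or NULL.
#' @param outdir output directory.
#' @param seed integer seed for every stochastic stage.
#' @param window_bp,min_snps,min_sites windowed-statistic settings.
#' @param radius_bp,tad_bin_bp,compartment_bin_bp,n_perm,min_inversion_bp
#'   enrichment settings.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(), inputs = NULL,
                            outdir = tempfile("invtad_run_"), seed = 1,
                            window_bp = 25000, min_snps = 25,
                            min_sites = 2500, radius_bp = 25000,
                            tad_bin_bp = 25000, compartment_bin_bp = 1e5,
                            n_perm = 999, min_inversion_bp = 25000) {
  if (!is.null(simulate) && !is.null(inputs)) {
    stop("config must give either a simulate block or input paths, not both",
         call. = FALSE)
  }
  if (is.null(simulate) && is.null(inputs)) {
    stop("config needs a simulate block or input paths", call. = FALSE)
  }
  structure(list(simulate = simulate, inputs = inputs, outdir = outdir,
                 seed = seed, window_bp = window_bp, min_snps = min_snps,
                 min_sites = min_sites, radius_bp = radius_bp,
                 tad_bin_bp = tad_bin_bp,
                 compartment_bin_bp = compartment_bin_bp, n_perm = n_perm,
                 min_inversion_bp = min_inversion_bp),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 reads "2.0e6" (no signed exponent) as a string; coerce scalars
  # that parse cleanly as numbers
  fix <- function(x) {
    if (is.list(x)) return(lapply(x, fix))
    if (is.character(x) && length(x) == 1 && !is.na(suppressWarnings(as.numeric(x)))) {
      return(as.numeric(x))
    }
    x
  }
  do.call(pipeline_config, fix(y))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              null = "null"), f)
  unname(tools::md5sum(f))
}

.sim_config_of <- function(config) {
  args <- config$simulate %||% list()
  args$seed <- args$seed %||% config$seed
  do.call(simulation_config, args)
}

.stamp <- function(config, outdir) {
  writeLines(paste0("config_hash\t", config_hash(config)),
             file.path(outdir, "RUN_INFO.tsv"))
}

#' Generate a synthetic dataset on disk
#'
#' Writes the SV VCF, all-sites genotype VCF, TAD table, sparse contact
#' matrices with bins tables, GC BEDGraph, gene BED, counts TSV and the
#' ground-truth JSON into `outdir`.
#'
#' @param config a `pipeline_config` with a simulate block.
#' @return (invisibly) the in-memory study object.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"), !is.null(config$simulate))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(.sim_config_of(config))
  out <- config$outdir
  write_sv_vcf(study$inversions, study$colinear, study$structure$layout,
               file.path(out, "sv.vcf"))
  g <- study$genotypes
  write_sites_vcf(g$gt, g$sites$chrom, g$sites$pos, g$samples,
                  file.path(out, "sites.vcf"))
  write_tads(study$structure$tads, file.path(out, "tads.tsv"))
  for (ch in names(study$contacts)) {
    write_contact_matrix(study$contacts[[ch]],
                         file.path(out, paste0("contacts_", ch, ".tsv")),
                         file.path(out, paste0("bins_", ch, ".tsv")))
  }
  write_gc_bedgraph(study$structure$gc, file.path(out, "gc.bedgraph"))
  genes <- study$expression$genes
  write_bed(data.frame(chrom = genes$chrom, start = genes$start,
                       end = genes$end, name = genes$gene_id),
            file.path(out, "genes.bed"))
  utils::write.table(cbind(gene_id = genes$gene_id,
                           length_bp = genes$length_bp,
                           as.data.frame(study$expression$counts)),
                     file.path(out, "counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  chroms <- study$structure$layout$chromosomes
  utils::write.table(chroms, file.path(out, "chromosomes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(out, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  .stamp(config, out)
  invisible(study)
}

.get_study <- function(config) {
  if (!is.null(config$simulate)) return(simulate_study(.sim_config_of(config)))
  stop("real-input mode: use the cmd_* functions with loaded objects or ",
       "point the simulate-mode pipeline at files via the readers",
       call. = FALSE)
}

#' Windowed population-genetic stage
#'
#' Windowed FST/dxy over the inverted/colinear partition, the
#' region-class rank tests and the per-class D statistics.
#'
#' @param config a `pipeline_config`.
#' @param study optional pre-built study (defaults to simulating per config).
#' @return list(window_stats, fst_comparison, dxy_comparison (NULL when
#'   undefined), d_by_class).
#' @export
cmd_popgen <- function(config, study = .get_study(config)) {
  layout <- study$structure$layout
  part <- region_partition(study$inversions, study$colinear, layout)
  sites <- apply_site_filters(study$genotypes$sites, filter_config(),
                              mode = "fst_dxy", layout = layout)
  sites <- annotate_sites_region(sites, part)
  ws <- window_stats(sites, window_bp = config$window_bp,
                     min_snps = config$min_snps, min_sites = config$min_sites)
  fst_cmp <- compare_region_stats(ws, "fst")
  dxy_cmp <- tryCatch(compare_region_stats(ws, "dxy"), error = function(e) NULL)
  ab <- apply_site_filters(study$genotypes$sites, filter_config(),
                           mode = "abba", layout = layout)
  ab <- annotate_sites_region(ab, part)
  d_by_class <- lapply(c(inverted = "inverted", colinear = "colinear"),
                       function(cl) d_statistic(ab, region_class = cl))
  list(window_stats = ws, fst_comparison = fst_cmp, dxy_comparison = dxy_cmp,
       d_by_class = d_by_class)
}

#' Hi-C stage: compartments, TAD boundaries, expression test
#'
#' @param config a `pipeline_config`.
#' @param study optional pre-built study.
#' @return list(tracks, segments, ab_boundaries, tads, tad_boundaries,
#'   boundary_counts, expression).
#' @export
cmd_hic <- function(config, study = .get_study(config)) {
  factor <- config$compartment_bin_bp / config$tad_bin_bp
  tracks <- list()
  for (ch in names(study$contacts)) {
    cmat <- aggregate_bins(study$contacts[[ch]], factor)
    bal <- kr_balance(cmat)
    oe <- observed_over_expected(bal$matrix)
    gc <- study$structure$gc
    gc <- gc$gc[gc$chrom == ch]
    tracks[[ch]] <- compartment_pc1(oe, gc[seq_len(nrow(oe$counts))])
  }
  track_all <- do.call(rbind, c(lapply(tracks, as.data.frame),
                                make.row.names = FALSE))
  seg <- compartment_segments(track_all)
  tads <- resolve_tad_hierarchy(study$structure$tads)
  tadb <- extract_tad_boundaries(tads)
  expr <- assign_and_compare_expression(study$expression$genes,
                                        study$expression$counts,
                                        seg$segments)
  list(tracks = tracks, segments = seg$segments,
       ab_boundaries = seg$boundaries, tads = tads, tad_boundaries = tadb,
       boundary_counts = tad_boundary_counts(tads), expression = expr)
}

#' Enrichment stage: the 8-cell breakpoint-boundary suite
#'
#' @param config a `pipeline_config`.
#' @param study optional pre-built study.
#' @param hic optional result of [cmd_hic()] (recomputed otherwise).
#' @return the suite table from [run_enrichment_suite()].
#' @export
cmd_enrich <- function(config, study = .get_study(config), hic = NULL) {
  if (is.null(hic)) hic <- cmd_hic(config, study)
  set.seed(config$seed + 29L)
  run_enrichment_suite(study$inversions, hic$tad_boundaries,
                       hic$ab_boundaries, study$structure$layout,
                       radius = config$radius_bp,
                       min_inversion_bp = config$min_inversion_bp,
                       n_perm = config$n_perm)
}

#' Run every stage and write the report
#'
#' Emits window statistics, the enrichment suite, breakpoint distances
#' and a human-readable text summary (differentiation, introgression,
#' compartments/TADs, enrichment -- in that order) into `outdir`.
#'
#' @param config a `pipeline_config`.
#' @return list(popgen, hic, enrichment, report_path) invisibly.
#' @export
cmd_all <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  study <- .get_study(config)
  pg <- cmd_popgen(config, study)
  hc <- cmd_hic(config, study)
  en <- cmd_enrich(config, study, hc)
  out <- config$outdir
  utils::write.table(pg$window_stats, file.path(out, "window_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(en, file.path(out, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dists <- attr(en, "results")
  if (length(dists)) {
    dt <- do.call(rbind, c(lapply(names(dists), function(nm)
      cbind(cell = nm, as.data.frame(dists[[nm]]$distances))),
      make.row.names = FALSE))
    utils::write.table(dt, file.path(out, "breakpoint_distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rpt <- file.path(out, "report.txt")
  con <- file(rpt, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("== Windowed differentiation (FST) ==")
  s <- pg$fst_comparison$summary
  for (i in seq_len(nrow(s))) {
    w("  %-9s n=%d mean=%.4f median=%.4f", s$region_class[i], s$n_windows[i],
      s$mean[i], s$median[i])
  }
  w("  Brunner-Munzel p = %.4g", pg$fst_comparison$test$p_two_sided)
  if (!is.null(pg$dxy_comparison)) {
    w("== Windowed divergence (dxy) ==")
    s <- pg$dxy_comparison$summary
    for (i in seq_len(nrow(s))) {
      w("  %-9s n=%d mean=%.5f median=%.5f", s$region_class[i],
        s$n_windows[i], s$mean[i], s$median[i])
    }
    w("  Brunner-Munzel p = %.4g", pg$dxy_comparison$test$p_two_sided)
  }
  w("== Introgression (ABBA-BABA) ==")
  for (cl in names(pg$d_by_class)) {
    d <- pg$d_by_class[[cl]]
    w("  %-9s D = %.4g, Z = %.3g, p = %.4g (%d sites)", cl, d$D, d$Z, d$p,
      d$n_sites_used)
  }
  w("== Compartments and TADs ==")
  segs <- hc$segments
  for (lab in c("A", "B")) {
    sl <- segs[segs$label == lab, , drop = FALSE]
    w("  %s compartment: %d segments, mean size %.0f bp", lab, nrow(sl),
      mean(sl$end - sl$start))
  }
  bc <- hc$boundary_counts
  for (i in seq_len(nrow(bc))) {
    w("  level-%d TADs: %d (boundaries: %d unique positions, %d endpoints)",
      bc$level[i], bc$n_tads[i], bc$unique_positions[i], bc$endpoints[i])
  }
  if (!is.null(hc$expression$test)) {
    w("  A vs B expression: Brunner-Munzel p = %.4g (A %d, B %d, spanning %d removed)",
      hc$expression$test$p_two_sided, hc$expression$n_A, hc$expression$n_B,
      hc$expression$n_spanning)
  }
  w("== Breakpoint-boundary enrichment ==")
  for (i in seq_len(nrow(en))) {
    w("  %s %-14s %-7s observed %.1f%% vs expected %.1f%% (perm p = %.4g)",
      en$frame[i], en$boundary_kind[i], en$inversion_set[i],
      100 * en$observed_fraction[i], 100 * en$expected_fraction[i],
      en$perm_p[i])
  }
  .stamp(config, out)
  invisible(list(popgen = pg, hic = hc, enrichment = en, report_path = rpt))
}
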