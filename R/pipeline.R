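#' Declarative run configuration
#'
#' Gathers every tunable of a simulated CPSA run — genome layout, landscape
#' parameters, expression coupling, size scheme, sample sheet settings and
#' analysis windows — under a single seed, so that a whole run is
#' reproducible from one object. Round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param depth Target fragment count per sample.
#' @param n_replicates MNase replicates per condition x digestion cell.
#' @param genome A [toy_genome_spec()].
#' @param landscape A [landscape_params()].
#' @param coupling An [expression_coupling()].
#' @param scheme A [size_scheme()].
#' @param tss_window subNSP TSS window for abundance/kurtosis analyses, bp.
#' @param test_windows -1/+1 windows of the occupancy test, bp.
#' @param tfbs_flank TFBS aggregation half-window, bp.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, depth = 2e5, n_replicates = 2L,
                       genome = toy_genome_spec(),
                       landscape = landscape_params(),
                       coupling = expression_coupling(),
                       scheme = size_scheme(),
                       tss_window = c(-250L, 50L),
                       test_windows = list(minus1 = c(-125L, -75L),
                                           plus1 = c(75L, 125L)),
                       tfbs_flank = 500L) {
  structure(list(seed = as.integer(seed), depth = depth,
                 n_replicates = as.integer(n_replicates), genome = genome,
                 landscape = landscape, coupling = coupling,
                 scheme = scheme, tss_window = as.integer(tss_window),
                 test_windows = test_windows,
                 tfbs_flank = as.integer(tfbs_flank)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x)[setdiff(names(attributes(x)), "names")] <- NULL
    } else if (is.atomic(x) && !is.null(names(x))) {
      x <- as.list(x)                  # keep names: YAML maps, not sequences
    }
    x
  }
  yaml::write_yaml(strip(unclass(config)), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    seed = y$seed, depth = y$depth, n_replicates = y$n_replicates,
    genome = do.call(toy_genome_spec, c(
      list(chrom_lengths = unlist(y$genome$chrom_lengths)),
      y$genome[setdiff(names(y$genome), "chrom_lengths")])),
    landscape = do.call(landscape_params, lapply(
      y$landscape, function(v) if (is.list(v)) unlist(v) else v)),
    coupling = do.call(expression_coupling, y$coupling),
    scheme = do.call(size_scheme, lapply(
      y$scheme, function(v) if (is.list(v)) unlist(v) else v)),
    tss_window = unlist(y$tss_window),
    test_windows = lapply(y$test_windows, unlist),
    tfbs_flank = y$tfbs_flank)
}

#' Simulate the full default experiment
#'
#' Builds the toy genome, plants the landscape, draws the eight-sample
#' differential-digestion fragment sets and the coupled expression/DE
#' tables — entirely in memory. [pipeline_simulate()] writes the same
#' objects to disk in standard formats.
#'
#' @param config A [run_config()].
#' @return List with `annotation`, `landscape`, `sheet`, `fragments`
#'   (named list of fragment sets), `expression`, `de`, `truth`.
#' @export
simulate_experiment <- function(config = run_config()) {
  genome <- config$genome
  genome$seed <- config$seed
  annotation <- build_toy_genome(genome)
  landscape <- plant_landscape(annotation, config$landscape,
                               seed = config$seed + 1L)
  sheet <- default_experiment(depth = config$depth,
                              base_seed = config$seed,
                              n_replicates = config$n_replicates)
  fragments <- simulate_samples(landscape, sheet)
  expr <- simulate_expression(landscape, config$coupling,
                              seed = config$seed + 2L)
  c(list(annotation = annotation, landscape = landscape, sheet = sheet,
         fragments = fragments), expr)
}

#' Write a simulated experiment to disk
#'
#' Emits per-sample fragment BEDs, the GFF3 annotation, the TFBS BED, the
#' expression / DE / planted-truth TSVs, the sample sheet, and a YAML run
#' manifest echoing every parameter and seed. Re-running with the same
#' config produces byte-identical files.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param sim Optional pre-built [simulate_experiment()] result.
#' @return The simulation list, invisibly, with attribute `paths`.
#' @export
pipeline_simulate <- function(config = run_config(), out_dir, sim = NULL) {
  if (is.null(sim)) sim <- simulate_experiment(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (sn in names(sim$fragments)) {
    p <- file.path(out_dir, paste0(sn, ".bed"))
    write_fragment_bed(sim$fragments[[sn]], p, sample_id = sn)
    paths[[paste0("bed_", sn)]] <- p
  }
  paths$gff3 <- file.path(out_dir, "annotation.gff3")
  write_annotation_gff3(sim$annotation, paths$gff3)
  if (!is.null(sim$landscape$tfbs)) {
    paths$tfbs <- file.path(out_dir, "tfbs.bed")
    fwrite(sim$landscape$tfbs, paths$tfbs, sep = "\t", col.names = FALSE,
           quote = FALSE)
  }
  paths$sample_sheet <- file.path(out_dir, "sample_sheet.tsv")
  fwrite(sim$sheet, paths$sample_sheet, sep = "\t")
  paths$expression <- file.path(out_dir, "expression.tsv")
  fwrite(sim$expression, paths$expression, sep = "\t")
  paths$de <- file.path(out_dir, "de.tsv")
  fwrite(sim$de, paths$de, sep = "\t")
  paths$truth <- file.path(out_dir, "truth.tsv")
  fwrite(sim$truth, paths$truth, sep = "\t")
  paths$manifest <- file.path(out_dir, "manifest.yaml")
  write_run_config(config, paths$manifest)
  setattr(sim, "paths", paths)
  invisible(sim)
}

#' Build and export the track set of one sample
#'
#' subNSP midpoints, mono midpoints (150 +/- 15 bp) and total >= 120 bp
#' coverage, each written as wiggle and bedGraph.
#'
#' @param fragments Fragment set of the sample.
#' @param chrom_lengths Chromosome table.
#' @param out_dir Output directory.
#' @param sample_id Label used in filenames.
#' @param scheme A [size_scheme()].
#' @param normalize Depth-normalize per million retained fragments.
#' @return Named list of track lists, invisibly.
#' @export
pipeline_tracks <- function(fragments, chrom_lengths, out_dir,
                            sample_id = "sample", scheme = size_scheme(),
                            normalize = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trks <- list(
    subnsp = subnsp_midpoint_track(fragments, chrom_lengths, scheme),
    mono = midpoint_track(fragments, chrom_lengths, scheme = scheme),
    coverage = coverage_track(fragments, chrom_lengths, scheme = scheme))
  if (normalize)
    trks <- lapply(trks, normalize_per_million, nrow(fragments))
  for (cls in names(trks)) {
    write_track(trks[[cls]],
                file.path(out_dir, sprintf("%s_%s.wig", sample_id, cls)),
                format = "wiggle", chrom_lengths = chrom_lengths)
    write_track(trks[[cls]],
                file.path(out_dir, sprintf("%s_%s.bedGraph", sample_id, cls)),
                format = "bedGraph", chrom_lengths = chrom_lengths)
  }
  invisible(trks)
}

#' Run the full CPSA analysis suite on a simulated experiment
#'
#' Ties the stages together the way the study does: per-sample tracks and
#' digestion indices; TSS profiles with the per-bin digestion correlation
#' and the -1/+1 window occupancy test; expression and kurtosis quartiles;
#' the subNSP versus expression fold-change analysis; genome-wide subNSP
#' position calls with distance-to-CDS fractions; and the TFBS aggregation
#' contrast.
#'
#' @param sim A [simulate_experiment()] result.
#' @param config The [run_config()] used to build it.
#' @return Named list of stage results (see the methods vignette for a
#'   walk-through).
#' @export
analyse_experiment <- function(sim, config = run_config()) {
  scheme <- config$scheme
  chroms <- sim$annotation$chroms
  sheet <- sim$sheet
  tss <- extract_anchors(sim$annotation, "TSS", shared_only = TRUE)

  ## per-sample tracks, digestion indices and TSS profiles
  idx <- vapply(sim$fragments, digestion_index, numeric(1), scheme = scheme)
  mono_norm <- lapply(names(sim$fragments), function(sn) {
    normalize_per_million(
      midpoint_track(sim$fragments[[sn]], chroms, scheme = scheme),
      nrow(sim$fragments[[sn]]))
  })
  names(mono_norm) <- names(sim$fragments)
  cov_raw <- lapply(sim$fragments, coverage_track, chroms, scheme = scheme)
  flank <- 1000L
  mono_prof <- lapply(mono_norm, function(tr)
    aggregate_profile(profile_matrix(tr, tss, flank = flank)))
  cov_prof <- lapply(cov_raw, function(tr)
    aggregate_profile(profile_matrix(tr, tss, flank = flank)))

  dig_cor <- digestion_correlation(mono_prof, idx)
  win_test <- window_occupancy_test(cov_prof, groups = sheet$digestion,
                                    windows = config$test_windows)

  ## expression quartiles on light replicates; kurtosis quartiles on the
  ## pooled light low-digest subNSP fragments
  light_cols <- grep("^light_r", names(sim$expression), value = TRUE)
  quart_expr <- quartiles_by_expression(
    cbind(sim$expression[, .(gene_id)],
          value = rowMeans(sim$expression[, light_cols, with = FALSE])),
    sample = "value")
  pool <- function(cond, dig = NULL) {
    sel <- sheet$condition == cond
    if (!is.null(dig)) sel <- sel & sheet$digestion == dig
    rbindlist(sim$fragments[sheet$sample_id[sel]])
  }
  light_low <- pool("light", "low")
  kstats <- tss_subnsp_stats(light_low, tss, scheme,
                             window = config$tss_window)
  sub_track_light <- normalize_per_million(
    subnsp_midpoint_track(light_low, chroms, scheme), nrow(light_low))
  sub_pm <- profile_matrix(sub_track_light, tss, flank = 500L)
  ## group light-sample expression by recruitment quartile (the kurtosis is
  ## measured on light fragments)
  light_expr <- cbind(sim$expression[, .(gene_id)],
                      expression = rowMeans(
                        sim$expression[, light_cols, with = FALSE]))
  kq <- quartiles_by_kurtosis(kstats, expression = light_expr,
                              expression_col = "expression",
                              profile = sub_pm)

  ## fold-change linkage
  light_all <- pool("light"); dark_all <- pool("dark")
  sfc <- subnsp_log2fc(light_all, dark_all, tss, scheme,
                       window = config$tss_window)
  pts <- fc_points(sfc, sim$de)
  fc <- fc_correlation(pts, seed = config$seed + 3L)

  ## genome-wide subNSP positions and TFBS aggregation
  pos <- call_subnsp_positions(sub_track_light)
  dists <- if (nrow(pos)) distance_to_nearest_cds(pos, sim$annotation)
    else numeric()
  distal <- if (base::length(dists)) fraction_beyond(dists) else NULL
  dark_low <- pool("dark", "low")
  sub_track_dark <- normalize_per_million(
    subnsp_midpoint_track(dark_low, chroms, scheme), nrow(dark_low))
  tfbs <- if (!is.null(sim$landscape$tfbs))
    tfbs_aggregate(sub_track_light, sub_track_dark, sim$landscape$tfbs,
                   flank = config$tfbs_flank) else NULL

  list(digestion_index = idx, mono_profiles = mono_prof,
       coverage_profiles = cov_prof, digestion_correlation = dig_cor,
       window_test = win_test, expression_quartiles = quart_expr,
       kurtosis = kstats, kurtosis_quartiles = kq,
       subnsp_log2fc = sfc, fc_points = pts, fc_correlation = fc,
       subnsp_positions = pos, cds_distances = dists,
       distal_fractions = distal, tfbs = tfbs)
}
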