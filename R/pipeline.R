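#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis with the
#' study defaults: a 10-arcminute grid, a one-degree circular neighborhood,
#' a 20-tree minimum cell sample, rarefaction to 40 genes, locally common
#' allele thresholds of 5% frequency and 25% occupancy, an admixture scan
#' over K = 1..10 with 20 restarts, and a 10-percentile training presence
#' threshold with five pseudo-absences per presence.
#'
#' @param cell_size grid cell edge, degrees.
#' @param diameter circular-neighborhood diameter, degrees.
#' @param min_n minimum re-sampled trees per cell.
#' @param rarefaction_g gene count for rarefaction.
#' @param freq_threshold,occupancy_threshold locally-common-allele cutoffs.
#' @param k_range admixture K values to scan (contiguous).
#' @param n_runs EM restarts per K.
#' @param min_vars climate-outlier variable threshold.
#' @param sdm_pct training-presence-threshold percentile.
#' @param pseudo_factor pseudo-absences per presence.
#' @param test_fraction held-out presence fraction for model evaluation.
#' @param reference sample_id of the reference cultivar for the GD map, or
#'   `NULL` to use the simulated cultivar genotype.
#' @param landscape a [landscape_config()] for the simulation stage.
#' @param seed master seed for every stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cell_size = 1 / 6, diameter = 1, min_n = 20,
                            rarefaction_g = 40, freq_threshold = 0.05,
                            occupancy_threshold = 0.25, k_range = 1:10,
                            n_runs = 20, min_vars = 2, sdm_pct = 10,
                            pseudo_factor = 5, test_fraction = 0.2,
                            reference = NULL,
                            landscape = landscape_config(),
                            seed = 42) {
  stopifnot(cell_size > 0, diameter >= cell_size, min_n >= 1,
            rarefaction_g >= 2, freq_threshold >= 0, freq_threshold <= 1,
            occupancy_threshold >= 0, occupancy_threshold <= 1,
            all(diff(k_range) == 1), n_runs >= 2, sdm_pct >= 0,
            sdm_pct <= 100, pseudo_factor >= 1,
            test_fraction > 0, test_fraction < 1)
  structure(list(cell_size = cell_size, diameter = diameter, min_n = min_n,
                 rarefaction_g = rarefaction_g,
                 freq_threshold = freq_threshold,
                 occupancy_threshold = occupancy_threshold,
                 k_range = k_range, n_runs = n_runs, min_vars = min_vars,
                 sdm_pct = sdm_pct, pseudo_factor = pseudo_factor,
                 test_fraction = test_fraction, reference = reference,
                 landscape = landscape, seed = seed),
            class = "pipeline_config")
}

#' Run the full diversity-mapping pipeline
#'
#' Orchestrates every stage on a simulated landscape (or a user-supplied
#' genotype table): simulation, climate-outlier cleaning, circular
#' neighborhood re-sampling, per-cell diversity statistics, admixture
#' clustering with Evanno delta-K, ex situ gap analysis and distribution
#' surface evaluation. All tables and rasters are written under `out_dir`
#' together with a JSON manifest of output files, their MD5 checksums and
#' the fully resolved configuration; identical seeds yield identical
#' manifests.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param table optional [genotype_table] to analyze instead of simulating
#'   one (the truth-dependent summaries are then skipped).
#' @return invisibly, a list with the key in-memory results (`table`,
#'   `assignment`, `stats`, `delta_k`, `gaps`, `sdm`, `coverage`) and the
#'   `manifest` data.frame.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  put <- function(p) { paths[length(paths) + 1] <<- p; p }
  log_msg <- function(...) message("[divmapr] ", ...)

  sim <- NULL
  if (is.null(table)) {
    log_msg("simulating landscape (seed ", config$landscape$seed, ")")
    sim <- simulate_landscape(config$landscape)
    table <- sim$table
    write_genotype_table(table, put(file.path(out_dir, "genotypes.csv")))
    utils::write.csv(sim$truth, put(file.path(out_dir, "truth.csv")),
                     row.names = FALSE)
  }

  extent <- c(range(table$samples$lon), range(table$samples$lat))
  grid <- make_grid(extent, config$cell_size)
  env <- simulate_env_stack(grid, seed = config$seed)

  log_msg("screening coordinates against ", ncol(env$values),
          " climate layers (min_vars = ", config$min_vars, ")")
  report <- flag_climate_outliers(table, env, min_vars = config$min_vars)
  utils::write.csv(report, put(file.path(out_dir, "cleaning_report.csv")),
                   row.names = FALSE)
  cleaned <- clean_dataset(table, report)

  log_msg("re-sampling ", n_samples(cleaned), " trees (cell ",
          signif(config$cell_size, 3), " deg, diameter ",
          config$diameter, " deg)")
  mask <- neighborhood_mask(config$cell_size, config$diameter)
  assignment <- resample_trees(cleaned, grid, mask)
  counts <- cell_counts(assignment)
  write_ascii_raster(counts, put(file.path(out_dir, "tree_counts.asc")))

  reference <- if (!is.null(config$reference))
    reference_genotype(cleaned, config$reference)
  else if (!is.null(sim)) sim$reference

  log_msg("computing per-cell diversity statistics (min_n = ",
          config$min_n, ", g = ", config$rarefaction_g, ")")
  stats <- compute_cell_stats(assignment, cleaned, min_n = config$min_n,
                              rarefaction_g = config$rarefaction_g,
                              reference = reference,
                              freq_threshold = config$freq_threshold,
                              occupancy_threshold = config$occupancy_threshold)
  write_cell_stats(stats, put(file.path(out_dir, "cell_stats.csv")),
                   geojson = put(file.path(out_dir, "cells.geojson")))
  for (col in intersect(c("na", "na_rarefied", "lca", "he", "f", "gd_ref"),
                        names(stats)))
    write_ascii_raster(stats_raster(stats, col),
                       put(file.path(out_dir, paste0(col, ".asc"))))

  log_msg("admixture scan over K = ", min(config$k_range), "..",
          max(config$k_range), " (", config$n_runs, " restarts)")
  scan <- admixture_scan(cleaned, config$k_range, n_runs = config$n_runs,
                         seed = config$seed)
  dk <- evanno_delta_k(scan$loglik, config$k_range)
  utils::write.csv(dk, put(file.path(out_dir, "delta_k.csv")),
                   row.names = FALSE)
  best_k <- attr(dk, "best_k")
  log_msg("delta-K selects K = ", best_k)
  best <- scan$best[[match(best_k, config$k_range)]]
  q_out <- data.frame(sample_id = cleaned$samples$sample_id, best$Q)
  names(q_out)[-1] <- paste0("cluster_", LETTERS[seq_len(best_k)])
  utils::write.csv(q_out, put(file.path(out_dir, "qmatrix.csv")),
                   row.names = FALSE)
  for (k in seq_len(best_k))
    write_ascii_raster(
      map_cluster_probability(assignment, best$Q, k, config$min_n),
      put(file.path(out_dir, sprintf("cluster_%s.asc", LETTERS[k]))))

  log_msg("ex situ gap analysis")
  gaps <- exsitu_missing_alleles(cleaned)
  utils::write.csv(gaps$missing, put(file.path(out_dir, "gap_alleles.csv")),
                   row.names = FALSE)
  write_ascii_raster(missing_allele_richness_map(assignment, cleaned, gaps),
                     put(file.path(out_dir, "missing_allele_richness.asc")))

  log_msg("distribution surface and sampling coverage")
  pres <- cbind(cleaned$samples$lon, cleaned$samples$lat)
  split_idx <- train_test_split(nrow(pres), config$test_fraction,
                                seed = config$seed)
  env_at <- extract_env(env, pres[, 1], pres[, 2])
  model <- envelope_sdm(env_at[split_idx$train, , drop = FALSE])
  surface <- divmap_raster(grid, predict(model, env$values))
  thr <- training_presence_threshold(
    predict(model, env_at[split_idx$train, , drop = FALSE]),
    pct = config$sdm_pct)
  binary <- divmap_raster(grid, as.numeric(surface$values >= thr))
  write_ascii_raster(binary, put(file.path(out_dir, "distribution.asc")))
  pa <- generate_pseudo_absences(pres[split_idx$test, , drop = FALSE],
                                 factor = config$pseudo_factor,
                                 seed = config$seed)
  abs_scores <- predict(model, extract_env(env, pa$lon, pa$lat))
  test_scores <- predict(model, env_at[split_idx$test, , drop = FALSE])
  auc <- evaluate_auc(test_scores, abs_scores)
  kap <- evaluate_kappa(test_scores, abs_scores, threshold = thr)
  # coverage on the extended assignment grid
  binary_ext <- divmap_raster(assignment$grid)
  ids <- cell_index(assignment$grid,
                    cell_center(grid, which(binary$values > 0))[, "lon"],
                    cell_center(grid, which(binary$values > 0))[, "lat"])
  binary_ext$values[ids[!is.na(ids)]] <- 1
  coverage <- sampling_coverage(binary_ext, counts, min_n = config$min_n)
  sdm <- list(threshold = thr, auc = auc, kappa = as.numeric(kap),
              coverage = unclass(coverage)[1:3])
  jsonlite::write_json(sdm, put(file.path(out_dir, "sdm_evaluation.json")),
                       auto_unbox = TRUE, digits = NA)

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(list(config = unclass_deep(config),
                            outputs = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_msg("wrote ", length(paths) + 1, " artifacts to ", out_dir)
  invisible(list(table = cleaned, assignment = assignment, stats = stats,
                 delta_k = dk, best = best, gaps = gaps, sdm = sdm,
                 coverage = coverage, manifest = manifest))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
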