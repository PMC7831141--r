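#' Build a pipeline run configuration
#'
#' Exactly one input source is used: a synthetic `preset` (`"table1"` for
#' the 18-cell condition study, or a scene preset from [scene_preset()]),
#' or `input`, a path to a lifetime dataset written by
#' [write_lifetime_dataset()].
#'
#' @param preset `"table1"`, `"fig5_cells"`, `"fig8_h2o2"`, `"uniform"`,
#'   `"cells_dark_bg"`, or `NULL` when `input` is given.
#' @param input optional dataset path (mutually exclusive with `preset`).
#' @param out_dir output directory (created if missing).
#' @param seed integer top-level seed; every stochastic stage derives its
#'   own seed from it.
#' @param constants a [calibration_constants()] object.
#' @param fit_model `"mono"` or `"bi_fixed"` for scene fitting.
#' @param minkowski_p Minkowski order for condition distances.
#' @param n_samples,dispersion_cv synthetic table generation knobs.
#' @param noise `"poisson"` or `"none"` for scene generation.
#' @param min_counts undefined-pixel intensity threshold for [fit_map()].
#' @return object of class `run_config`.
#' @export
run_config <- function(preset = "table1", input = NULL, out_dir, seed,
                       constants = calibration_constants(),
                       fit_model = "mono", minkowski_p = 1,
                       n_samples = 500, dispersion_cv = 0.08,
                       noise = "poisson", min_counts = 50) {
  if (is.null(preset) == is.null(input)) {
    stop("exactly one of `preset` or `input` must be given", call. = FALSE)
  }
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(preset = preset, input = input, out_dir = out_dir,
                 seed = as.integer(seed), constants = constants,
                 fit_model = fit_model, minkowski_p = minkowski_p,
                 n_samples = n_samples, dispersion_cv = dispersion_cv,
                 noise = noise, min_counts = min_counts),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Recognised fields mirror the arguments of [run_config()]; a nested
#' `calibration` block is passed to [calibration_constants()].
#'
#' @param path config file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  constants <- if (is.null(cfg$calibration)) calibration_constants() else {
    do.call(calibration_constants, cfg$calibration)
  }
  args <- cfg[intersect(names(cfg),
                        setdiff(names(formals(run_config)), "constants"))]
  do.call(run_config, c(args, list(constants = constants)))
}

pipeline_log <- function(.path, .stage, ...) {
  kv <- list(...)
  line <- paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] ", .stage,
                 if (length(kv)) paste0(" ", paste(names(kv), unlist(lapply(kv, format)),
                                                   sep = "=", collapse = " ")))
  cat(line, "\n", file = .path, append = TRUE)
  invisible(line)
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates generation (or loading), statistics, clustering and/or
#' imaging according to the configuration, writing a reproducible artifact
#' bundle into `out_dir`: for condition datasets a condition table,
#' distance matrix, full and per-subset dendrograms (Newick + JSON); for
#' scenes a lifetime map, histogram, bimodal split and oxygen map. Every
#' stage appends its parameters to `log.txt`. Identical config + seed
#' gives identical numeric outputs.
#'
#' @param config a [run_config()] (or path understood by
#'   [read_run_config()]).
#' @return invisibly, a named list of the in-memory artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(config$out_dir, "log.txt")
  cat("", file = log) # truncate
  pipeline_log(log, "start", seed = config$seed,
               source = config$preset %||% config$input)
  scene_presets <- c("fig5_cells", "fig8_h2o2", "uniform", "cells_dark_bg")
  if (!is.null(config$preset) && config$preset %in% scene_presets) {
    run_scene_stage(config, log)
  } else {
    run_condition_stage(config, log)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_condition_stage <- function(config, log) {
  out <- config$out_dir
  if (!is.null(config$input)) {
    ds <- read_lifetime_dataset(config$input)
    pipeline_log(log, "load_dataset", path = config$input, n = nrow(ds))
  } else {
    specs <- table1_specs(n_samples = config$n_samples,
                          dispersion_cv = config$dispersion_cv)
    ds <- generate_dataset(specs, derive_seed(config$seed, "table1"))
    pipeline_log(log, "generate_dataset", cells = length(specs),
                 n_per_cell = config$n_samples,
                 dispersion_cv = config$dispersion_cv,
                 seed = derive_seed(config$seed, "table1"))
  }
  write_lifetime_dataset(ds, file.path(out, "dataset.tsv"))
  tab <- condition_table(ds, config$constants)
  write.table(as.data.frame(tab), file.path(out, "condition_table.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  pipeline_log(log, "condition_table", rows = nrow(tab),
               intercept_a = config$constants$intercept_a,
               slope_b = config$constants$slope_b)
  vecs <- condition_summary_vectors(ds)
  d <- minkowski_distance_matrix(vecs, p = config$minkowski_p)
  write_distance_matrix(d, file.path(out, "distance_matrix.tsv"))
  dend <- ward_d2_linkage(d)
  writeLines(export_newick(dend), file.path(out, "dendrogram_full.nwk"))
  write_dendrogram_json(dend, file.path(out, "dendrogram_full.json"))
  pipeline_log(log, "cluster_full", p = config$minkowski_p,
               leaves = length(dend$labels), method = "ward.D2")
  regime_vecs <- condition_summary_vectors(ds, by = "regime")
  regime_dend <- ward_d2_linkage(
    minkowski_distance_matrix(regime_vecs, p = config$minkowski_p))
  writeLines(export_newick(regime_dend),
             file.path(out, "dendrogram_regimes.nwk"))
  pipeline_log(log, "cluster_regimes", leaves = length(regime_dend$labels))
  subsets <- list()
  for (gb in c("regime", "time_post_admin")) {
    sd_ <- subset_dendrograms(ds, group_by = gb, location_filter = "in",
                              p = config$minkowski_p)
    for (nm in names(sd_)) {
      fn <- file.path(out, sprintf("dendrogram_in_%s_%s.nwk", gb, nm))
      writeLines(export_newick(sd_[[nm]]), fn)
    }
    pipeline_log(log, "cluster_subsets", group_by = gb,
                 levels = length(sd_))
    subsets[[gb]] <- sd_
  }
  pipeline_log(log, "done")
  invisible(list(dataset = ds, condition_table = tab, distance = d,
                 dendrogram = dend, regime_dendrogram = regime_dend,
                 subset_dendrograms = subsets))
}

run_scene_stage <- function(config, log) {
  out <- config$out_dir
  scene <- generate_scene(config$preset, noise = config$noise,
                          seed = derive_seed(config$seed, config$preset))
  pipeline_log(log, "generate_scene", preset = config$preset,
               noise = config$noise,
               seed = derive_seed(config$seed, config$preset))
  map <- fit_map(scene$stack, model = config$fit_model,
                 min_counts = config$min_counts)
  write_grid(map$tau, file.path(out, "lifetime_map.tsv"))
  write_grid(map$intensity, file.path(out, "intensity_map.tsv"))
  pipeline_log(log, "fit_map", model = config$fit_model,
               min_counts = config$min_counts,
               defined = sum(!is.na(map$tau)))
  hist <- map_histogram(map)
  write.table(hist, file.path(out, "histogram.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  split <- split_bimodal(map, constants = config$constants)
  jsonlite::write_json(
    list(threshold = split$threshold,
         lower = split$lower[c("n", "mean_tau", "percent_o2")],
         upper = split$upper[c("n", "mean_tau", "percent_o2")]),
    file.path(out, "bimodal_split.json"), auto_unbox = TRUE, digits = NA)
  pipeline_log(log, "split_bimodal", threshold = split$threshold,
               n_lower = split$lower$n, n_upper = split$upper$n)
  omap <- oxygen_map(map, config$constants)
  write_grid(omap$percent_o2, file.path(out, "oxygen_map.tsv"))
  pipeline_log(log, "oxygen_map",
               below_calibration = sum(omap$below_calibration))
  pipeline_log(log, "done")
  invisible(list(scene = scene, map = map, histogram = hist,
                 split = split, oxygen = omap))
}
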