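#' Default pipeline configuration
#'
#' Nested list of stage parameters for [run_pipeline()]. Every stochastic
#' stage receives a seed derived deterministically from the global `seed`,
#' so a configuration fixes the whole run. Configurations round-trip
#' losslessly through YAML ([read_pipeline_config()] /
#' [write_pipeline_config()]).
#'
#' @param seed global integer seed.
#' @param outdir output directory.
#' @param cohort `"uniform"` or `"periphery_biased"`.
#' @param n_cells cohort size for `simulate`.
#' @param depth_scale periphery bias scale (see [sample_locus_positions()]).
#' @param w density shell width.
#' @param threshold_bp proximity threshold.
#' @param wt_label wild-type genotype label for rate fold changes.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = "periloc_out",
                            cohort = "uniform", n_cells = 50L,
                            depth_scale = 0.05, w = 0.1,
                            threshold_bp = 600, wt_label = "WT") {
  structure(list(seed = as.integer(seed), outdir = outdir, cohort = cohort,
                 n_cells = as.integer(n_cells), depth_scale = depth_scale,
                 w = w, threshold_bp = threshold_bp, wt_label = wt_label),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Simulate a cohort of single-spot nuclei; returns stacks + truths in memory.
simulate_cohort <- function(n_cells, cohort = "uniform", depth_scale = 0.05,
                            seed = 1L, scene_args = list()) {
  pos <- sample_locus_positions(
    n_cells,
    mode = if (cohort == "uniform") "uniform_volume" else "periphery_biased",
    depth_scale = depth_scale, seed = derive_seed(seed, "positions"))
  lapply(seq_len(n_cells), function(i) {
    dir_i <- as.numeric(pos[i, c("x", "y", "z")])
    nrm <- sqrt(sum(dir_i^2))
    dir_i <- if (nrm > 0) dir_i / nrm else c(1, 0, 0)
    args <- modifyList(list(spot_scaled_depth = pos$s[i],
                            spot_direction = dir_i,
                            seed = derive_seed(seed, paste0("cell", i))),
                       scene_args)
    sc <- do.call(synthetic_scene, args)
    c(render_nucleus_stack(sc), list(scene = sc))
  })
}

# Full imaging pipeline on one simulated cohort: localize + reconstruct +
# pool the radial density.
analyze_cohort <- function(cells, w = 0.1, energy = energy_config()) {
  spots <- vector("list", length(cells))
  nuclei <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    st <- cells[[i]]$stack
    fits <- suppressWarnings(localize_spots(st))
    spots[[i]] <- if (length(fits)) fits[[1]] else NULL
    nuclei[[i]] <- tryCatch(suppressWarnings(reconstruct_nucleus(st, energy)),
                            error = function(e) NULL)
  }
  dens <- cohort_density(spots, nuclei, w = w)
  list(spots = spots, nuclei = nuclei, density = dens)
}

#' Run the pipeline end to end
#'
#' Orchestrates the requested stages: `simulate` (synthetic cohort),
#' `localize`, `reconstruct`, `density` (the three imaging stages run
#' in-memory on the simulated cohort), `proximity` (interval inputs) and
#' `rates` (plating-count input); `all` runs
#' simulate/localize/reconstruct/density. Writes per-stage CSVs and a
#' `manifest.json` recording the configuration, derived seeds and per-stage
#' exclusion counts to `config$outdir`. Identical configurations produce
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stage names, or `"all"`.
#' @param features_path,peaks_path interval files for `proximity`.
#' @param counts_path CSV plating table for `rates`.
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all",
                         features_path = NULL, peaks_path = NULL,
                         counts_path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("all", "simulate", "localize", "reconstruct", "density",
             "proximity", "rates")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  imaging <- any(stages %in% c("all", "simulate", "localize", "reconstruct",
                               "density"))
  want_density <- any(stages %in% c("all", "density"))
  if (want_density && !any(stages %in% c("all", "simulate")))
    stop("missing inputs: `density` needs the simulated cohort (run `simulate` or `all`)")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  tables <- list()
  manifest <- list(config = unclass(config),
                   derived_seeds = list(
                     positions = derive_seed(config$seed, "positions")),
                   exclusions = list())

  if (imaging) {
    cells <- simulate_cohort(config$n_cells, config$cohort,
                             config$depth_scale, config$seed)
    truth <- data.frame(
      cell = seq_along(cells),
      s_true = vapply(cells, function(x) x$truth$true_scaled_depth, 0),
      volume_true = vapply(cells, function(x) x$truth$true_volume, 0))
    tables$ground_truth <- truth
    if (identical(stages, "simulate")) {
      # simulate alone materializes the cohort on disk: TIFF stacks with
      # voxel sidecars plus per-cell ground truth JSON
      sdir <- file.path(config$outdir, "stacks")
      dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_along(cells)) {
        write_stack(cells[[i]]$stack,
                    file.path(sdir, sprintf("cell%04d.tif", i)))
        jsonlite::write_json(cells[[i]]$truth,
                             file.path(sdir, sprintf("cell%04d.truth.json", i)),
                             auto_unbox = TRUE, digits = NA)
      }
    }
    if (!identical(stages, "simulate")) {
      ana <- analyze_cohort(cells, w = config$w)
      tables$spots <- spot_table(Filter(Negate(is.null), ana$spots),
                                 which(!vapply(ana$spots, is.null, TRUE)))
      tables$nuclei <- nucleus_table(Filter(Negate(is.null), ana$nuclei),
                                     which(!vapply(ana$nuclei, is.null, TRUE)))
      tables$density <- ana$density$bins
      cellinfo <- attr(ana$density, "cells")
      tables$cell_inclusion <- cellinfo
      manifest$exclusions$imaging <- as.list(table(cellinfo$reason[!cellinfo$included]))
      results$density <- ana$density
      results$cohort <- ana
    }
  }

  if (any(stages %in% c("proximity"))) {
    if (is.null(features_path) || is.null(peaks_path))
      stop("missing inputs: `proximity` needs features_path and peaks_path")
    feats <- read_intervals(features_path)
    pks <- read_intervals(peaks_path)
    pr <- proximity_fraction(feats, pks, config$threshold_bp)
    tables$proximity <- pr$per_feature
    manifest$proximity_summary <- list(n_within = pr$n_within,
                                       n_total = pr$n_total,
                                       fraction = pr$fraction,
                                       threshold_bp = pr$threshold)
    results$proximity <- pr
  }

  if (any(stages %in% c("rates"))) {
    if (is.null(counts_path)) stop("missing inputs: `rates` needs counts_path")
    counts <- read.csv(counts_path, stringsAsFactors = FALSE)
    rt <- rate_table(counts)
    rt <- fold_change_ln(rt, config$wt_label)
    tables$rates <- rt
    manifest$exclusions$rates <- list(zero_rate = sum(!rt$ln_defined))
    results$rates <- rt
  }

  write_results(tables, config$outdir, manifest)
  invisible(results)
}
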