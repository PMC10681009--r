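#' Experiment plan over the simulation grid
#'
#' Encodes a reproducible sweep over push rates, sampling sizes, sampling
#' methods and replicates.  Each run gets a derived seed
#' `base_seed + run index`, so rerunning an identical plan reproduces
#' every output byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param push_rates Numeric vector of push rates.
#' @param sample_sizes Cells per spatial sample.
#' @param sampling_methods Subset of `"random"`, `"centre"`, `"margin"`.
#' @param replicates Replicates per grid point.
#' @param base_seed Base RNG seed.
#' @param n_samples Spatial samples per run.
#' @param target_size,mutation_rate,dimension,push_algorithm,
#'   max_generations Passed to [sim_config()].
#' @param max_inference_samples Per-sample VAF inference is averaged over
#'   at most this many samples per run (compute cap).
#' @return An `experiment_plan`: the run grid plus shared settings.
#' @export
experiment_plan <- function(out_dir, push_rates, sample_sizes = 100,
                            sampling_methods = "random", replicates = 1,
                            base_seed = 1, n_samples = 500,
                            target_size = 2^14, mutation_rate = 10,
                            dimension = 2,
                            push_algorithm = "random_direction",
                            max_generations = 1000,
                            max_inference_samples = 50) {
  grid <- expand.grid(replicate = seq_len(replicates),
                      sampling = sampling_methods,
                      sample_size = sample_sizes,
                      push_rate = push_rates,
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("push_rate", "sample_size", "sampling", "replicate")]
  grid$run <- seq_len(nrow(grid))
  grid$seed <- base_seed + grid$run
  structure(list(grid = grid, out_dir = out_dir, base_seed = base_seed,
                 n_samples = n_samples, target_size = target_size,
                 mutation_rate = mutation_rate, dimension = dimension,
                 push_algorithm = push_algorithm,
                 max_generations = max_generations,
                 max_inference_samples = max_inference_samples),
            class = "experiment_plan")
}

#' Run an experiment plan
#'
#' For every grid point: grow the tumour, draw spatial samples, compute
#' the pairwise Jaccard table and the VAF inference, and write the cell,
#' mutation, sample, Jaccard and inference TSV tables plus a JSON
#' manifest (configuration echo, seed, package version) into
#' `out_dir/run_NNN/`.  A run whose manifest is marked complete is
#' skipped on rerun, making interrupted plans resumable; an unreadable
#' manifest aborts rather than silently recomputing.
#'
#' The inference table holds one row per run: the whole-tumour fit plus
#' the mean per-sample slope over at most `max_inference_samples`
#' samples.
#'
#' @param plan An [experiment_plan()].
#' @param quiet Suppress per-run progress messages.
#' @return Data frame of all inference rows, invisibly; tables on disk.
#' @export
run_experiment <- function(plan, quiet = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  dir.create(plan$out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(plan$grid))
  for (k in seq_len(nrow(plan$grid))) {
    g <- plan$grid[k, ]
    run_dir <- file.path(plan$out_dir, sprintf("run_%03d", g$run))
    manifest_path <- file.path(run_dir, "manifest.json")
    if (file.exists(manifest_path)) {
      man <- tryCatch(jsonlite::read_json(manifest_path),
                      error = function(e) NULL)
      if (is.null(man))
        stop("corrupted manifest, refusing to resume: ", manifest_path,
             call. = FALSE)
      if (isTRUE(man$complete)) {
        if (!quiet) message("skipping completed ", basename(run_dir))
        rows[[k]] <- utils::read.delim(file.path(run_dir,
                                                 "inference.tsv"))
        next
      }
    }
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- sim_config(push_rate = g$push_rate,
                      mutation_rate = plan$mutation_rate,
                      dimension = plan$dimension,
                      target_size = plan$target_size,
                      max_generations = plan$max_generations,
                      push_algorithm = plan$push_algorithm,
                      seed = g$seed)
    if (!quiet)
      message(sprintf("run %d: p = %g, S = %d, %s sampling, seed %d",
                      g$run, g$push_rate, g$sample_size, g$sampling,
                      g$seed))
    tum <- grow_tumour(cfg)
    region <- if (g$sampling == "random") "any" else g$sampling
    ss <- random_square_samples(tum, g$sample_size, plan$n_samples,
                                region = region)
    rec <- jaccard_distance_table(tum, ss)
    whole <- infer_mutation_rate(tum)
    n_inf <- min(plan$max_inference_samples, length(ss$members))
    sample_slopes <- vapply(seq_len(n_inf), function(i)
      infer_mutation_rate(tum, ss$members[[i]])$slope, numeric(1))
    inf <- data.frame(run = g$run, replicate = g$replicate,
                      push_rate = g$push_rate,
                      sample_size = g$sample_size,
                      sampling = g$sampling,
                      slope = whole$slope, intercept = whole$intercept,
                      ks_distance = whole$ks_distance,
                      n_points = whole$n_points,
                      mean_sample_slope = mean(sample_slopes),
                      n_inference_samples = n_inf)
    write_cell_table(tum, file.path(run_dir, "cells.tsv"))
    write_mutation_table(tum, file.path(run_dir, "mutations.tsv"))
    write_sample_table(ss, file.path(run_dir, "samples.tsv"))
    write_jaccard_table(rec, file.path(run_dir, "jaccard.tsv"))
    .write_tsv(inf, file.path(run_dir, "inference.tsv"))
    manifest <- list(run = g$run, seed = g$seed,
                     push_rate = g$push_rate,
                     sample_size = g$sample_size,
                     sampling = g$sampling,
                     mutation_rate = plan$mutation_rate,
                     dimension = plan$dimension,
                     target_size = plan$target_size,
                     push_algorithm = plan$push_algorithm,
                     n_samples = plan$n_samples,
                     generations = tum$generations,
                     n_cells = tum$n_alive,
                     version = as.character(packageVersion("spatialith")),
                     complete = TRUE)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    rows[[k]] <- inf
  }
  invisible(do.call(rbind, rows))
}
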