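#' Validate a simulation scenario configuration
#'
#' Bundles founder, demography, migration and selection settings for a
#' replicated scenario run.  Replicate seeds are derived deterministically
#' as `seed + replicate index`, so a scenario is exactly reproducible from
#' its configuration.
#'
#' @param label scenario label (unique within a grid).
#' @param n_founders founder haplotype count `F` (both 100 and 105 appear
#'   in common experimental setups; 100 is the default here).
#' @param n_gametes gametes per deme `N`.
#' @param n_demes deme count `D`.
#' @param generations generations `G`.
#' @param migrants migration events per generation `M`.
#' @param replicates number of replicate runs.
#' @param seed base seed.
#' @param selection `NULL`, a `qtl_config`, or a `locus_selection_config`.
#' @param n_sites panel sites `L`.
#' @param target_het founder-panel calibration target.
#' @param spectrum founder frequency spectrum (see
#'   [generate_founder_panel()]).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(label, n_founders = 100, n_gametes = 2000,
                            n_demes = 5, generations = 800, migrants = 0,
                            replicates = 20, seed = 1, selection = NULL,
                            n_sites = 10000, target_het = 0.32,
                            spectrum = "neutral") {
  stopifnot(n_founders >= 2, n_gametes >= 1, n_demes >= 1,
            generations >= 0, migrants >= 0, replicates >= 1)
  if (!is.null(selection) &&
      !inherits(selection, c("qtl_config", "locus_selection_config")))
    stop("selection must be NULL, a qtl_config or a locus_selection_config")
  structure(list(
    label = label, n_founders = as.integer(n_founders),
    n_gametes = as.integer(n_gametes), n_demes = as.integer(n_demes),
    generations = as.integer(generations), migrants = as.integer(migrants),
    replicates = as.integer(replicates), seed = as.integer(seed),
    selection = selection, n_sites = as.integer(n_sites),
    target_het = target_het, spectrum = spectrum
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario_config:", x$label, "- F =", x$n_founders, "N =",
      x$n_gametes, "D =", x$n_demes, "G =", x$generations, "M =",
      x$migrants, ",", x$replicates, "replicates\n")
  invisible(x)
}

#' Run a replicated scenario and aggregate its summary row
#'
#' Generates the founder panel once from the base seed (the same founders
#' underlie every replicate, as when a fixed line panel founds each run),
#' installs QTL states if configured, then runs `replicates` seeded
#' simulations and aggregates their summary statistics.
#'
#' @param config a [scenario_config()].
#' @param window_size spatial-variance window (bp).
#' @param keep_freqs retain each replicate's frequency matrix (memory!).
#' @param panel optionally, a pre-built `founder_panel` to reuse across
#'   scenarios (e.g. across migration rates within a family).
#' @return A list of class `scenario_run`: `summary` (one-row data frame),
#'   `replicates` (per-replicate rows), `panel`, `config`, `seeds`, and
#'   optionally `freqs` (list of `L x D` matrices).
#' @export
run_scenario <- function(config, window_size = 5e4, keep_freqs = FALSE,
                         panel = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(panel)) {
    panel <- generate_founder_panel(config$n_founders, config$n_sites,
                                    config$target_het, config$spectrum,
                                    seed = config$seed)
    if (inherits(config$selection, "qtl_config"))
      panel <- assign_qtl_states(panel, config$selection)
  }
  seeds <- config$seed + seq_len(config$replicates)
  rows <- vector("list", config$replicates)
  freqs <- if (keep_freqs) vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    run <- run_simulation(panel, config$n_demes, config$n_gametes,
                          config$generations, config$migrants,
                          config$selection, seed = seeds[r])
    rows[[r]] <- summarize_freqs(run$freqs, panel$positions_bp,
                                 window_size)
    if (keep_freqs) freqs[[r]] <- run$freqs
  }
  reps <- do.call(rbind, rows)
  reps$replicate <- seq_len(config$replicates)
  out <- list(summary = aggregate_scenario(reps, config$label),
              replicates = reps, panel = panel, config = config,
              seeds = seeds)
  if (keep_freqs) out$freqs <- freqs
  class(out) <- "scenario_run"
  out
}

#' @export
print.scenario_run <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Write a JSON run manifest
#'
#' Records the configuration, derived replicate seeds and package version
#' of a scenario run, for provenance alongside exported tables.
#'
#' @param run a `scenario_run`.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_run_manifest <- function(run, path) {
  cfg <- run$config
  cfg$selection <- if (is.null(cfg$selection)) NULL
    else unclass(cfg$selection)
  manifest <- list(
    label = run$config$label,
    config = unclass(cfg),
    seeds = run$seeds,
    package_version = as.character(utils::packageVersion("ersim")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Neutral-plus-migration scenario family
#'
#' The neutral rows of the migration scenario grid: drift only, at the
#' requested migration rates.
#'
#' @param M_values migration rates to cover.
#' @param ... passed to [scenario_config()].
#' @return List of `scenario_config`.
#' @export
scenario_grid_neutral <- function(M_values = c(0, 1, 5), ...) {
  lapply(M_values, function(m)
    scenario_config(label = paste0("neutral_M", m), migrants = m, ...))
}

#' Optimizing-selection scenario family
#'
#' QTL scenarios crossing QTL number (3/10/20, shipped effect presets),
#' starting frequency (0.05/0.5) and migration rate (0/1/5).
#'
#' @param Q_values QTL counts.
#' @param start_freqs starting frequencies.
#' @param M_values migration rates.
#' @param n_sites panel sites (QTL are spaced over these).
#' @param ... passed to [scenario_config()].
#' @return List of `scenario_config`.
#' @export
scenario_grid_qtl <- function(Q_values = c(3, 10, 20),
                              start_freqs = c(0.05, 0.5),
                              M_values = c(0, 1, 5),
                              n_sites = 10000, ...) {
  grid <- expand.grid(Q = Q_values, f = start_freqs, M = M_values)
  lapply(seq_len(nrow(grid)), function(i) {
    q <- grid$Q[i]; f0 <- grid$f[i]; m <- grid$M[i]
    scenario_config(
      label = sprintf("qtl%d_f%s_M%d", q, format(f0), m),
      migrants = m, n_sites = n_sites,
      selection = make_qtl_config(q, f0, n_sites = n_sites), ...)
  })
}

#' Export per-deme mpileup inputs for sweep-scan tools
#'
#' Converts a completed run's exact frequencies into pool-seq reads with
#' the configured depth and error models and writes one mpileup file per
#' deme, plus a JSON manifest of the export parameters.
#'
#' @param run a `wf_run` with `freqs`, or a frequency matrix.
#' @param positions_bp site positions (taken from `panel`).
#' @param dir output directory (created if needed).
#' @param mean_depth,depth_dispersion,error_rate see
#'   [sample_pool_reads()].
#' @param seed optional integer seed.
#' @param prefix file name prefix.
#' @return Invisibly, the mpileup file paths.
#' @export
export_sweepscan_inputs <- function(run, positions_bp, dir,
                                    mean_depth = 60,
                                    depth_dispersion = 21.8,
                                    error_rate = 0.001, seed = NULL,
                                    prefix = "deme") {
  freqs <- if (inherits(run, "wf_run")) run$freqs else run
  if (is.null(freqs) || !is.numeric(as.matrix(freqs)) ||
      length(freqs) == 0)
    stop("run has no frequency matrix; rerun with project = TRUE")
  freqs <- as.matrix(freqs)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- sample_pool_reads(freqs, positions_bp, mean_depth,
                           depth_dispersion, error_rate, seed = seed)
  paths <- vapply(seq_len(ncol(freqs)), function(p) {
    path <- file.path(dir, sprintf("%s%d.mpileup", prefix, p))
    write_mpileup(tab, path, population = p)
    path
  }, "")
  jsonlite::write_json(
    list(mean_depth = mean_depth, depth_dispersion = depth_dispersion,
         error_rate = error_rate, populations = length(paths)),
    file.path(dir, "export_manifest.json"), auto_unbox = TRUE)
  invisible(paths)
}
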