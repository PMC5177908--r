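#' Run a replicated-deme Wright-Fisher simulation
#'
#' Founds `n_demes` demes of `n_gametes` single-founder gametes each from
#' the panel, then advances `generations` generations of the
#' founder-segment engine, with optional selection and one-way island
#' migration (`migrants` replacement events per generation on the pooled
#' gametes).  Runs in compiled code but consumes R's RNG stream in the
#' documented draw order, so results are reproducible from `seed` and can
#' be replayed by pure-R reference implementations.
#'
#' Selection:
#' \describe{
#'   \item{`NULL`}{neutral drift (gamete mode).}
#'   \item{[make_qtl_config()]}{optimizing (Gaussian) selection on a
#'     quantitative trait, gamete mode; QTL states must have been installed
#'     with [assign_qtl_states()].  The optimum is placed
#'     `optimum_shift * sqrt(vp0)` above the expected starting mean
#'     phenotype.}
#'   \item{[locus_selection_config()]}{multiplicative per-locus fitness on
#'     diploids (fecundity selection), diploid mode with Poisson
#'     multi-crossover meioses on the half (sex-averaged) map.}
#' }
#'
#' @param panel a `founder_panel`.
#' @param n_demes number of demes `D`.
#' @param n_gametes gametes per deme `N`.
#' @param generations generations `G`.
#' @param migrants migration events per generation `M`.
#' @param selection `NULL`, a `qtl_config`, or a `locus_selection_config`.
#' @param seed optional integer seed.
#' @param crossover_model gamete-mode meiosis: `"single"` (one potential
#'   crossover per meiosis, the default) or `"poisson"` (Poisson number of
#'   crossovers at rate `map_length` Morgans).
#' @param log_trajectory record per-generation mean phenotype, polygenic
#'   mean and mean fitness (QTL mode only).
#' @param project compute exact allele frequencies at the end.
#' @return An object of class `wf_run`: final gametes (`founder_states`,
#'   `breakpoints`, flat deme-major lists), `freqs` (`L x D` matrix if
#'   `project`), dimensions, `polygenic_mean`, optional trajectories.
#' @export
run_simulation <- function(panel, n_demes = 5, n_gametes = 2000,
                           generations = 800, migrants = 0,
                           selection = NULL, seed = NULL,
                           crossover_model = c("single", "poisson"),
                           log_trajectory = FALSE, project = TRUE) {
  crossover_model <- match.arg(crossover_model)
  if (!is.null(seed)) set.seed(seed)
  F <- nrow(panel$alleles)
  map_len <- panel$map$total_cM / 100
  D <- as.integer(n_demes); N <- as.integer(n_gametes)
  G <- as.integer(generations); M <- as.integer(migrants)
  stopifnot(D >= 1, N >= 1, G >= 0, M >= 0)

  # found demes: N founder indices per deme, deme-major order
  init_states <- vector("list", D * N)
  init_breaks <- rep(list(numeric(0)), D * N)
  for (d in seq_len(D)) {
    idx <- sample.int(F, N, replace = TRUE)
    for (n in seq_len(N)) init_states[[(d - 1) * N + n]] <- idx[n]
  }

  if (inherits(selection, "qtl_config")) {
    opt <- sum(selection$start_freqs * selection$effects) +
      selection$polygenic_mean +
      selection$optimum_shift * sqrt(selection$vp0)
    sel <- list(
      qtl_pos = panel$positions_M[selection$positions],
      qtl_alleles = panel$alleles[, selection$positions, drop = FALSE],
      effects = selection$effects,
      va_poly = selection$va_poly, ve = selection$ve,
      variance_fitness = selection$variance_fitness,
      optimum = opt, polygenic_mean = selection$polygenic_mean)
    res <- cpp_wf_run(init_states, init_breaks, map_len, D, N, G, M, sel,
                      crossover_model == "poisson", log_trajectory)
  } else if (inherits(selection, "locus_selection_config")) {
    res <- cpp_wf_run_diploid(
      init_states, init_breaks, map_len / 2, D, N, G, M,
      panel$positions_M[selection$site] / 2,
      panel$alleles[, selection$site, drop = FALSE],
      selection$s, selection$h, selection$favored)
  } else if (is.null(selection)) {
    res <- cpp_wf_run(init_states, init_breaks, map_len, D, N, G, M,
                      list(), crossover_model == "poisson", FALSE)
  } else stop("unrecognized selection configuration")

  run <- structure(list(
    founder_states = res$founder_states,
    breakpoints = res$breakpoints,
    D = D, N = N, generations = G, migrants = M,
    map_length_morgans = map_len,
    selection = selection,
    polygenic_mean = res$polygenic_mean,
    mean_breakpoints = cpp_mean_breakpoints(res$breakpoints)
  ), class = "wf_run")
  if (log_trajectory && !is.null(res$mean_phenotype)) {
    run$mean_phenotype <- res$mean_phenotype
    run$polygenic_mean_traj <- res$polygenic_mean_traj
    run$mean_fitness <- res$mean_fitness
  }
  if (project) {
    pos <- panel$positions_M
    if (inherits(selection, "locus_selection_config")) pos <- pos / 2
    run$freqs <- cpp_project_freqs(res$founder_states, res$breakpoints,
                                   pos, panel$alleles, D, N)
  }
  run
}

#' @export
print.wf_run <- function(x, ...) {
  cat("wf_run:", x$D, "demes x", x$N, "gametes,", x$generations,
      "generations, M =", x$migrants,
      "; mean breakpoints/gamete =", round(x$mean_breakpoints, 1), "\n")
  invisible(x)
}

#' Convert a `wf_run` back to a `metapopulation`
#'
#' @param run a [run_simulation()] result.
#' @return A `metapopulation` of `gamete` objects.
#' @export
as_metapopulation <- function(run) {
  demes <- lapply(seq_len(run$D), function(d) {
    lapply(seq_len(run$N), function(n) {
      i <- (d - 1) * run$N + n
      new_gamete(run$founder_states[[i]], run$breakpoints[[i]])
    })
  })
  new_metapopulation(demes, run$generations, run$map_length_morgans)
}

#' Dump gametes to a columnar TSV checkpoint
#'
#' One row per segment: `deme`, `gamete`, `segment`, `founder`, `end_M`
#' (the segment's right edge; the map length for the final segment).
#'
#' @param run a `wf_run` (or a `metapopulation`).
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_gametes_tsv <- function(run, path) {
  if (inherits(run, "metapopulation")) {
    flat <- do.call(c, run$demes)
    states <- lapply(flat, `[[`, "founder_states")
    breaks <- lapply(flat, `[[`, "breakpoints")
    D <- run$D; N <- run$N; L <- run$map_length_morgans
  } else {
    states <- run$founder_states; breaks <- run$breakpoints
    D <- run$D; N <- run$N; L <- run$map_length_morgans
  }
  rows <- lapply(seq_along(states), function(i) {
    s <- states[[i]]; b <- breaks[[i]]
    data.frame(deme = (i - 1) %/% N + 1, gamete = (i - 1) %% N + 1,
               segment = seq_along(s), founder = s, end_M = c(b, L))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an allele-frequency matrix as a site x deme TSV
#'
#' @param freqs `L x D` matrix (e.g. `run$freqs`).
#' @param positions_bp site physical positions.
#' @param path output TSV path.
#' @param chrom chromosome label.
#' @return Invisibly, `path`.
#' @export
write_freqs_tsv <- function(freqs, positions_bp, path, chrom = "3R") {
  df <- data.frame(chrom = chrom, pos = positions_bp)
  colnames(freqs) <- paste0("deme", seq_len(ncol(freqs)))
  utils::write.table(cbind(df, freqs), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
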