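#' Per-locus selection configuration
#'
#' Encodes directional or overdominant selection at individual sites with
#' genotype fitnesses `w11 = 1`, `w12 = 1 + h*s`, `w22 = 1 + s` (genotype
#' classes counted in copies of the favored allele), multiplicative across
#' loci.
#'
#' @param sites panel site indices under selection.
#' @param s selection coefficients (recycled).
#' @param h dominance coefficients (recycled): `h = 0` favored allele
#'   recessive-acting on `w12`, `h = 1` dominant, `h = 0.5` codominant,
#'   `h > 1` overdominant.
#' @param favored favored allele (0 or 1, recycled).
#' @return An object of class `locus_selection_config`: a data frame with
#'   columns `site`, `s`, `h`, `favored`.
#' @export
locus_selection_config <- function(sites, s, h = 0.5, favored = 1L) {
  loci <- data.frame(site = as.integer(sites),
                     s = rep_len(s, length(sites)),
                     h = rep_len(h, length(sites)),
                     favored = as.integer(rep_len(favored, length(sites))))
  if (any(1 + loci$s <= 0) || any(1 + loci$h * loci$s <= 0))
    stop("selection coefficients give non-positive genotype fitness ",
         "(need s > -1 and h*s > -1)")
  if (!all(loci$favored %in% c(0L, 1L)))
    stop("favored allele must be 0 or 1")
  class(loci) <- c("locus_selection_config", "data.frame")
  loci
}

#' Multiplicative per-locus fitness
#'
#' Maps per-individual counts of the favored allele at each selected locus
#' to fitness `prod_l w(count_l)` with `w(0) = 1`, `w(1) = 1 + h*s`,
#' `w(2) = 1 + s`.
#'
#' @param genotype_counts integer matrix (individuals x loci) or vector of
#'   favored-allele counts in `{0, 1, 2}`.
#' @param config a [locus_selection_config()].
#' @return Numeric vector of fitnesses, one per individual.
#' @examples
#' cfg <- locus_selection_config(1, s = 0.1, h = 0.5)
#' locus_fitness(matrix(0:2, ncol = 1), cfg)  # 1, 1.05, 1.1
#' @export
locus_fitness <- function(genotype_counts, config) {
  m <- if (is.matrix(genotype_counts)) genotype_counts
       else matrix(genotype_counts, ncol = max(1, nrow(config)))
  if (nrow(config) == 0) return(rep(1, nrow(m)))
  if (ncol(m) != nrow(config))
    stop("genotype_counts must have one column per configured locus")
  if (!all(m %in% 0:2)) stop("genotype counts must be 0, 1 or 2")
  fit <- rep(1, nrow(m))
  for (l in seq_len(nrow(config))) {
    wl <- c(1, 1 + config$h[l] * config$s[l], 1 + config$s[l])
    fit <- fit * wl[m[, l] + 1L]
  }
  fit
}

#' Overdominant selection configuration
#'
#' With `h > 1` the heterozygote is fittest (`w12 = 1 + h*s` exceeds both
#' `w11 = 1` and `w22 = 1 + s`), which maintains an interior equilibrium at
#' favored-allele frequency
#' `(w12 - w11) / ((w12 - w11) + (w12 - w22)) = h / (2h - 1)`.
#'
#' @param sites panel site indices.
#' @param s selection coefficient(s), `s > 0`.
#' @param h_overdominant dominance coefficient, must exceed 1.
#' @return A `locus_selection_config` with attribute `equilibrium_freq`.
#' @examples
#' cfg <- make_overdominant_config(1, s = 0.1, h_overdominant = 2)
#' attr(cfg, "equilibrium_freq")  # 2/3
#' @export
make_overdominant_config <- function(sites, s, h_overdominant = 2) {
  if (any(h_overdominant <= 1))
    stop("h must exceed 1 for overdominance (heterozygote advantage)")
  if (any(s <= 0)) stop("overdominant s must be positive")
  cfg <- locus_selection_config(sites, s, h_overdominant, favored = 1L)
  attr(cfg, "equilibrium_freq") <- h_overdominant / (2 * h_overdominant - 1)
  cfg
}

#' Preset QTL effect-size vectors
#'
#' The effect-size vectors used for the 3-, 10- and 20-QTL optimizing
#' selection scenarios; the sum of squared effects is held (approximately)
#' constant across the three so the trait heritability does not change with
#' QTL number.
#'
#' @param Q 3, 10 or 20.
#' @return Numeric effect-size vector of length `Q`.
#' @export
qtl_effect_preset <- function(Q) {
  switch(as.character(Q),
    "3"  = c(1, 2, 2),
    "10" = c(1, 1, 1, 1, 1, 1, 1, 1, 0.71, 0.71),
    "20" = c(rep(0.71, 16), rep(0.5, 4)),
    stop("no shipped effect preset for Q = ", Q,
         "; supply `effects` explicitly"))
}

#' Quantitative-trait (optimizing selection) configuration
#'
#' Sets up `Q` additively acting QTL evenly spaced across the arm's sites,
#' a Gaussian polygenic background, environmental noise, and a shifted
#' phenotypic optimum.  The default variance partition at generation zero
#' is 12% QTL, 38% polygenic, 50% environmental (total phenotypic variance
#' 1); with `rescale_to_h2 = TRUE` (default) effect sizes are multiplied by
#' the constant `c` such that `sum_i p_i q_i (c a_i)^2` equals the target
#' QTL variance at the nominal starting frequencies (`p q a^2` per gamete;
#' the per-diploid-individual equivalent is `2 p q a^2`).
#'
#' @param Q number of QTL; 3, 10 and 20 have shipped effect presets.
#' @param start_freq starting allele frequency for every QTL (0.05 or 0.5
#'   in the default scenario grids), or a length-`Q` vector.
#' @param n_sites total number of panel sites the QTL are spaced over.
#' @param rescale_to_h2 rescale effects to hit `h2_qtl` (default TRUE).
#' @param effects explicit effect sizes (required for other `Q`).
#' @param h2_qtl target QTL variance fraction at generation 0.
#' @param va_poly polygenic additive variance.
#' @param ve environmental variance.
#' @param vp0 total phenotypic variance at generation 0.
#' @param optimum_shift optimum displacement in phenotypic SD units.
#' @param variance_fitness width parameter of the Gaussian fitness
#'   function.
#' @return An object of class `qtl_config`.
#' @examples
#' make_qtl_config(3, 0.5, n_sites = 1000)
#' @export
make_qtl_config <- function(Q, start_freq = 0.5, n_sites,
                            rescale_to_h2 = TRUE, effects = NULL,
                            h2_qtl = 0.12, va_poly = 0.38, ve = 0.5,
                            vp0 = 1.0, optimum_shift = 15,
                            variance_fitness = 12) {
  if (is.null(effects)) effects <- qtl_effect_preset(Q)
  if (length(effects) != Q) stop("need one effect size per QTL")
  start_freq <- rep_len(start_freq, Q)
  if (any(start_freq <= 0 | start_freq >= 1))
    stop("start frequencies must lie strictly inside (0, 1)")
  stopifnot(va_poly > 0, ve > 0, variance_fitness > 0)
  positions <- floor(seq_len(Q) * n_sites / (Q + 1))
  positions <- pmax(positions, 1L)
  scale <- 1
  if (rescale_to_h2) {
    v_raw <- sum(start_freq * (1 - start_freq) * effects^2)
    scale <- sqrt(h2_qtl * vp0 / v_raw)
  }
  structure(list(
    Q = Q, positions = as.integer(positions), effects = effects * scale,
    raw_effects = effects, start_freqs = start_freq,
    rescale_to_h2 = rescale_to_h2,
    va_poly = va_poly, ve = ve, vp0 = vp0,
    optimum_shift = optimum_shift, variance_fitness = variance_fitness,
    polygenic_mean = 0
  ), class = "qtl_config")
}

#' @export
print.qtl_config <- function(x, ...) {
  cat("qtl_config:", x$Q, "QTL, start freq",
      paste(unique(x$start_freqs), collapse = "/"),
      "; effects", paste(signif(x$effects, 3), collapse = ", "), "\n")
  cat("  Va_qtl =", signif(sum(x$start_freqs * (1 - x$start_freqs) *
                                 x$effects^2), 4),
      " Va_poly =", x$va_poly, " Ve =", x$ve,
      " optimum shift =", x$optimum_shift, "SD\n")
  invisible(x)
}

#' Assign QTL founder states to a panel
#'
#' Overwrites the panel alleles at the configured QTL sites with Bernoulli
#' draws at the configured starting frequencies (binomial sampling of QTL
#' states across founders), redrawing monomorphic outcomes so each QTL
#' segregates in the panel.
#'
#' @param panel a `founder_panel`.
#' @param config a [make_qtl_config()] object whose positions index this
#'   panel's sites.
#' @param seed optional integer seed.
#' @return The panel with QTL states installed and `site_freqs` refreshed.
#' @export
assign_qtl_states <- function(panel, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  F <- nrow(panel$alleles)
  for (k in seq_along(config$positions)) {
    j <- config$positions[k]
    repeat {
      a <- as.integer(stats::runif(F) < config$start_freqs[k])
      if (sum(a) > 0 && sum(a) < F) break
    }
    panel$alleles[, j] <- a
  }
  panel$site_freqs <- colMeans(panel$alleles)
  panel
}

#' Per-gamete phenotypes under the QTL model
#'
#' Phenotype of gamete `i` is the sum of its QTL allelic effects, plus a
#' Gaussian polygenic deviate (variance `va_poly`), plus a Gaussian
#' environmental deviate (variance `ve`), plus the current polygenic mean
#' of the population.  Deviates are drawn per gamete in (polygenic,
#' environmental) order.
#'
#' @param gametes list of `gamete` objects.
#' @param panel the `founder_panel` with QTL states installed.
#' @param config a `qtl_config`.
#' @return Numeric phenotype vector.
#' @export
qtl_phenotypes <- function(gametes, panel, config) {
  pos <- panel$positions_M[config$positions]
  g <- vapply(gametes, function(gm) {
    f <- vapply(pos, function(p) segment_founder_at(gm, p), integer(1))
    sum(config$effects * panel$alleles[cbind(f, config$positions)])
  }, numeric(1))
  z <- matrix(stats::rnorm(2 * length(gametes)), nrow = 2)
  g + config$polygenic_mean +
    z[1, ] * sqrt(config$va_poly) + z[2, ] * sqrt(config$ve)
}

#' Gaussian stabilizing-selection weights
#'
#' Selection weights proportional to
#' `exp(-(phenotype - optimum)^2 / (2 * variance_fitness))`, normalized to
#' sum to one.  (The raw squared deviation alone would increase with
#' distance from the optimum; the standard Gaussian fitness function places
#' it inside a negative exponential.)
#'
#' @param phenotypes numeric vector.
#' @param optimum phenotypic optimum.
#' @param variance_fitness width of the fitness function (> 0).
#' @return Normalized weights summing to 1.
#' @export
gaussian_fitness <- function(phenotypes, optimum, variance_fitness) {
  stopifnot(variance_fitness > 0)
  w <- exp(-(phenotypes - optimum)^2 / (2 * variance_fitness))
  if (sum(w) <= 0 || !is.finite(sum(w)))
    stop("all fitness weights underflow to zero: ",
         "population too far from the optimum")
  w / sum(w)
}

#' Breeder's-equation update of the polygenic mean
#'
#' The untracked polygenic background responds to selection as
#' `R = h2_poly * S`, with `h2_poly = va_poly / (va_poly + ve)` and `S` the
#' observed selective differential (mean phenotype of the individuals
#' chosen to reproduce minus the population mean phenotype).
#'
#' @param polygenic_mean current background mean.
#' @param S observed selective differential.
#' @param va_poly polygenic additive variance.
#' @param ve environmental variance.
#' @return Updated polygenic mean.
#' @examples
#' breeders_update(0, S = 1, va_poly = 0.38, ve = 0.5)  # 0.4318...
#' @export
breeders_update <- function(polygenic_mean, S, va_poly, ve) {
  stopifnot(va_poly + ve > 0)
  polygenic_mean + S * va_poly / (va_poly + ve)
}
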