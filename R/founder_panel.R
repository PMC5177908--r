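#' Generate a synthetic founder haplotype panel
#'
#' Emulates a panel of inbred-line haplotypes (e.g. DGRP chromosome-3R
#' lines) used to found laboratory populations: `F` binary haplotypes over
#' `L` polymorphic sites on one chromosome arm, with a genetic map and a
#' per-site frequency spectrum rescaled so that the realized panel mean
#' heterozygosity (mean of `2pq` over sites) hits a calibration target.
#'
#' Spectra:
#' \describe{
#'   \item{`"neutral"`}{density proportional to `1/x`, the standing neutral
#'     site-frequency spectrum, truncated to `[a, 1-a]` with `a` solved so
#'     the expected `2pq` equals `target_het` (after the finite-panel
#'     correction factor `1 - 1/F`).}
#'   \item{`"uniform"`}{frequencies uniform on `[a, 1-a]`, `a` solved the
#'     same way.}
#'   \item{`"beta"`}{`Beta(shape1, shape2)` frequencies, rescaled linearly
#'     toward 0.5 to meet the target.}
#' }
#' Alleles are drawn per haplotype per site at the sampled frequency;
#' monomorphic outcomes are redrawn so every site is polymorphic in the
#' panel.
#'
#' @param n_haplotypes number of founder haplotypes `F` (>= 2).
#' @param n_sites number of polymorphic sites `L`.
#' @param target_het calibration target for panel mean `2pq`, in (0, 0.5].
#' @param spectrum one of `"neutral"`, `"uniform"`, `"beta"`.
#' @param map a [build_genetic_map()] object; default: uniform 63 cM map.
#' @param seed optional integer seed (panels are reproducible given a seed).
#' @param shape1,shape2 Beta spectrum parameters.
#' @return An object of class `founder_panel`: `alleles` (`F x L` 0/1
#'   integer matrix), `positions_bp`, `positions_M` (genetic positions in
#'   Morgans), `map`, `site_freqs` (realized alternate-allele frequencies).
#' @examples
#' p <- generate_founder_panel(20, 500, target_het = 0.32, seed = 1)
#' mean(2 * p$site_freqs * (1 - p$site_freqs))
#' @export
generate_founder_panel <- function(n_haplotypes = 100, n_sites = 10000,
                                   target_het = 0.32,
                                   spectrum = c("neutral", "uniform", "beta"),
                                   map = NULL, seed = NULL,
                                   shape1 = 0.5, shape2 = 0.5) {
  spectrum <- match.arg(spectrum)
  if (n_haplotypes < 2) stop("need at least 2 founder haplotypes")
  if (target_het <= 0 || target_het > 0.5)
    stop("target_het must be in (0, 0.5]: maximum achievable 2pq is 0.5")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(map)) map <- uniform_genetic_map()
  F <- as.integer(n_haplotypes)
  L <- as.integer(n_sites)

  # expected 2pq of the sampled panel is E[2x(1-x)] * (1 - 1/F); aim the
  # continuous spectrum at the inflated target so the realized panel lands
  # on target_het
  xt <- min(target_het / (1 - 1 / F), 0.4999)
  p <- draw_spectrum(spectrum, L, xt, shape1, shape2)

  alleles <- matrix(0L, nrow = F, ncol = L)
  for (j in seq_len(L)) {
    repeat {
      a <- as.integer(stats::runif(F) < p[j])
      s <- sum(a)
      if (s > 0L && s < F) break
    }
    alleles[, j] <- a
  }

  positions_bp <- sort(sample.int(map$chrom_end_bp, L)) - 1L # 0-based coords
  pos_cM <- bp_to_cM(map, positions_bp)

  structure(list(
    alleles      = alleles,
    positions_bp = positions_bp,
    positions_M  = pos_cM / 100,
    map          = map,
    site_freqs   = colMeans(alleles)
  ), class = "founder_panel")
}

# Sample L frequencies from the chosen spectrum with mean 2x(1-x) = target.
draw_spectrum <- function(spectrum, L, target, shape1, shape2) {
  switch(spectrum,
    neutral = {
      # density 1/x on [a, 1-a]: E[2x(1-x)] = (1-2a)/log((1-a)/a)
      f <- function(a) (1 - 2 * a) / log((1 - a) / a) - target
      a <- stats::uniroot(f, c(1e-8, 0.499))$root
      u <- stats::runif(L)
      a * ((1 - a) / a)^u   # inverse-CDF of truncated 1/x
    },
    uniform = {
      # uniform on [0.5 - k/2, 0.5 + k/2]: E[2x(1-x)] = 1/2 - k^2/6, which
      # spans (1/3, 1/2] for k in [0, 1) -- lower targets are unreachable
      # by range rescaling of a uniform spectrum
      if (target < 1 / 3)
        stop("uniform spectrum cannot be rescaled below mean het 1/3; ",
             "use the neutral or beta spectrum for target_het ", target)
      k <- sqrt(6 * (0.5 - target))
      stats::runif(L, 0.5 - k / 2, 0.5 + k / 2)
    },
    beta = {
      x <- stats::rbeta(L, shape1, shape2)
      # rescale around 0.5 (x' = 0.5 + c*(x-0.5)): c < 1 shrinks toward 0.5
      # and raises het, c > 1 widens and lowers it, capped at the unit range
      cmax <- 0.5 / max(abs(x - 0.5))
      g <- function(cc) mean(2 * (0.5 + cc * (x - 0.5)) *
                               (0.5 - cc * (x - 0.5))) - target
      if (g(cmax) > 0)
        stop("target_het ", target, " below the reach of this beta spectrum")
      cc <- stats::uniroot(g, c(0, cmax))$root
      x <- 0.5 + cc * (x - 0.5)
      pmin(pmax(x, 1e-6), 1 - 1e-6)
    })
}

#' @export
print.founder_panel <- function(x, ...) {
  het <- mean(2 * x$site_freqs * (1 - x$site_freqs))
  cat("founder_panel:", nrow(x$alleles), "haplotypes x",
      ncol(x$alleles), "sites; mean 2pq =", round(het, 4), "\n")
  invisible(x)
}

#' Panel mean heterozygosity
#'
#' Mean of `2pq` over panel sites.
#' @param panel a `founder_panel`.
#' @return Scalar mean heterozygosity.
#' @export
panel_heterozygosity <- function(panel) {
  mean(2 * panel$site_freqs * (1 - panel$site_freqs))
}

#' Expand a founder panel into a starting gamete pool
#'
#' Each starting gamete is a single unrecombined founder chromosome drawn
#' uniformly with replacement from the panel, mirroring the expansion of a
#' line panel to the census size of an experimental population.
#'
#' @param panel a `founder_panel` (or a founder count, for engine-level use).
#' @param n_gametes pool size `N`.
#' @param seed optional integer seed.
#' @return A list of [new_gamete()] objects of length `n_gametes`.
#' @export
expand_panel <- function(panel, n_gametes, seed = NULL) {
  F <- if (inherits(panel, "founder_panel")) nrow(panel$alleles)
       else as.integer(panel)
  if (is.na(F) || F < 1) stop("empty founder panel")
  if (n_gametes < 1) stop("n_gametes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(F, n_gametes, replace = TRUE)
  lapply(idx, function(i) new_gamete(i, numeric(0)))
}

#' Write a founder panel to plain TSV files
#'
#' Writes `<prefix>.haplotypes.tsv` (haplotype x site 0/1 matrix) and
#' `<prefix>.sites.tsv` (chrom, pos_bp, cM columns).
#'
#' @param panel a `founder_panel`.
#' @param prefix output file prefix.
#' @param chrom chromosome label used in the site table.
#' @return Invisibly, the two file paths.
#' @export
write_founder_panel <- function(panel, prefix, chrom = "3R") {
  hap_path <- paste0(prefix, ".haplotypes.tsv")
  site_path <- paste0(prefix, ".sites.tsv")
  utils::write.table(panel$alleles, hap_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(chrom = chrom, pos_bp = panel$positions_bp,
               cM = panel$positions_M * 100),
    site_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(hap_path, site_path))
}

#' Read a founder panel from TSV files written by [write_founder_panel()]
#'
#' @param prefix file prefix used at write time.
#' @param map optional `genetic_map`; default: uniform 63 cM map.
#' @return A `founder_panel`.
#' @export
read_founder_panel <- function(prefix, map = NULL) {
  alleles <- as.matrix(utils::read.table(paste0(prefix, ".haplotypes.tsv"),
                                         sep = "\t"))
  dimnames(alleles) <- NULL
  storage.mode(alleles) <- "integer"
  sites <- utils::read.table(paste0(prefix, ".sites.tsv"),
                             header = TRUE, sep = "\t")
  if (is.null(map)) map <- uniform_genetic_map()
  structure(list(
    alleles = alleles, positions_bp = sites$pos_bp,
    positions_M = sites$cM / 100, map = map,
    site_freqs = colMeans(alleles)
  ), class = "founder_panel")
}

#' Import phased haplotypes from a VCF as a founder panel
#'
#' Reads phased GT fields from a biallelic VCF; each haplotype column of
#' every sample becomes one founder chromosome.  Requires the `vcfR`
#' package.
#'
#' @param path VCF file.
#' @param map optional `genetic_map` (default uniform 63 cM).
#' @return A `founder_panel`.
#' @export
read_haplotypes_vcf <- function(path, map = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF import requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  if (any(!grepl("^[01][|/][01]$", gt)))
    stop("expected phased biallelic GT fields (0|0, 0|1, 1|0, 1|1)")
  h1 <- substr(gt, 1, 1); h2 <- substr(gt, 3, 3)
  alleles <- rbind(t(matrix(as.integer(h1), nrow = nrow(gt))),
                   t(matrix(as.integer(h2), nrow = nrow(gt))))
  pos <- as.integer(vcfR::getPOS(v))
  keep <- colMeans(alleles) > 0 & colMeans(alleles) < 1
  alleles <- alleles[, keep, drop = FALSE]
  pos <- pos[keep]
  o <- order(pos)
  alleles <- alleles[, o, drop = FALSE]
  pos <- pos[o]
  if (is.null(map)) map <- uniform_genetic_map(chrom_length_bp =
                                                 max(pos) + 1e5)
  structure(list(
    alleles = alleles, positions_bp = pos,
    positions_M = bp_to_cM(map, pos) / 100, map = map,
    site_freqs = colMeans(alleles)
  ), class = "founder_panel")
}
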