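#' Per-site heterozygosity from major/minor counts
#'
#' `2 p (1 - p)` with `p = major / (major + minor)`; accepts exact
#' frequencies directly through `freq`.
#'
#' @param major,minor allele counts (vectorized).
#' @param freq alternatively, allele frequencies.
#' @return Heterozygosity in `[0, 0.5]`; `NA` at zero-depth sites.
#' @examples
#' site_heterozygosity(48, 12)  # 0.32
#' @export
site_heterozygosity <- function(major, minor, freq = NULL) {
  if (!is.null(freq)) return(2 * freq * (1 - freq))
  tot <- major + minor
  p <- ifelse(tot > 0, major / tot, NA_real_)
  2 * p * (1 - p)
}

# generic windowed mean of per-site values: values is L x P, positions bp
window_mean <- function(positions_bp, values, window_size) {
  values <- as.matrix(values)
  win <- floor(positions_bp / window_size)
  uw <- sort(unique(win))
  out <- lapply(seq_len(ncol(values)), function(p) {
    v <- tapply(values[, p], win, mean, na.rm = TRUE)
    n <- tapply(!is.na(values[, p]), win, sum)
    data.frame(window_start = uw * window_size,
               window_end = (uw + 1) * window_size,
               population = p,
               value = as.numeric(v[as.character(uw)]),
               n_snps = as.integer(n[as.character(uw)]))
  })
  do.call(rbind, out)
}

#' Windowed heterozygosity
#'
#' Mean per-SNP heterozygosity over non-overlapping physical windows
#' (half-open `[start, start + window_size)`), computed directly from the
#' ref/alt counts of a pool-seq table or from an exact frequency matrix.
#' Windows containing no SNPs are absent from the output (missing).
#'
#' @param x a `counts_table`, or an `L x P` frequency matrix (then
#'   `positions_bp` is required).
#' @param window_size window width in bp (default 100 kb).
#' @param positions_bp site positions when `x` is a matrix.
#' @return Data frame: `window_start`, `window_end`, `population`,
#'   `value` (mean heterozygosity), `n_snps`.
#' @export
window_heterozygosity <- function(x, window_size = 1e5,
                                  positions_bp = NULL) {
  if (inherits(x, "counts_table")) {
    het <- sapply(seq_along(x$counts), function(p) {
      m <- x$counts[[p]]
      r <- m[cbind(seq_len(nrow(m)), match(x$sites$ref, BASES))]
      a <- m[cbind(seq_len(nrow(m)), match(x$sites$alt, BASES))]
      site_heterozygosity(r, a)
    })
    window_mean(x$sites$pos, het, window_size)
  } else {
    if (is.null(positions_bp))
      stop("positions_bp required for a frequency matrix")
    het <- 2 * x * (1 - x)
    window_mean(positions_bp, het, window_size)
  }
}

#' Truncated Watterson denominator
#'
#' `a(b, d) = sum_{i=b}^{d-b} 1/i`: the harmonic normalizer for counting
#' segregating sites detectable at uniform read depth `d` with a minimum
#' minor-allele count `b`.
#'
#' @param b minimum minor-allele count (default 2).
#' @param d uniform read depth.
#' @return The denominator value.
#' @examples
#' watterson_denominator(2, 30)  # ~2.927
#' @export
watterson_denominator <- function(b = 2, d) {
  if (d < 2 * b) stop("depth d must be at least 2b for detectable SNPs")
  sum(1 / seq.int(b, d - b))
}

#' Pooled Watterson theta over windows
#'
#' Per window and population,
#' `theta_W = S_w / (a(b, d) * C_w)`, where `S_w` counts covered sites
#' whose minor-allele read count reaches `b`, `C_w` counts sites with
#' sufficient (uniform) coverage `d`, and `a(b, d)` is
#' [watterson_denominator()].  Windows where fewer than
#' `min_covered_fraction` of sites have sufficient coverage are reported
#' `NA`.  The table must first be subsampled to uniform depth with
#' [subsample_to_depth()]; its `insufficient` attribute marks low-coverage
#' sites.  Theta is per tracked (SNP-table) site, not per base pair.
#'
#' @param table a `counts_table` at uniform depth `d`.
#' @param d the uniform depth (default 30).
#' @param b minimum minor-allele count (default 2).
#' @param window_size window width in bp.
#' @param min_covered_fraction minimum fraction of window sites with
#'   sufficient coverage (default 0.6).
#' @return Data frame: `window_start`, `window_end`, `population`,
#'   `theta`, `n_segregating`, `n_covered`, `n_sites`.
#' @export
watterson_theta_window <- function(table, d = 30, b = 2,
                                   window_size = 1e5,
                                   min_covered_fraction = 0.6) {
  an <- watterson_denominator(b, d)
  insuff <- attr(table, "insufficient")
  if (is.null(insuff))
    insuff <- pool_coverage(table) < d
  win <- floor(table$sites$pos / window_size)
  uw <- sort(unique(win))
  out <- lapply(seq_along(table$counts), function(p) {
    m <- table$counts[[p]][, 1:4, drop = FALSE]
    cov_ok <- !insuff[, p]
    minor <- apply(m, 1, function(cnt) sum(cnt) - max(cnt))
    seg <- cov_ok & minor >= b
    S <- tapply(seg, win, sum)[as.character(uw)]
    C <- tapply(cov_ok, win, sum)[as.character(uw)]
    Tot <- tapply(rep(TRUE, length(win)), win, sum)[as.character(uw)]
    theta <- ifelse(C / Tot >= min_covered_fraction & C > 0,
                    S / (an * C), NA_real_)
    data.frame(window_start = uw * window_size,
               window_end = (uw + 1) * window_size,
               population = p, theta = as.numeric(theta),
               n_segregating = as.integer(S), n_covered = as.integer(C),
               n_sites = as.integer(Tot))
  })
  do.call(rbind, out)
}

#' Per-site F_ST across demes
#'
#' `F_ST = (H_T - H_S) / H_T`, with `H_T = 2 pbar (1 - pbar)` from the
#' unweighted mean frequency across demes and `H_S` the mean within-deme
#' `2 p (1 - p)`.  Undefined (`NA`) where `H_T = 0` (sites monomorphic
#' everywhere are skipped, not scored 0).
#'
#' @param freqs for [site_fst()], a vector of per-deme frequencies at one
#'   site; for [fst_per_site()], an `L x D` matrix.
#' @return F_ST value(s) in `[0, 1]`, `NA` where undefined.
#' @examples
#' site_fst(c(0.6, 0.4))  # 0.04
#' site_fst(c(1, 1, 1, 1, 0))  # 1
#' @export
site_fst <- function(freqs) {
  as.numeric(fst_per_site(matrix(freqs, nrow = 1)))
}

#' @rdname site_fst
#' @export
fst_per_site <- function(freqs) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) < 2) stop("F_ST needs at least two demes")
  pbar <- rowMeans(freqs)
  ht <- 2 * pbar * (1 - pbar)
  hs <- rowMeans(2 * freqs * (1 - freqs))
  ifelse(ht > 0, (ht - hs) / ht, NA_real_)
}

#' Summary statistics of one simulated replicate
#'
#' From exact per-deme frequencies: mean heterozygosity (per-deme mean
#' `2pq` over the selected polymorphic sites, averaged over demes), mean
#' per-site F_ST over those sites, and the between-window variances of
#' windowed heterozygosity (averaged over demes) and windowed F_ST.
#'
#' @param freqs `L x D` frequency matrix.
#' @param positions_bp site positions (bp); needed for window variances.
#' @param window_size spatial-variance window width (50 kb, the scenario
#'   grid convention; genome scans conventionally use 100 kb).
#' @param polymorphic which sites enter the means: polymorphic in the
#'   pooled metapopulation (default), in at least one deme, or all sites.
#' @return One-row data frame: `mean_het`, `mean_fst`, `var_het`,
#'   `var_fst`, `n_polymorphic`.
#' @export
summarize_freqs <- function(freqs, positions_bp = NULL,
                            window_size = 5e4,
                            polymorphic = c("metapopulation", "any_deme",
                                            "all_sites")) {
  polymorphic <- match.arg(polymorphic)
  freqs <- as.matrix(freqs)
  pbar <- rowMeans(freqs)
  poly <- switch(polymorphic,
    metapopulation = pbar > 0 & pbar < 1,
    any_deme = apply(freqs > 0 & freqs < 1, 1, any),
    all_sites = rep(TRUE, nrow(freqs)))
  f <- freqs[poly, , drop = FALSE]
  mean_het <- mean(colMeans(2 * f * (1 - f)))
  fst <- fst_per_site(f)
  mean_fst <- mean(fst, na.rm = TRUE)
  var_het <- NA_real_; var_fst <- NA_real_
  if (!is.null(positions_bp)) {
    pos <- positions_bp[poly]
    wh <- window_heterozygosity(f, window_size, positions_bp = pos)
    var_het <- mean(tapply(wh$value, wh$population, stats::var,
                           na.rm = TRUE))
    wf <- window_mean(pos, matrix(fst, ncol = 1), window_size)
    var_fst <- stats::var(wf$value, na.rm = TRUE)
  }
  data.frame(mean_het = mean_het, mean_fst = mean_fst,
             var_het = var_het, var_fst = var_fst,
             n_polymorphic = sum(poly))
}

#' Aggregate replicate summaries into a scenario row
#'
#' Means over replicate runs plus 95% confidence bounds (2.5 and 97.5
#' percentiles of the replicate distribution) for the spatial-variance
#' quantities, mirroring the scenario-table layout.
#'
#' @param replicates data frame of per-replicate rows from
#'   [summarize_freqs()].
#' @param label scenario label.
#' @return One-row data frame of class `summary_row`.
#' @export
aggregate_scenario <- function(replicates, label = "scenario") {
  if (nrow(replicates) < 2)
    stop("aggregation needs at least two replicates")
  ci <- function(x) stats::quantile(x, c(0.025, 0.975), na.rm = TRUE,
                                    names = FALSE)
  ch <- ci(replicates$var_het); cf <- ci(replicates$var_fst)
  out <- data.frame(
    scenario = label, n_replicates = nrow(replicates),
    mean_het = mean(replicates$mean_het),
    var_het = mean(replicates$var_het),
    var_het_lo = ch[1], var_het_hi = ch[2],
    mean_fst = mean(replicates$mean_fst),
    var_fst = mean(replicates$var_fst),
    var_fst_lo = cf[1], var_fst_hi = cf[2])
  class(out) <- c("summary_row", "data.frame")
  out
}
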