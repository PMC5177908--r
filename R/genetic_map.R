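#' Build a genetic map from windowed recombination rates
#'
#' Constructs a piecewise-linear map from physical position (bp) to genetic
#' position (cM) from per-window rates, as produced by windowed recombination
#' rate calculators.  Windows are half-open `[start, next_start)`; the last
#' window's width is taken to equal the preceding one (or `window_bp` when a
#' single window is given).
#'
#' Because recombination is absent in male Drosophila, simulations of mixed-sex
#' populations conventionally use half the female map; setting
#' `sex_averaged = TRUE` halves all rates before accumulation.
#'
#' @param window_starts integer vector of window left edges in bp, strictly
#'   increasing, first element is the origin of the arm.
#' @param window_rates cM per window (not per Mb), `rates >= 0`, same length
#'   as `window_starts`.
#' @param sex_averaged halve all rates (female-only recombination).
#' @param window_bp fallback window width when only one window is given.
#' @return An object of class `genetic_map` with elements `window_starts`,
#'   `window_rates`, `cumulative_cM` (cM at each window start), `total_cM`,
#'   and `chrom_end_bp`.
#' @examples
#' m <- build_genetic_map(c(0L, 100000L), c(1, 1))
#' bp_to_cM(m, 150000)  # 1.5 cM
#' @export
build_genetic_map <- function(window_starts, window_rates,
                              sex_averaged = FALSE, window_bp = 1e5) {
  if (length(window_starts) != length(window_rates))
    stop("window_starts and window_rates must have equal length")
  d <- diff(window_starts)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1]
    stop("window_starts must be strictly increasing; window ", bad + 1,
         " (start ", window_starts[bad + 1], ") does not advance")
  }
  if (any(window_rates < 0)) stop("window rates must be >= 0")
  rates <- if (sex_averaged) window_rates / 2 else window_rates
  widths <- if (length(window_starts) > 1) c(d, d[length(d)]) else window_bp
  cum <- c(0, cumsum(rates))
  structure(list(
    window_starts = as.numeric(window_starts),
    window_widths = as.numeric(widths),
    window_rates  = as.numeric(rates),
    cumulative_cM = cum[-length(cum)],
    total_cM      = cum[length(cum)],
    chrom_end_bp  = window_starts[length(window_starts)] +
      widths[length(widths)]
  ), class = "genetic_map")
}

#' Uniform genetic map over a chromosome arm
#'
#' Convenience constructor for a constant-rate map, the package default when
#' no empirical windowed rates are supplied: 63 cM spread evenly over the
#' arm, emulating D. melanogaster chromosome 3R.
#'
#' @param chrom_length_bp physical length of the arm in bp.
#' @param total_cM total (female) map length in cM.
#' @param window_bp window width used to discretize the map.
#' @param sex_averaged halve the map (see [build_genetic_map()]).
#' @return A `genetic_map`.
#' @export
uniform_genetic_map <- function(chrom_length_bp = 28e6, total_cM = 63,
                                window_bp = 1e5, sex_averaged = FALSE) {
  starts <- seq(0, chrom_length_bp - window_bp, by = window_bp)
  rate <- total_cM / length(starts)
  build_genetic_map(starts, rep(rate, length(starts)),
                    sex_averaged = sex_averaged, window_bp = window_bp)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("genetic_map:", length(x$window_starts), "windows,",
      format(x$chrom_end_bp, big.mark = ","), "bp,",
      round(x$total_cM, 3), "cM total\n")
  invisible(x)
}

#' Convert physical to genetic position
#'
#' Piecewise-linear interpolation within windows.  Positions at or beyond the
#' arm end map to `total_cM`.
#'
#' @param map a `genetic_map`.
#' @param pos_bp physical positions (bp), vectorized.
#' @return Genetic positions in cM.
#' @export
bp_to_cM <- function(map, pos_bp) {
  if (any(pos_bp < map$window_starts[1]))
    stop("position before the start of the map")
  w <- findInterval(pos_bp, map$window_starts)
  frac <- pmin((pos_bp - map$window_starts[w]) / map$window_widths[w], 1)
  map$cumulative_cM[w] + frac * map$window_rates[w]
}

#' Convert genetic to physical position (pseudo-inverse)
#'
#' Inverts [bp_to_cM()].  Within zero-rate windows the map is flat, so the
#' inverse returns the left edge of the first window attaining the queried
#' cM value; round-trips are exact up to one window of resolution.
#'
#' @param map a `genetic_map`.
#' @param pos_cM genetic positions in cM, within `[0, total_cM]`.
#' @return Physical positions in bp.
#' @export
cM_to_bp <- function(map, pos_cM) {
  if (any(pos_cM < 0 | pos_cM > map$total_cM))
    stop("genetic position outside [0, total_cM]")
  ends <- map$cumulative_cM + map$window_rates
  w <- pmax(findInterval(pos_cM, map$cumulative_cM,
                         left.open = TRUE, rightmost.closed = FALSE), 1)
  # step back over trailing zero-rate windows
  w <- pmin(w, length(map$window_rates))
  frac <- ifelse(map$window_rates[w] > 0,
                 (pos_cM - map$cumulative_cM[w]) / map$window_rates[w], 0)
  map$window_starts[w] + pmin(pmax(frac, 0), 1) * map$window_widths[w]
}

#' Read a windowed genetic map from TSV
#'
#' Expects two columns: `window_start_bp` and `cM` (cM per window), with a
#' header line.
#'
#' @param path TSV file path.
#' @param sex_averaged halve rates (see [build_genetic_map()]).
#' @return A `genetic_map`.
#' @export
read_genetic_map <- function(path, sex_averaged = FALSE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("window_start_bp", "cM") %in% names(tab)))
    stop("map file needs columns window_start_bp and cM")
  build_genetic_map(tab$window_start_bp, tab$cM, sex_averaged = sex_averaged)
}
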