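#' Closed-form F_ST under pure drift
#'
#' Expected fixation index among subpopulations that diverged `t` generations
#' ago from a common ancestral population, each of diploid effective size
#' `N`, with no migration and no mutation:
#' \deqn{F_{ST} = 1 - (1 - 1/(2N))^t}
#'
#' @param N diploid effective population size of each subpopulation (so the
#'   number of gametes per population is `2N`).
#' @param t generations since divergence.
#' @return Predicted F_ST in `[0, 1)`.
#' @examples
#' predict_fst_drift(1000, 800)  # ~0.33
#' @export
predict_fst_drift <- function(N, t) {
  stopifnot(N > 0, t >= 0)
  1 - (1 - 1 / (2 * N))^t
}

#' Invert the drift F_ST prediction for effective population size
#'
#' Solves `fst = 1 - (1 - 1/(2N))^t` for `N`.
#'
#' @param fst observed F_ST, strictly inside (0, 1).
#' @param t generations since divergence.
#' @return Diploid effective size `N`.
#' @examples
#' solve_N(0.08, 785)  # ~4700
#' @export
solve_N <- function(fst, t) {
  stopifnot(fst > 0, fst < 1, t > 0)
  N <- 1 / (2 * (1 - (1 - fst)^(1 / t)))
  stopifnot(abs(predict_fst_drift(N, t) - fst) < 1e-10)
  N
}

#' Equilibrium F_ST under the island model
#'
#' With `Nm` migrants per subpopulation per generation, small migration rate
#' and no mutation, the equilibrium differentiation is
#' \deqn{F_{ST} = 1 / (4 N m + 1)}
#'
#' @param Nm number of migrants per generation.
#' @return Equilibrium F_ST.
#' @examples
#' predict_fst_island(2.875)  # 0.08
#' @export
predict_fst_island <- function(Nm) {
  stopifnot(Nm >= 0)
  1 / (4 * Nm + 1)
}

#' Invert the island-model F_ST for the number of migrants
#'
#' @param fst observed equilibrium F_ST, strictly inside (0, 1).
#' @return `Nm`, migrants per generation.
#' @examples
#' solve_Nm(0.08)  # 2.875
#' @export
solve_Nm <- function(fst) {
  stopifnot(fst > 0, fst < 1)
  Nm <- (1 / fst - 1) / 4
  stopifnot(abs(predict_fst_island(Nm) - fst) < 1e-10)
  Nm
}
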