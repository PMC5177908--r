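#' Construct a gamete as founder segments plus breakpoints
#'
#' A gamete is represented as an ordered founder-state vector `S` and a
#' strictly increasing recombination-breakpoint vector `B` in map units
#' (Morgans), with `length(S) == length(B) + 1`.  Segment `k` covers the
#' half-open interval `[B[k-1], B[k])` (with `B[0] = 0` and the last
#' segment closed at the map end).  For example `S = {3, 17, 31, 3}`,
#' `B = {0.20, 0.25, 0.60}` carries founder 3 on `[0, 0.20)`, founder 17 on
#' `[0.20, 0.25)`, and so on.  Adjacent equal states are kept as-is, never
#' merged.
#'
#' @param founder_states integer vector of founder indices (1-based).
#' @param breakpoints numeric vector, strictly increasing, strictly inside
#'   the map.
#' @return An object of class `gamete`.
#' @export
new_gamete <- function(founder_states, breakpoints = numeric(0)) {
  founder_states <- as.integer(founder_states)
  breakpoints <- as.numeric(breakpoints)
  if (length(founder_states) != length(breakpoints) + 1L)
    stop("need length(founder_states) == length(breakpoints) + 1")
  if (length(breakpoints) && any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly increasing")
  structure(list(founder_states = founder_states, breakpoints = breakpoints),
            class = "gamete")
}

#' @export
print.gamete <- function(x, ...) {
  cat("gamete: S = {", paste(x$founder_states, collapse = ", "),
      "}, B = {", paste(signif(x$breakpoints, 4), collapse = ", "), "}\n")
  invisible(x)
}

#' Founder index covering a map position
#'
#' @param gamete a [new_gamete()] object.
#' @param position_M position in Morgans; a breakpoint position belongs to
#'   the segment on its right (half-open convention).
#' @return Integer founder index.
#' @export
segment_founder_at <- function(gamete, position_M) {
  gamete$founder_states[findInterval(position_M, gamete$breakpoints) + 1L]
}

#' Panel allele carried by a gamete at a panel site
#'
#' Looks up which founder segment covers the queried map position and
#' returns that founder's allele at the panel site located there.
#'
#' @param gamete a `gamete`.
#' @param position_M map position in Morgans; must coincide with a panel
#'   site position.
#' @param panel a `founder_panel`.
#' @return 0/1 allele.
#' @export
genotype_at <- function(gamete, position_M, panel) {
  if (position_M < 0 || position_M > panel$map$total_cM / 100)
    stop("position outside the genetic map")
  site <- which(abs(panel$positions_M - position_M) < 1e-9)
  if (length(site) != 1L)
    stop("no panel site at map position ", position_M, " M")
  panel$alleles[segment_founder_at(gamete, position_M), site]
}

#' One meiosis in gamete mode
#'
#' Produces one offspring gamete from two parental gametes under the
#' single-crossover rule: only even offspring slots recombine (recombination
#' is female-limited and offspring alternate sexes by slot parity), and for
#' an even slot a single uniform draw `r ~ U(0,1)` yields a crossover at `r`
#' iff `r` falls inside the map (`r < L`, with `L` the map length in
#' Morgans, 0.63 for a 63 cM arm).  Otherwise the offspring is a copy of
#' `parent1`.  One uniform deviate is consumed exactly when
#' `offspring_index` is even and `r` is not supplied.
#'
#' @param parent1,parent2 `gamete` objects on the same map.
#' @param offspring_index slot index `n` (1-based); recombination happens
#'   only when `n %% 2 == 0`.
#' @param map_length_morgans map length `L` in Morgans.
#' @param r optional pre-drawn uniform deviate (for testing).
#' @return Offspring `gamete`.
#' @export
recombine_gamete_mode <- function(parent1, parent2, offspring_index,
                                  map_length_morgans = 0.63, r = NULL) {
  if (offspring_index %% 2 != 0) return(parent1)
  if (is.null(r)) r <- stats::runif(1)
  if (r >= map_length_morgans) return(parent1)
  crossover_at(parent1, parent2, r)
}

# Join parent1 left of r with parent2 right of r, breakpoint at r.
crossover_at <- function(p1, p2, r) {
  k1 <- findInterval(r, p1$breakpoints, left.open = TRUE)  # breaks < r
  k2 <- findInterval(r, p2$breakpoints)                    # breaks <= r
  n2 <- length(p2$founder_states)
  structure(list(
    founder_states = c(p1$founder_states[seq_len(k1 + 1L)],
                       p2$founder_states[(k2 + 1L):n2]),
    breakpoints = c(p1$breakpoints[seq_len(k1)], r,
                    p2$breakpoints[p2$breakpoints > r])
  ), class = "gamete")
}

#' Assemble a metapopulation of gamete demes
#'
#' @param demes list of demes, each a list of `N` gametes (all demes equal
#'   size).
#' @param generation generation counter.
#' @param map_length_morgans map length in Morgans.
#' @return An object of class `metapopulation`.
#' @export
new_metapopulation <- function(demes, generation = 0L,
                               map_length_morgans = 0.63) {
  sizes <- lengths(demes)
  if (length(unique(sizes)) != 1L)
    stop("all demes must hold the same number of gametes")
  structure(list(demes = demes, D = length(demes), N = sizes[[1]],
                 generation = as.integer(generation),
                 map_length_morgans = map_length_morgans),
            class = "metapopulation")
}

#' @export
print.metapopulation <- function(x, ...) {
  cat("metapopulation:", x$D, "demes x", x$N, "gametes, generation",
      x$generation, "\n")
  invisible(x)
}

#' Found a metapopulation from a founder panel
#'
#' Each deme is an independent expansion of the panel: `N` single-segment
#' gametes drawn uniformly with replacement from the founders.
#'
#' @param panel a `founder_panel`.
#' @param n_demes number of demes `D`.
#' @param n_gametes gametes per deme `N`.
#' @param seed optional integer seed.
#' @return A `metapopulation` at generation 0.
#' @export
found_metapopulation <- function(panel, n_demes = 5, n_gametes = 2000,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  demes <- lapply(seq_len(n_demes), function(d)
    expand_panel(panel, n_gametes))
  new_metapopulation(demes,
                     map_length_morgans = panel$map$total_cM / 100)
}

# First index with cumw >= target (inversion sampling on cumulative
# weights); shared tie convention with the C++ engine.
weighted_pick <- function(cumw, target) {
  min(findInterval(target, cumw, left.open = TRUE) + 1L, length(cumw))
}

#' Advance a metapopulation by one Wright-Fisher generation (gamete mode)
#'
#' For each offspring slot `n = 1..N` in each deme, two parental gametes are
#' drawn with replacement from the previous generation — uniformly, or with
#' probability proportional to `fitness_weights` — and the offspring is
#' produced by [recombine_gamete_mode()].  RNG consumption per slot: one
#' uniform per parent draw, plus one uniform crossover draw on even slots.
#'
#' This is the reference R implementation of the engine's generation step;
#' [run_simulation()] runs the identical algorithm (same RNG stream) in
#' compiled code.
#'
#' @param metapop a `metapopulation`.
#' @param fitness_weights `NULL` for neutral drift, or a list of per-deme
#'   non-negative weight vectors of length `N`.
#' @return The next-generation `metapopulation`.
#' @export
next_generation <- function(metapop, fitness_weights = NULL) {
  N <- metapop$N
  L <- metapop$map_length_morgans
  demes <- vector("list", metapop$D)
  for (d in seq_len(metapop$D)) {
    pool <- metapop$demes[[d]]
    w <- fitness_weights[[d]]
    cumw <- NULL
    if (!is.null(w)) {
      if (length(w) != N || any(w < 0))
        stop("weights must be non-negative and of length N")
      if (all(w == 0))
        stop("all fitness weights zero in deme ", d,
             ": population is inviable (fixation/lethality)")
      cumw <- cumsum(w)
    }
    offspring <- vector("list", N)
    for (n in seq_len(N)) {
      if (is.null(cumw)) {
        i1 <- min(floor(stats::runif(1) * N) + 1, N)
        i2 <- min(floor(stats::runif(1) * N) + 1, N)
      } else {
        i1 <- weighted_pick(cumw, stats::runif(1) * cumw[N])
        i2 <- weighted_pick(cumw, stats::runif(1) * cumw[N])
      }
      offspring[[n]] <- recombine_gamete_mode(pool[[i1]], pool[[i2]], n, L)
    }
    demes[[d]] <- offspring
  }
  new_metapopulation(demes, metapop$generation + 1L, L)
}

#' One-way island migration
#'
#' Performs `M` replacement events on the pooled `D * N` gametes: each event
#' draws a uniform random pair (which may fall in the same deme) and
#' overwrites the first member with a copy of the second.  Gametes are not
#' exchanged, so migration is one-way; pairs span any two demes with equal
#' probability, so it is an island model.  Two uniform deviates are consumed
#' per event.
#'
#' @param metapop a `metapopulation`.
#' @param M number of migrant (replacement) events this generation.
#' @param distinct_demes if `TRUE`, redraw the second member until it lies
#'   in a different deme than the first (sensitivity-analysis variant; the
#'   default matches the uniform pooled draw).
#' @return The `metapopulation` after migration.
#' @export
migrate <- function(metapop, M, distinct_demes = FALSE) {
  if (M < 0) stop("M must be >= 0")
  if (M == 0) return(metapop)
  DN <- metapop$D * metapop$N
  flat <- do.call(c, metapop$demes)
  for (k in seq_len(M)) {
    i <- min(floor(stats::runif(1) * DN) + 1, DN)
    j <- min(floor(stats::runif(1) * DN) + 1, DN)
    if (distinct_demes) {
      di <- (i - 1) %/% metapop$N
      repeat {
        if ((j - 1) %/% metapop$N != di) break
        j <- min(floor(stats::runif(1) * DN) + 1, DN)
      }
    }
    flat[[i]] <- flat[[j]]
  }
  demes <- split(flat, rep(seq_len(metapop$D), each = metapop$N))
  names(demes) <- NULL
  new_metapopulation(lapply(demes, identity), metapop$generation,
                     metapop$map_length_morgans)
}

#' Project a metapopulation onto per-site allele frequencies
#'
#' For every panel site and every deme, the exact frequency of the alternate
#' allele: the mean over the deme's `N` gametes of the allele carried by the
#' founder segment covering the site.  No sampling noise is involved.
#'
#' @param metapop a `metapopulation`.
#' @param panel the `founder_panel` the gametes refer to.
#' @return `L x D` numeric matrix of frequencies.
#' @export
allele_frequencies <- function(metapop, panel) {
  states <- lapply(do.call(c, metapop$demes), `[[`, "founder_states")
  breaks <- lapply(do.call(c, metapop$demes), `[[`, "breakpoints")
  cpp_project_freqs(states, breaks, panel$positions_M, panel$alleles,
                    metapop$D, metapop$N)
}
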