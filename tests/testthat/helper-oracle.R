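# Reference implementations used as independent oracles.
#
# The engine's RNG contract (draw order per generation): for each deme,
# [QTL only] per gamete one polygenic then one environmental N(0,1); then
# per offspring slot n = 1..N one uniform per parent draw (two), plus on
# even n one uniform crossover draw (crossover iff r < map length in
# Morgans); then M migration events of two uniforms each.  The oracles
# below consume the identical stream but materialize every gamete as an
# explicit allele vector, so agreement is representation-independent.

# construct a founder_panel by hand (no RNG)
tiny_panel <- function(alleles, positions_M, total_cM = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (is.null(total_cM)) total_cM <- 63
  chrom_len <- 28e6
  map <- ersim::uniform_genetic_map(chrom_len, total_cM)
  structure(list(
    alleles = alleles,
    positions_bp = round(positions_M * 100 / total_cM * chrom_len),
    positions_M = positions_M,
    map = map,
    site_freqs = colMeans(alleles)
  ), class = "founder_panel")
}

# explicit-haplotype neutral Wright-Fisher, bit-compatible RNG stream
oracle_neutral_run <- function(panel, D, N, G, M = 0, seed = 1) {
  set.seed(seed)
  F <- nrow(panel$alleles)
  L <- ncol(panel$alleles)
  pos <- panel$positions_M
  map_len <- panel$map$total_cM / 100
  # founding: deme-major sample.int, as in run_simulation()
  pool <- vector("list", D)
  for (d in seq_len(D)) {
    idx <- sample.int(F, N, replace = TRUE)
    pool[[d]] <- lapply(idx, function(i) panel$alleles[i, ])
  }
  for (g in seq_len(G)) {
    nxt <- vector("list", D)
    for (d in seq_len(D)) {
      cur <- pool[[d]]
      off <- vector("list", N)
      for (n in seq_len(N)) {
        i1 <- min(floor(runif(1) * N) + 1, N)
        i2 <- min(floor(runif(1) * N) + 1, N)
        if (n %% 2 == 0) {
          r <- runif(1)
          if (r < map_len) {
            child <- cur[[i1]]
            right <- pos >= r
            child[right] <- cur[[i2]][right]
            off[[n]] <- child
          } else off[[n]] <- cur[[i1]]
        } else off[[n]] <- cur[[i1]]
      }
      nxt[[d]] <- off
    }
    pool <- nxt
    if (M > 0) {
      flat <- do.call(c, pool)
      DN <- D * N
      for (k in seq_len(M)) {
        i <- min(floor(runif(1) * DN) + 1, DN)
        j <- min(floor(runif(1) * DN) + 1, DN)
        flat[[i]] <- flat[[j]]
      }
      pool <- split(flat, rep(seq_len(D), each = N))
      names(pool) <- NULL
    }
  }
  sapply(seq_len(D), function(d)
    colMeans(do.call(rbind, pool[[d]])))
}

# explicit-haplotype QTL (optimizing selection) run, same stream as the
# compiled engine; plain-double accumulation throughout
oracle_qtl_run <- function(panel, config, D, N, G, M = 0, seed = 1) {
  set.seed(seed)
  F <- nrow(panel$alleles)
  pos <- panel$positions_M
  map_len <- panel$map$total_cM / 100
  qsites <- config$positions
  eff <- config$effects
  sd_poly <- sqrt(config$va_poly); sd_e <- sqrt(config$ve)
  vf <- config$variance_fitness
  h2 <- config$va_poly / (config$va_poly + config$ve)
  opt <- sum(config$start_freqs * config$effects) + config$polygenic_mean +
    config$optimum_shift * sqrt(config$vp0)
  polymean <- rep(config$polygenic_mean, D)

  pool <- vector("list", D)
  for (d in seq_len(D)) {
    idx <- sample.int(F, N, replace = TRUE)
    pool[[d]] <- lapply(idx, function(i) panel$alleles[i, ])
  }
  pick <- function(cumw, target)
    min(findInterval(target, cumw, left.open = TRUE) + 1L, length(cumw))
  for (g in seq_len(G)) {
    nxt <- vector("list", D)
    for (d in seq_len(D)) {
      cur <- pool[[d]]
      pheno <- numeric(N); w <- numeric(N)
      sum_pheno <- 0
      for (n in seq_len(N)) {
        gsum <- 0
        for (q in seq_along(qsites))
          gsum <- gsum + eff[q] * cur[[n]][qsites[q]]
        zp <- rnorm(1); ze <- rnorm(1)
        pheno[n] <- gsum + polymean[d] + zp * sd_poly + ze * sd_e
        dev <- pheno[n] - opt
        w[n] <- exp(-dev * dev / (2 * vf))
        sum_pheno <- sum_pheno + pheno[n]
      }
      cumw <- numeric(N); acc <- 0
      for (n in seq_len(N)) { acc <- acc + w[n]; cumw[n] <- acc }
      off <- vector("list", N)
      psum <- 0
      for (n in seq_len(N)) {
        i1 <- pick(cumw, runif(1) * cumw[N])
        i2 <- pick(cumw, runif(1) * cumw[N])
        psum <- psum + pheno[i1] + pheno[i2]
        if (n %% 2 == 0) {
          r <- runif(1)
          if (r < map_len) {
            child <- cur[[i1]]
            right <- pos >= r
            child[right] <- cur[[i2]][right]
            off[[n]] <- child
          } else off[[n]] <- cur[[i1]]
        } else off[[n]] <- cur[[i1]]
      }
      S <- psum / (2 * N) - sum_pheno / N
      polymean[d] <- polymean[d] + h2 * S
      nxt[[d]] <- off
    }
    pool <- nxt
    if (M > 0) {
      flat <- do.call(c, pool)
      DN <- D * N
      for (k in seq_len(M)) {
        i <- min(floor(runif(1) * DN) + 1, DN)
        j <- min(floor(runif(1) * DN) + 1, DN)
        flat[[i]] <- flat[[j]]
      }
      pool <- split(flat, rep(seq_len(D), each = N))
      names(pool) <- NULL
    }
  }
  list(freqs = sapply(seq_len(D), function(d)
         colMeans(do.call(rbind, pool[[d]]))),
       polygenic_mean = polymean)
}

# deterministic infinite-population allele-frequency iteration for one
# selected locus: standard single-locus recursion under w11/w12/w22
deterministic_locus_iteration <- function(p0, s, h, generations) {
  w11 <- 1; w12 <- 1 + h * s; w22 <- 1 + s
  p <- p0
  for (g in seq_len(generations)) {
    q <- 1 - p
    wbar <- p^2 * w22 + 2 * p * q * w12 + q^2 * w11
    p <- (p^2 * w22 + p * q * w12) / wbar
  }
  p
}
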