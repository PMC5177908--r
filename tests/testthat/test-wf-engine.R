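test_that("gamete construction enforces the segment invariants", {
  g <- new_gamete(c(3, 17, 31, 3), c(0.20, 0.25, 0.60))
  expect_s3_class(g, "gamete")
  expect_error(new_gamete(c(1, 2), c(0.3, 0.4)), "length")
  expect_error(new_gamete(c(1, 2, 3), c(0.4, 0.3)), "increasing")
})

test_that("segment lookup follows the half-open convention", {
  g <- new_gamete(c(3, 17, 31, 3), c(0.20, 0.25, 0.60))
  expect_equal(segment_founder_at(g, 0.10), 3L)
  expect_equal(segment_founder_at(g, 0.22), 17L)   # founder 17 on [0.20, 0.25)
  expect_equal(segment_founder_at(g, 0.25), 31L)   # breakpoint -> right segment
  expect_equal(segment_founder_at(g, 0.62), 3L)
})

test_that("genotype_at returns the covering founder's panel allele", {
  al <- matrix(0L, 40, 3)
  al[17, ] <- 1L; al[31, 3] <- 1L
  panel <- tiny_panel(al, c(0.10, 0.22, 0.40))
  g <- new_gamete(c(3, 17, 31, 3), c(0.20, 0.25, 0.60))
  expect_equal(genotype_at(g, 0.22, panel), 1L)  # founder 17 carries 1
  expect_equal(genotype_at(g, 0.10, panel), 0L)  # founder 3 carries 0
  expect_equal(genotype_at(g, 0.40, panel), 1L)  # founder 31's segment
  expect_error(genotype_at(g, 0.9, panel), "outside")
  expect_error(genotype_at(g, 0.15, panel), "no panel site")
})

test_that("single-crossover recombination joins parents at r", {
  p1 <- new_gamete(3); p2 <- new_gamete(17)
  child <- recombine_gamete_mode(p1, p2, offspring_index = 2, 0.63, r = 0.20)
  expect_equal(child$founder_states, c(3L, 17L))
  expect_equal(child$breakpoints, 0.20)
  # r beyond the map: copy of parent1
  expect_identical(recombine_gamete_mode(p1, p2, 2, 0.63, r = 0.70), p1)
  # odd slot never recombines and consumes no randomness
  expect_identical(recombine_gamete_mode(p1, p2, 1, 0.63), p1)
  # identical parents: child genetically identical for any r
  g <- new_gamete(c(5, 9), 0.3)
  ch <- recombine_gamete_mode(g, g, 2, 0.63, r = 0.5)
  expect_equal(segment_founder_at(ch, 0.2), 5L)
  expect_equal(segment_founder_at(ch, 0.45), 9L)
  # multi-segment parents keep their flanking breakpoints
  a <- new_gamete(c(1, 2, 3), c(0.1, 0.5))
  b <- new_gamete(c(7, 8), 0.4)
  ch2 <- recombine_gamete_mode(a, b, 2, 0.63, r = 0.3)
  expect_equal(ch2$founder_states, c(1L, 2L, 7L, 8L))
  expect_equal(ch2$breakpoints, c(0.1, 0.3, 0.4))
})

test_that("deme size is conserved and weights act on parentage", {
  p <- generate_founder_panel(10, 60, seed = 1)
  mp <- found_metapopulation(p, n_demes = 2, n_gametes = 10, seed = 2)
  for (g in 1:5) mp <- next_generation(mp)
  expect_equal(mp$generation, 5L)
  expect_true(all(lengths(mp$demes) == 10))
  # a zero-weight gamete never parents: give gamete 1 weight 0 and mark it
  mp0 <- found_metapopulation(p, 1, 10, seed = 3)
  mp0$demes[[1]][[1]] <- new_gamete(999L)  # sentinel founder state
  w <- list(c(0, rep(1, 9)))
  for (rep in 1:20) {
    nxt <- next_generation(mp0, w)
    states <- unlist(lapply(nxt$demes[[1]], `[[`, "founder_states"))
    expect_false(999L %in% states)
  }
  expect_error(next_generation(mp0, list(rep(0, 10))), "inviable")
})

test_that("neutral reproduction preserves expected founder frequencies", {
  # one deme, two founder states at 50:50; offspring counts are Binomial(N, 1/2)
  pool <- c(rep(list(new_gamete(1L)), 10), rep(list(new_gamete(2L)), 10))
  mp <- new_metapopulation(list(pool), map_length_morgans = 0.63)
  set.seed(8)
  props <- replicate(1000, {
    nxt <- next_generation(mp)
    mean(vapply(nxt$demes[[1]], function(g) g$founder_states[1] == 1L,
                logical(1)))
  })
  expect_lt(abs(mean(props) - 0.5), 3 * sqrt(0.25 / 20) / sqrt(1000))
})

test_that("migration conserves counts and M = 0 is the identity", {
  p <- generate_founder_panel(10, 40, seed = 5)
  mp <- found_metapopulation(p, 3, 8, seed = 6)
  expect_identical(migrate(mp, 0), mp)
  set.seed(9)
  moved <- migrate(mp, 10)
  expect_equal(moved$D, 3); expect_true(all(lengths(moved$demes) == 8))
  # replacement only copies existing gametes
  before <- unlist(lapply(do.call(c, mp$demes), `[[`, "founder_states"))
  after <- unlist(lapply(do.call(c, moved$demes), `[[`, "founder_states"))
  expect_true(all(after %in% before))
})

test_that("migration reduces expected between-deme variance", {
  # two demes fixed for different founder states; any cross-deme replacement
  # strictly reduces the frequency contrast, so variance is non-increasing in M
  p <- tiny_panel(matrix(c(0L, 1L), 2, 1), 0.3)
  base <- new_metapopulation(list(rep(list(new_gamete(1L)), 20),
                                  rep(list(new_gamete(2L)), 20)),
                             map_length_morgans = 0.63)
  var_after <- function(M, reps = 300) {
    mean(replicate(reps, {
      f <- allele_frequencies(migrate(base, M), p)
      var(as.numeric(f))
    }))
  }
  set.seed(10)
  v <- c(var_after(0, 1), var_after(2), var_after(8))
  expect_true(all(diff(v) < 0))
})

test_that("segment engine matches the explicit-haplotype oracle exactly", {
  set.seed(41)
  al <- matrix(rbinom(50 * 260, 1, 0.35), 50, 260)
  al <- al[, colMeans(al) > 0 & colMeans(al) < 1][, 1:200]
  panel <- tiny_panel(al, sort(runif(200, 0, 0.63)))
  # N = 50, L = 200, 20 generations, shared RNG stream
  oracle <- oracle_neutral_run(panel, D = 2, N = 50, G = 20, M = 0, seed = 17)
  run <- run_simulation(panel, 2, 50, 20, migrants = 0, seed = 17)
  expect_identical(unname(run$freqs), unname(oracle))
  # with migration in the stream too
  oracle_m <- oracle_neutral_run(panel, 2, 50, 20, M = 4, seed = 18)
  run_m <- run_simulation(panel, 2, 50, 20, migrants = 4, seed = 18)
  expect_identical(unname(run_m$freqs), unname(oracle_m))
})

test_that("R-level generation stepping reproduces the compiled engine", {
  p <- generate_founder_panel(12, 100, seed = 21)
  G <- 8
  run <- run_simulation(p, 2, 20, G, migrants = 3, seed = 22)
  set.seed(22)
  mp <- found_metapopulation(p, 2, 20)
  for (g in seq_len(G)) mp <- migrate(next_generation(mp), 3)
  expect_identical(unname(allele_frequencies(mp, p)), unname(run$freqs))
})

test_that("founder states are conserved across generations", {
  p <- generate_founder_panel(15, 50, seed = 30)
  mp <- found_metapopulation(p, 1, 30, seed = 31)
  prev <- unique(unlist(lapply(mp$demes[[1]], `[[`, "founder_states")))
  for (g in 1:10) {
    mp <- next_generation(mp)
    cur <- unique(unlist(lapply(mp$demes[[1]], `[[`, "founder_states")))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("breakpoints accumulate at no more than 0.63/2 per generation", {
  p <- generate_founder_panel(20, 100, seed = 33)
  G <- 40
  run <- run_simulation(p, 1, 200, G, seed = 34)
  rate <- run$mean_breakpoints / G
  # expectation is 0.63/2 per slot; allow Monte-Carlo slack upward
  expect_lt(rate, 0.63 / 2 * 1.15)
  expect_gt(rate, 0.63 / 2 * 0.85)
})

test_that("identical seeds give identical trajectories", {
  p <- generate_founder_panel(20, 150, seed = 50)
  r1 <- run_simulation(p, 2, 40, 30, migrants = 1, seed = 51)
  r2 <- run_simulation(p, 2, 40, 30, migrants = 1, seed = 51)
  expect_identical(r1$freqs, r2$freqs)
  expect_identical(r1$founder_states, r2$founder_states)
})

test_that("neutral heterozygosity decays as (1 - 1/N)^t", {
  p <- generate_founder_panel(40, 300, seed = 60)
  N <- 100; G <- 80; reps <- 24
  ratios <- vapply(seq_len(reps), function(r) {
    # same seed founds the identical generation-0 pool in both runs
    f0 <- run_simulation(p, 1, N, 0, seed = 600 + r)$freqs[, 1]
    fG <- run_simulation(p, 1, N, G, seed = 600 + r)$freqs[, 1]
    mean(2 * fG * (1 - fG)) / mean(2 * f0 * (1 - f0))
  }, numeric(1))
  expected <- (1 - 1 / N)^G
  se <- sd(ratios) / sqrt(reps)
  expect_lt(abs(mean(ratios) - expected), 3 * se)
})

test_that("checkpoint TSV dump covers every gamete and segment", {
  p <- generate_founder_panel(10, 40, seed = 70)
  run <- run_simulation(p, 2, 10, 15, seed = 71)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gametes_tsv(run, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(length(unique(paste(tab$deme, tab$gamete))), 20)
  expect_true(all(tab$end_M <= 0.63 + 1e-12))
  # per-gamete segment ends strictly increase
  ok <- tapply(tab$end_M, paste(tab$deme, tab$gamete),
               function(x) all(diff(x) > 0))
  expect_true(all(ok))
})
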