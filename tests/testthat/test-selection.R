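test_that("per-locus fitness follows w11 = 1, w12 = 1+hs, w22 = 1+s", {
  cfg <- locus_selection_config(1, s = 0.1, h = 0.5)
  expect_equal(locus_fitness(matrix(0:2, ncol = 1), cfg),
               c(1, 1.05, 1.1))
  # multiplicative across loci: het at locus 1, homozygous favored at 2
  cfg2 <- locus_selection_config(c(1, 2), s = 0.1, h = 0.5)
  expect_equal(locus_fitness(matrix(c(1, 2), nrow = 1), cfg2),
               1.05 * 1.1)
  # empty configuration: neutral
  cfg0 <- locus_selection_config(integer(0), numeric(0), numeric(0))
  expect_equal(locus_fitness(matrix(0, 3, 0), cfg0), rep(1, 3))
  expect_error(locus_selection_config(1, s = -1.2), "non-positive")
  expect_error(locus_fitness(matrix(3, 1, 1), cfg), "0, 1 or 2")
})

test_that("overdominance equilibrium is h/(2h-1) and iteration converges", {
  cfg <- make_overdominant_config(1, s = 0.1, h_overdominant = 2)
  eq <- attr(cfg, "equilibrium_freq")
  expect_equal(eq, 2 / 3)
  # fitnesses are (1, 1.2, 1.1)
  expect_equal(locus_fitness(matrix(0:2, ncol = 1), cfg), c(1, 1.2, 1.1))
  # deterministic infinite-population iteration converges to eq from both sides
  expect_equal(deterministic_locus_iteration(0.1, 0.1, 2, 3000), eq,
               tolerance = 1e-6)
  expect_equal(deterministic_locus_iteration(0.95, 0.1, 2, 3000), eq,
               tolerance = 1e-6)
  expect_error(make_overdominant_config(1, 0.1, h_overdominant = 0.5),
               "exceed 1")
})

test_that("directional selection fixes the favored allele deterministically
           and raises its frequency in finite populations", {
  expect_gt(deterministic_locus_iteration(0.05, 0.1, 0.5, 2000), 0.999)
  # finite diploid simulation: favored allele rises above its neutral drift
  p <- generate_founder_panel(40, 200, seed = 90)
  site <- 100L
  cfg <- locus_selection_config(site, s = 0.3, h = 0.5)
  f_sel <- vapply(1:6, function(r)
    run_simulation(p, 1, 200, 60, selection = cfg,
                   seed = 900 + r)$freqs[site, 1], numeric(1))
  f_neu <- vapply(1:6, function(r)
    run_simulation(p, 1, 200, 60, seed = 900 + r)$freqs[site, 1],
    numeric(1))
  expect_gt(mean(f_sel), p$site_freqs[site])
  expect_gt(mean(f_sel), mean(f_neu))
})

test_that("simulated overdominant sites stay near the equilibrium", {
  p <- generate_founder_panel(60, 300, seed = 95)
  sites <- c(75L, 150L, 225L)
  cfg <- make_overdominant_config(sites, s = 0.3, h_overdominant = 2)
  eq <- attr(cfg, "equilibrium_freq")
  devs <- vapply(1:5, function(r) {
    run <- run_simulation(p, 1, 1000, 300, selection = cfg, seed = 950 + r)
    mean(abs(run$freqs[sites, 1] - eq))
  }, numeric(1))
  expect_lt(median(devs), 0.1)
})

test_that("QTL effect presets keep the squared-effect sum constant", {
  expect_equal(qtl_effect_preset(3), c(1, 2, 2))
  expect_equal(sum(qtl_effect_preset(3)^2), 9)
  expect_equal(sum(qtl_effect_preset(10)^2), 8 + 2 * 0.71^2)
  expect_equal(sum(qtl_effect_preset(20)^2), 16 * 0.71^2 + 4 * 0.5^2)
  # both alternative sums are within ~1% of the 3-QTL sum of 9
  expect_lt(abs(sum(qtl_effect_preset(20)^2) - 9) / 9, 0.01)
  expect_error(qtl_effect_preset(7), "explicitly")
})

test_that("effect rescaling hits the target QTL variance exactly", {
  cfg <- make_qtl_config(3, 0.5, n_sites = 1000)
  expect_equal(sum(0.25 * cfg$effects^2), 0.12)
  expect_equal(cfg$effects, c(1, 2, 2) * sqrt(0.12 / (0.25 * 9)))
  cfg2 <- make_qtl_config(10, 0.05, n_sites = 1000)
  expect_equal(sum(0.05 * 0.95 * cfg2$effects^2), 0.12)
  raw <- make_qtl_config(3, 0.5, n_sites = 1000, rescale_to_h2 = FALSE)
  expect_equal(raw$effects, c(1, 2, 2))
  expect_error(make_qtl_config(7, 0.5, n_sites = 1000), "explicitly")
  expect_error(make_qtl_config(3, 1.2, n_sites = 1000), "inside")
})

test_that("QTL positions are evenly spaced and states hit start frequencies", {
  cfg <- make_qtl_config(10, 0.5, n_sites = 10000)
  expect_equal(length(unique(diff(cfg$positions))), 1)  # even spacing
  p <- generate_founder_panel(100, 10000, seed = 101)
  p2 <- assign_qtl_states(p, cfg, seed = 102)
  realized <- p2$site_freqs[cfg$positions]
  se <- sqrt(0.25 / 100)
  expect_true(all(abs(realized - 0.5) < 4 * se))
  expect_true(all(realized > 0 & realized < 1))
})

test_that("phenotype decomposition recovers the 12/38/50 variance split", {
  n_sites <- 2000
  cfg <- make_qtl_config(10, 0.5, n_sites = n_sites)
  # a large founder panel keeps finite-panel LD between QTL from inflating
  # the realized QTL variance relative to the 0.12 target
  p <- generate_founder_panel(2000, n_sites, seed = 110)
  p <- assign_qtl_states(p, cfg, seed = 111)
  n <- 1e5
  pool <- expand_panel(p, n, seed = 112)
  # genetic values alone (no deviates): variance ~ 0.12
  g <- vapply(pool, function(gm)
    sum(cfg$effects * p$alleles[gm$founder_states[1], cfg$positions]),
    numeric(1))
  expect_equal(var(g), 0.12, tolerance = 0.1)
  set.seed(113)
  ph <- qtl_phenotypes(pool, p, cfg)
  expect_equal(var(ph), 1.0, tolerance = 0.03)
  expect_equal(var(ph - g), 0.88, tolerance = 0.02)
  # mean phenotype = polygenic_mean + sum p_i a_i within 3 SE
  mu <- sum(p$site_freqs[cfg$positions] * cfg$effects)
  expect_lt(abs(mean(ph) - mu), 3 * sqrt(1 / n))
  # degenerate case: no effects, no variances -> constant polygenic mean
  cfg0 <- cfg; cfg0$effects <- rep(0, 10)
  cfg0$va_poly <- 1e-20; cfg0$ve <- 1e-20; cfg0$polygenic_mean <- 2.5
  ph0 <- qtl_phenotypes(pool[1:50], p, cfg0)
  expect_equal(ph0, rep(2.5, 50), tolerance = 1e-6)
})

test_that("Gaussian fitness weights behave like a normal kernel", {
  w <- gaussian_fitness(c(10, 12, 8), optimum = 10, variance_fitness = 12)
  expect_equal(sum(w), 1)
  expect_equal(which.max(w), 1)   # at the optimum
  # phenotypes at opt and opt + sqrt(2 * 12 * log(2)): weight ratio 2:1
  w2 <- gaussian_fitness(c(0, sqrt(2 * 12 * log(2))), 0, 12)
  expect_equal(w2[1] / w2[2], 2)
  expect_error(gaussian_fitness(c(1e4, 2e4), 0, 12), "underflow")
  expect_error(gaussian_fitness(1, 0, -1))
})

test_that("Breeder's-equation update scales S by h2_poly", {
  expect_equal(breeders_update(0.3, S = 0, va_poly = 0.38, ve = 0.5), 0.3)
  expect_equal(breeders_update(0, S = 1, va_poly = 0.38, ve = 0.5),
               0.38 / 0.88)
  expect_equal(breeders_update(1, S = 2, va_poly = 0.4, ve = 0), 3)
})

test_that("compiled QTL engine matches the explicit-haplotype reference", {
  set.seed(120)
  al <- matrix(rbinom(30 * 200, 1, 0.4), 30, 200)
  al <- al[, colMeans(al) > 0 & colMeans(al) < 1][, 1:150]
  panel <- tiny_panel(al, sort(runif(150, 0, 0.63)))
  cfg <- make_qtl_config(3, 0.5, n_sites = 150)
  panel <- assign_qtl_states(panel, cfg, seed = 121)
  ref <- oracle_qtl_run(panel, cfg, D = 2, N = 40, G = 15, M = 2, seed = 122)
  run <- run_simulation(panel, 2, 40, 15, migrants = 2, selection = cfg,
                        seed = 122)
  expect_identical(unname(run$freqs), unname(ref$freqs))
  expect_equal(as.numeric(run$polygenic_mean), ref$polygenic_mean,
               tolerance = 1e-12)
})

test_that("the population climbs toward the shifted optimum", {
  n_sites <- 500
  cfg <- make_qtl_config(10, 0.5, n_sites = n_sites)
  p <- generate_founder_panel(100, n_sites, seed = 130)
  p <- assign_qtl_states(p, cfg, seed = 131)
  run <- run_simulation(p, 1, 500, 400, selection = cfg, seed = 132,
                        log_trajectory = TRUE)
  opt <- sum(cfg$start_freqs * cfg$effects) + 15
  traj <- run$mean_phenotype[, 1]
  expect_gt(traj[400], traj[1])               # directional response
  expect_lt(abs(traj[400] - opt), 2)          # near the optimum (within 2 SD)
  # polygenic background contributed part of the response
  expect_gt(run$polygenic_mean[1], 1)
})
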