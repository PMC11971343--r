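test_that("burst efficiencies apply corrections and the stoichiometry window", {
  b <- data.frame(n_A = c(50, 0, 30), n_D = c(50, 80, 30), S = c(0.5, 0.5, 0.1))
  be <- burst_efficiencies(b)
  expect_equal(be$E, c(0.5, 0))
  expect_equal(attr(be, "n_dropped_S"), 1)          # S = 0.1 outside (0.2, 0.75)

  cfg <- analysis_config(corrections = list(bg_A = 5, bg_D = 10, gamma = 1.2))
  b2 <- data.frame(n_A = c(55), n_D = c(110))
  be2 <- burst_efficiencies(b2, cfg)
  expect_equal(be2$E, 50 / (50 + 1.2 * 100))
  # zero signal after correction: dropped and counted
  b3 <- data.frame(n_A = c(5), n_D = c(10))
  be3 <- burst_efficiencies(b3, cfg)
  expect_equal(nrow(be3), 0)
  expect_equal(attr(be3, "n_dropped_zero"), 1)
})

test_that("Gaussian peak decomposition recovers means and areas", {
  set.seed(1)
  E1 <- rnorm(5000, 0.334, 0.05)
  fp <- fit_gaussian_peaks(E1, 1)
  expect_lt(abs(fp$mean - 0.334), 2 * 0.05 / sqrt(5000) * 3)  # generous 2 SE-ish
  set.seed(2)
  E2 <- c(rnorm(3000, 0.3, 0.04), rnorm(3000, 0.7, 0.04))
  fp2 <- fit_gaussian_peaks(E2, 2)
  expect_equal(fp2$mean, c(0.3, 0.7), tolerance = 0.01)
  expect_equal(fp2$area, c(0.5, 0.5), tolerance = 0.03)
  expect_false(any(fp2$degenerate))
  expect_error(fit_gaussian_peaks(c(0.5, 0.5, 0.5), 2), "too few")
})

test_that("1:1 mean-efficiency prediction matches a numeric equilibrium oracle", {
  expect_equal(predict_mean_E_1to1(15e-6, 0.334, 0.21, 0, 1e-10), 0.334)
  # p_tot -> 0 at g_tot = Kd: half saturation
  expect_equal(predict_mean_E_1to1(15e-6, 0.334, 0.21, 15e-6, 1e-14),
               0.334 + 0.21 / 2, tolerance = 1e-6)
  # general case vs brute-force equilibrium solve
  for (case in list(c(2e-6, 5e-6, 3e-6), c(50e-6, 20e-6, 20e-6),
                    c(1e-6, 1e-4, 1e-7))) {
    kd <- case[1]; g <- case[2]; p <- case[3]
    oracle <- brute_force_populations(kd, g, p)
    expect_lt(abs(predict_mean_E_1to1(kd, 0, 1, g, p) - oracle$p[2]), 1e-10)
  }
})

test_that("sequential population solver satisfies its invariants and matches the oracle", {
  # N = 1 reduces to the quadratic solution
  p1 <- solve_sequential_populations(15e-6, 20e-6, 1e-9)
  expect_lt(abs(p1$p[2] - predict_mean_E_1to1(15e-6, 0, 1, 20e-6, 1e-9)), 1e-13)
  # huge Kd: everything free
  p2 <- solve_sequential_populations(rep(1e3, 4), 1e-5, 1e-6)
  expect_gt(p2$p[1], 1 - 1e-6)
  # N = 4 vs independent solver
  kds <- c(2e-6, 8e-6, 30e-6, 120e-6)
  for (g in c(1e-6, 1e-5, 1e-4)) {
    s <- solve_sequential_populations(kds, g, 5e-6)
    o <- brute_force_populations(kds, g, 5e-6)
    expect_lt(max(abs(s$p - o$p)), 1e-9)
  }
  # conservation and mass balance across random conditions
  set.seed(33)
  for (i in 1:25) {
    kds_i <- 10^runif(4, -6.5, -3.5)
    g <- 10^runif(1, -7, -3); p <- 10^runif(1, -8, -4)
    s <- solve_sequential_populations(kds_i, g, p)
    expect_lt(abs(sum(s$p) - 1), 1e-10)
    mb <- abs(s$g_free + sum(seq_len(4) * s$p[-1]) * p - g)
    expect_lt(mb / max(g, 1e-300), 1e-9)
  }
})

test_that("multistate prediction reduces to 1:1 and honors the alpha profile", {
  a1 <- alpha_profile(c(0, 1))
  g <- 10^seq(-7, -4, length.out = 8)
  e_multi <- predict_mean_E_multistate(15e-6, a1, 0.334, 0.21, g, rep(1e-10, 8))
  e_11 <- predict_mean_E_1to1(15e-6, 0.334, 0.21, g, rep(1e-10, 8))
  expect_equal(e_multi, e_11, tolerance = 1e-10)
  expect_equal(predict_mean_E_multistate(c(1e-6, 1e-5), alpha_profile(c(0, 0.8, 1)),
                                         0.3, 0.2, 0, 1e-9), 0.3)
  expect_error(alpha_profile(c(0.1, 1)), "alpha_0")
  expect_error(alpha_profile(c(0, 0.9, 0.8, 1)), "non-decreasing")
})

test_that("mean efficiency is monotone in ligand for positive saturation change", {
  g <- 10^seq(-8, -3, length.out = 40)
  e <- predict_mean_E_1to1(15e-6, 0.334, 0.21, g, rep(1e-10, 40))
  expect_true(all(diff(e) > 0))
})

test_that("titration fitting recovers the truth with calibrated uncertainties", {
  des <- titration_design()
  # noiseless: exact
  ts0 <- make_titration(17e-6, g_tot_M = des$g_tot, p_tot_M = des$p_tot,
                        noise_sd = 0, seed = 1)
  f0 <- fit_titration(ts0)
  expect_rel(f0$parameters$estimate[1], 17e-6, 1e-6)
  # simulation study: 50 seeds at noise 0.005
  kds <- ses <- numeric(50)
  for (s in 1:50) {
    ts <- make_titration(17e-6, g_tot_M = des$g_tot, p_tot_M = des$p_tot,
                         noise_sd = 0.005, seed = s)
    f <- fit_titration(ts)
    kds[s] <- f$parameters$estimate[1]; ses[s] <- f$parameters$se[1]
  }
  expect_rel(mean(kds), 17e-6, 0.05)                 # mean within 5%
  expect_rel(mean(ses), sd(kds), 0.30)               # SE calibration within 30%
  expect_error(fit_titration(ts0[1:3, ]), ">= 4 points")
})

test_that("the 1:4 model fit flags overparameterized constants", {
  des <- titration_design(16)
  kds <- c(15e-6, 60e-6, 2.4e-4, 1e-3)
  ts <- make_titration(kds, g_tot_M = des$g_tot, p_tot_M = des$p_tot,
                       noise_sd = 0.005, seed = 8)
  f <- fit_titration(ts, model = "multistate")
  p <- f$parameters
  # the first binding step and efficiencies are identified...
  expect_false(p$overparameterized[p$parameter == "kd_1"])
  expect_false(p$overparameterized[p$parameter == "E0"])
  # ...and at least one higher constant is not
  expect_true(any(p$overparameterized[p$parameter %in% c("kd_2", "kd_3", "kd_4")]))
  expect_rel(p$estimate[p$parameter == "kd_1"], 15e-6, 0.5)
})

test_that("population-curve fitting recovers sequential constants", {
  kds <- c(2e-6, 8e-6, 30e-6, 120e-6)
  p_tot <- 1e-6
  g_grid <- 10^seq(-7, -3, length.out = 12)
  pops <- do.call(rbind, lapply(g_grid, function(g) {
    p <- solve_sequential_populations(kds, g, p_tot)$p
    data.frame(g_tot_M = g, state = 0:4, fraction = p)
  }))
  fit0 <- fit_population_curves(pops, N = 4, p_tot_M = p_tot, start = kds * 2)
  expect_equal(fit0$estimate, kds, tolerance = 1e-6)
  # noisy recovery within 2 SE
  set.seed(21)
  popsn <- pops
  popsn$fraction <- pmin(pmax(pops$fraction + rnorm(nrow(pops), 0, 0.01), 0), 1)
  popsn$se <- 0.01
  fitn <- fit_population_curves(popsn, N = 4, p_tot_M = p_tot, start = kds * 2)
  expect_true(all(abs(fitn$estimate - kds) < 3 * fitn$se | fitn$unidentifiable))
  # N = 1 reduces to the titration fit on the bound fraction
  pops1 <- do.call(rbind, lapply(g_grid, function(g) {
    p <- solve_sequential_populations(kds[1], g, p_tot)$p
    data.frame(g_tot_M = g, state = 0:1, fraction = p)
  }))
  fit1 <- fit_population_curves(pops1, N = 1, p_tot_M = p_tot)
  expect_equal(fit1$estimate, kds[1], tolerance = 1e-6)
})

test_that("anti-cooperative synthetic data yields increasing macroscopic constants", {
  # equal intrinsic site affinity k on 4 sites: macroscopic
  # K_Di = k * i / (4 - i + 1)
  k_int <- 1e-5
  kds_true <- k_int * seq_len(4) / (4 - seq_len(4) + 1)
  des <- titration_design(16)
  ts <- make_titration(kds_true, g_tot_M = des$g_tot, p_tot_M = des$p_tot,
                       noise_sd = 0, seed = 1)
  f <- fit_titration(ts, model = "multistate", start = list(kds = kds_true * 1.5))
  est <- f$parameters$estimate[1:4]
  expect_true(all(diff(est) > 0))
})

test_that("salt-dependence fit returns the exact slope on a noiseless line", {
  ss <- make_salt_series(1e-6, 4.6, c(0.02, 0.06, 0.2, 0.6, 2),
                         noise_sd_log = 0, seed = 1)
  fit <- fit_salt_dependence(ss)
  expect_equal(fit$ions_released, 4.6, tolerance = 1e-12)
  # noisy: truth inside the 90% CI (checked across a few seeds)
  hits <- 0
  for (s in 1:10) {
    ssn <- make_salt_series(1e-6, 4.6, c(0.06, 0.09, 0.13, 0.18, 0.24, 0.3),
                            noise_sd_log = 0.05, seed = s)
    ci <- fit_salt_dependence(ssn)$ci90
    hits <- hits + (ci[1] <= 4.6 && 4.6 <= ci[2])
  }
  expect_gte(hits, 8)
  expect_error(fit_salt_dependence(salt_series(c(0.1, 0.2), c(1e-6, 1e-5))),
               "3 distinct")
})
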