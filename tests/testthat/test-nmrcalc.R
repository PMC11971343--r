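test_that("chemical shift perturbations follow the weighted-distance formula", {
  free <- data.frame(residue = 1:4, delta_H_ppm = c(8, 8.1, 8.2, 8.3),
                     delta_N_ppm = c(120, 121, 122, 123))
  same <- compute_csp(free, free)
  expect_equal(same$csp_ppm, rep(0, 4))
  bound <- free
  bound$delta_H_ppm <- bound$delta_H_ppm + 0.01
  bound$delta_N_ppm <- bound$delta_N_ppm + 0.1
  csp <- compute_csp(free, bound)
  expect_equal(csp$csp_ppm, rep(sqrt(0.01^2 + (0.154 * 0.1)^2), 4),
               tolerance = 1e-12)
  expect_equal(csp$csp_ppm[1], 0.0183619, tolerance = 1e-5) # hand evaluation
  # homogeneity: doubling a nitrogen-only perturbation doubles the CSP
  b1 <- free; b1$delta_N_ppm <- b1$delta_N_ppm + 0.1
  b2 <- free; b2$delta_N_ppm <- b2$delta_N_ppm + 0.2
  expect_equal(compute_csp(free, b2)$csp_ppm, 2 * compute_csp(free, b1)$csp_ppm)
  # invariance to a global reference offset applied to both states
  off_f <- free; off_b <- bound
  off_f$delta_H_ppm <- off_f$delta_H_ppm + 0.3; off_b$delta_H_ppm <- off_b$delta_H_ppm + 0.3
  off_f$delta_N_ppm <- off_f$delta_N_ppm + 2; off_b$delta_N_ppm <- off_b$delta_N_ppm + 2
  expect_equal(compute_csp(off_f, off_b)$csp_ppm, csp$csp_ppm)
  # missing residues flagged, not imputed
  csp_m <- compute_csp(free, bound[1:2, ])
  expect_equal(nrow(csp_m), 2)
  expect_equal(attr(csp_m, "missing"), c(3, 4))
  expect_error(compute_csp(free, data.frame(residue = 99, delta_H_ppm = 8,
                                            delta_N_ppm = 120)), "shared")
})

test_that("normalized CSP sum is a ratio with replicate-propagated error", {
  mk <- function(scale) data.frame(residue = 1:10,
                                   csp_ppm = scale * seq(0.01, 0.1, by = 0.01))
  expect_equal(normalized_csp_sum(mk(1), mk(1))$ratio, 1)
  expect_equal(normalized_csp_sum(mk(2), mk(1))$ratio, 2)
  # replicate spread: relative error ~ spread / sqrt(n), against a bootstrap
  set.seed(4)
  reps <- lapply(1:3, function(i) mk(1 + rnorm(1, 0, 0.05)))
  res <- normalized_csp_sum(mk(1.5), mk(1), wt_replicates = reps)
  scales <- vapply(reps, function(r) sum(r$csp_ppm) / sum(mk(1)$csp_ppm), numeric(1))
  boot <- replicate(2000, {
    res$ratio * sd(sample(scales, replace = TRUE)) / mean(scales) / sqrt(3)
  })
  expect_lt(abs(res$se - res$ratio * sd(scales) / mean(scales) / sqrt(3)), 1e-12)
  expect_lt(abs(res$se - mean(boot)) / res$se, 1)     # same scale as bootstrap
  expect_error(normalized_csp_sum(mk(1), mk(0)), "zero")
})

test_that("exponential decay fitting recovers relaxation rates", {
  delays <- c(34, 68, 102, 136, 204, 271, 407, 475, 543) / 1000  # R2 grid, s
  I <- 100 * exp(-3.1 * delays)
  f <- fit_exponential_decay(delays, I)
  expect_rel(f$rate_s, 3.1, 1e-8)
  # 2% noise, triplicates: within 2 SE
  set.seed(6)
  d3 <- rep(delays, 3)
  I3 <- 100 * exp(-3.1 * d3) * (1 + rnorm(length(d3), 0, 0.02))
  f3 <- fit_exponential_decay(d3, I3)
  expect_lt(abs(f3$rate_s - 3.1), 2.5 * f3$rate_se)
  # constant signal: flagged
  expect_warning(fc <- fit_exponential_decay(delays, rep(50, length(delays))),
                 "zero")
  expect_true(fc$flagged)
  expect_error(fit_exponential_decay(c(0.1, 0.2), c(1, 0.5)), ">= 3")
})

test_that("orientation correlation matches P2 behavior", {
  # static vector: C(t) = 1
  v_static <- nh_vectors(array(rep(c(1, 0, 0), each = 100),
                               dim = c(100, 3, 1)), dt_ps = 5)
  cs <- orientation_correlation(v_static, 1, max_lag = 20)
  expect_equal(cs$C, rep(1, 21), tolerance = 1e-12)
  # tumbling fixture: matches exp(-t/tau_c); bounded in [-0.5, 1]
  fx <- tumbling_fixture()
  corr <- fx$corr_1
  expect_true(all(corr$C <= 1 + 1e-9 & corr$C >= -0.5 - 1e-9))
  sel <- corr$lag_ns <= 3 * fx$tau_c_ns
  expect_lt(max(abs(corr$C[sel] - exp(-corr$lag_ns[sel] / fx$tau_c_ns))), 0.15)
})

test_that("spectral model fitting is exact on synthetic multi-exponentials", {
  t_ns <- seq(0, 50, by = 0.025)
  # single exponential: one dominant component
  C1 <- 0.9 * exp(-t_ns / 4)
  sm1 <- fit_spectral_model(data.frame(lag_ns = t_ns, C = C1))
  dom <- which.max(sm1$a)
  expect_rel(sm1$a[dom], 0.9, 1e-4)
  expect_rel(sm1$tau_ns[dom], 4, 1e-4)
  expect_lt(sum(sm1$a[-dom]), 1e-5)
  # triple exponential: parameters recovered
  a_t <- c(0.2, 0.3, 0.45); tau_t <- c(0.05, 1.2, 8)
  C3 <- vapply(t_ns, function(t) sum(a_t * exp(-t / tau_t)), numeric(1))
  sm3 <- fit_spectral_model(data.frame(lag_ns = t_ns, C = C3))
  expect_equal(sort(sm3$tau_ns), sort(tau_t), tolerance = 1e-4)
  expect_equal(sort(sm3$a), sort(a_t), tolerance = 1e-4)
  # J(0) equals 2 sum a_k tau_k and matches quadrature of the fitted curve
  J0 <- sm3$J(0)
  expect_rel(J0, 2 * sum(a_t * tau_t * 1e-9), 1e-6)
  quad <- 2 * integrate(function(t) vapply(t, function(ti)
    sum(sm3$a * exp(-ti / (sm3$tau_ns * 1e-9))), numeric(1)),
    0, Inf)$value
  expect_lt(abs(J0 - quad), 1e-8)
})

test_that("relaxation formulas obey their analytic limits and an independent oracle", {
  cst <- relax_constants(750)
  # extreme narrowing with no CSA: R1 = R2
  flatJ <- list(J = function(w) rep(2 * 1e-12, length(w)))
  cst0 <- cst; cst0$C <- 0
  rn <- relaxation_rates(flatJ, cst0)
  expect_rel(rn$R2_s, rn$R1_s, 1e-3)
  # extreme narrowing NOE limit: 1 + gammaH/(2 gammaN)
  expect_rel(rn$hetNOE, 1 + cst$gamma_H / (2 * cst$gamma_N), 1e-3)
  expect_lt(rn$hetNOE, 0)
  # Lorentzian with tau_c = 5 ns vs a literal re-implementation
  tau <- 5e-9
  r <- relaxation_rates(list(J = lorentzian_J(tau)), cst)
  J <- function(w) 2 * tau / (1 + (w * abs(tau))^2)
  wH <- cst$omega_H; wN <- cst$omega_N; D <- cst$D; C <- cst$C
  R1_ref <- D * (J(abs(wH - wN)) + 3 * J(abs(wN)) + 6 * J(abs(wH + wN))) + C * J(abs(wN))
  R2_ref <- D / 2 * (4 * J(0) + J(abs(wH - wN)) + 3 * J(abs(wN)) + 6 * J(abs(wH)) +
                       6 * J(abs(wH + wN))) + C / 6 * (4 * J(0) + 3 * J(abs(wN)))
  noe_ref <- 1 + D * (cst$gamma_H / cst$gamma_N) / R1_ref *
    (6 * J(abs(wH + wN)) - J(abs(wH - wN)))
  expect_lt(abs(r$R1_s - R1_ref), 1e-10)
  expect_lt(abs(r$R2_s - R2_ref), 1e-10)
  expect_lt(abs(r$hetNOE - noe_ref), 1e-10)
})

test_that("the back-calculation pipeline reproduces Lorentzian rates at both fields", {
  fx <- tumbling_fixture()
  sm <- fit_spectral_model(fx$corr_avg)
  for (field in c(600, 750)) {
    cst <- relax_constants(field)
    got <- relaxation_rates(sm, cst)
    want <- relaxation_rates(list(J = lorentzian_J(fx$tau_c_ns * 1e-9)), cst)
    expect_rel(got$R1_s, want$R1_s, 0.05)
    expect_rel(got$R2_s, want$R2_s, 0.05)
    expect_rel(got$hetNOE, want$hetNOE, 0.05)
  }
})

test_that("block uncertainty matches i.i.d. statistics and defaults to 10 blocks", {
  # identical blocks: zero error
  v <- nh_vectors(array(rep(c(0, 0, 1), each = 200), dim = c(200, 3, 1)), 5)
  bu <- block_uncertainty(v, function(b) 1.0)
  expect_equal(bu$sigma_M, 0)
  expect_equal(nrow(bu$blocks), 10)                  # default block count
  # i.i.d. Gaussian block values: sigma_M ~ sd / sqrt(10)
  set.seed(9)
  vals <- rnorm(10)
  i <- 0
  bu2 <- block_uncertainty(v, function(b) { i <<- i + 1; vals[i] })
  pop_sd <- sqrt(mean((vals - mean(vals))^2))
  expect_equal(bu2$sigma_M, pop_sd / sqrt(10), tolerance = 1e-12)
  expect_error(block_uncertainty(v, length, n_blocks = 300), "shorter")
})
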