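# Shared fixtures; expensive ones are built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixtures)) assign(key, build(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Isotropic-tumbling bond vectors (tau_c = 5 ns) with residue-averaged
# orientation correlation, used by both the unit and acceptance tests.
tumbling_fixture <- function() {
  memo("tumbling", function() {
    v <- make_tumbling_vectors(tau_c_ns = 5, dt_ps = 5, n_steps = 2e5,
                               n_residues = 8, seed = 42)
    corrs <- lapply(v$residues, function(r) orientation_correlation(v, r, max_lag = 3000))
    C_avg <- Reduce(`+`, lapply(corrs, `[[`, "C")) / length(corrs)
    list(traj = v,
         corr_avg = data.frame(lag_ns = corrs[[1]]$lag_ns, C = C_avg),
         corr_1 = corrs[[1]],
         tau_c_ns = 5)
  })
}

# Closed-form Lorentzian spectral density for a single correlation time.
lorentzian_J <- function(tau_c_s) {
  function(omega) 2 * tau_c_s / (1 + (omega * tau_c_s)^2)
}

# Independent brute-force equilibrium solver for sequential 1:N binding:
# solves for free [G] with uniroot on the raw mass balance, populations
# from the definition of the stepwise constants. Shares no code with
# solve_sequential_populations beyond arithmetic.
brute_force_populations <- function(kds, g_tot, p_tot) {
  N <- length(kds)
  pops <- function(g) {
    w <- numeric(N + 1); w[1] <- 1
    for (i in seq_len(N)) w[i + 1] <- w[i] * g / kds[i]
    w / sum(w)
  }
  if (g_tot == 0) return(list(p = pops(0), g_free = 0))
  f <- function(g) g + sum(seq_len(N) * pops(g)[-1]) * p_tot - g_tot
  g <- uniroot(f, c(0, g_tot), tol = .Machine$double.eps * g_tot)$root
  list(p = pops(g), g_free = g)
}

# Default titration design: log-spaced ligand series over the transition
# with trace labeled chain, as in an excess titration.
titration_design <- function(n = 12) {
  list(g_tot = 10^seq(-7, -3.5, length.out = n), p_tot = rep(1e-10, n))
}

expect_rel <- function(x, target, tol) {
  expect_true(abs(x / target - 1) < tol,
              label = sprintf("%.6g vs %.6g (rel dev %.3g, tol %.3g)",
                              x, target, abs(x / target - 1), tol))
}
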