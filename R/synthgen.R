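# Seeded synthetic-data generators with the statistical structure each
# analysis stage assumes. Every generator records its true parameters
# in the "truth" attribute of the output.

with_truth <- function(x, truth, seed) {
  attr(x, "truth") <- truth
  attr(x, "seed") <- seed
  x
}

#' Synthetic FRET titration
#'
#' Mean transfer efficiencies from the 1:1 model (or the sequential 1:N
#' model with a fixed alpha profile) plus i.i.d. Gaussian noise.
#'
#' @param kd_app dissociation constant (mol/L) for the 1:1 model, or a
#'   vector K_D1..K_DN for the sequential model.
#' @param E0 free-chain mean transfer efficiency.
#' @param dE_sat saturated efficiency change.
#' @param g_tot_M,p_tot_M total concentrations per point, mol/L.
#' @param noise_sd Gaussian noise SD in efficiency units.
#' @param seed integer seed.
#' @param alpha [alpha_profile()] when length(kd_app) > 1.
#' @return [titration_series()] with truth attributes.
#' @export
make_titration <- function(kd_app, E0 = 0.334, dE_sat = 0.21,
                           g_tot_M, p_tot_M, noise_sd = 0.005, seed = 1L,
                           alpha = alpha_profile()) {
  check_nonneg(g_tot_M, "g_tot_M")
  check_nonneg(noise_sd, "noise_sd")
  mu <- if (length(kd_app) == 1L)
    predict_mean_E_1to1(kd_app, E0, dE_sat, g_tot_M, p_tot_M)
  else
    predict_mean_E_multistate(kd_app, as.numeric(alpha), E0, dE_sat,
                              g_tot_M, p_tot_M)
  set.seed(seed)
  eps <- if (noise_sd > 0) rnorm(length(mu), 0, noise_sd) else 0
  ts <- titration_series(g_tot_M, p_tot_M, mu + eps,
                         rep(max(noise_sd, 1e-6), length(mu)))
  with_truth(ts, list(kd = kd_app, E0 = E0, dE_sat = dE_sat,
                      noise_sd = noise_sd), seed)
}

#' Synthetic salt-dependence series
#'
#' log10 Kd linear in log10 ionic strength with slope \code{n_ions}
#' (ions released) plus Gaussian noise in log space, anchored at
#' \code{kd_ref} for the first ionic strength.
#'
#' @param kd_ref Kd at the reference (first) ionic strength, mol/L.
#' @param n_ions slope: counterions released.
#' @param ionic_strengths_M ionic strengths (> 0, >= 2 values), mol/L.
#' @param noise_sd_log Gaussian noise SD in log10 units.
#' @param seed integer seed.
#' @return [salt_series()] with truth attributes.
#' @export
make_salt_series <- function(kd_ref, n_ions, ionic_strengths_M,
                             noise_sd_log = 0.05, seed = 1L) {
  check_positive(ionic_strengths_M, "ionic_strengths_M")
  if (length(unique(ionic_strengths_M)) < 2L)
    stop_input("need >= 2 distinct ionic strengths for a slope to be fittable")
  set.seed(seed)
  l0 <- log10(ionic_strengths_M[1])
  lkd <- log10(kd_ref) + n_ions * (log10(ionic_strengths_M) - l0) +
    rnorm(length(ionic_strengths_M), 0, noise_sd_log)
  kd <- 10^lkd
  ss <- salt_series(ionic_strengths_M, kd, kd * log(10) * max(noise_sd_log, 1e-6))
  with_truth(ss, list(kd_ref = kd_ref, n_ions = n_ions,
                      noise_sd_log = noise_sd_log), seed)
}

#' Synthetic isotropically tumbling bond vectors
#'
#' Unit vectors evolved by isotropic rotational diffusion with
#' D_rot = 1/(6 tau_c), so the P2 orientation correlation decays as
#' exp(-t/tau_c). Each residue is an independent realization. The
#' integration step must satisfy dt <= tau_c/50 (enforced) to keep the
#' small-step discretization error below statistical error.
#'
#' @param tau_c_ns rotational correlation time, ns.
#' @param dt_ps sampling interval, ps.
#' @param n_steps steps per residue.
#' @param n_residues independent vector trajectories.
#' @param seed integer seed.
#' @return [nh_vectors()] object with truth attributes; warns when the
#'   trajectory is shorter than 10 tau_c.
#' @export
make_tumbling_vectors <- function(tau_c_ns, dt_ps, n_steps, n_residues = 1L,
                                  seed = 1L) {
  check_positive(tau_c_ns, "tau_c_ns")
  check_positive(dt_ps, "dt_ps")
  dt_ns <- dt_ps / 1000
  if (dt_ns > tau_c_ns / 50)
    stop_input("dt must satisfy dt <= tau_c/50 (got dt = %g ns, tau_c = %g ns)",
               dt_ns, tau_c_ns)
  if (n_steps * dt_ns < 10 * tau_c_ns)
    warning("trajectory shorter than 10 tau_c: poor correlation statistics",
            call. = FALSE)
  D <- 1 / (6 * tau_c_ns)              # 1/ns
  sdk <- sqrt(2 * D * dt_ns)
  set.seed(seed)
  vec <- array(0, dim = c(n_steps, 3, n_residues))
  v <- matrix(rnorm(3 * n_residues), n_residues, 3)
  v <- v / sqrt(rowSums(v^2))
  for (t in seq_len(n_steps)) {
    vec[t, , ] <- t(v)
    kick <- matrix(rnorm(3 * n_residues, sd = sdk), n_residues, 3)
    # remove the component along v: pure rotation, no stretching bias
    kick <- kick - v * rowSums(kick * v)
    v <- v + kick
    v <- v / sqrt(rowSums(v^2))
  }
  nh <- nh_vectors(vec, dt_ps)
  with_truth(nh, list(tau_c_ns = tau_c_ns, D_rot = D), seed)
}

#' Synthetic Ornstein-Uhlenbeck distance trace
#'
#' Exact-discretization OU series with stationary mean/SD and
#' autocorrelation time \code{relax_time_ns} (no Euler error: the
#' update uses phi = exp(-dt/tau) and innovation SD sd*sqrt(1-phi^2)).
#'
#' @param mean_nm stationary mean, nm.
#' @param sd_nm stationary standard deviation, nm (> 0; use a tiny
#'   value for an effectively constant trace).
#' @param relax_time_ns autocorrelation time, ns.
#' @param dt_ns sampling interval, ns.
#' @param n_steps length of the series.
#' @param seed integer seed.
#' @return numeric vector with attributes \code{dt_ns}, truth and seed.
#' @export
make_ou_trace <- function(mean_nm, sd_nm, relax_time_ns, dt_ns, n_steps,
                          seed = 1L) {
  check_positive(sd_nm, "sd_nm")
  check_positive(relax_time_ns, "relax_time_ns")
  check_positive(dt_ns, "dt_ns")
  phi <- exp(-dt_ns / relax_time_ns)
  set.seed(seed)
  innov <- rnorm(n_steps, 0, sd_nm * sqrt(1 - phi^2))
  innov[1] <- rnorm(1, 0, sd_nm)       # stationary start
  x <- as.numeric(stats::filter(innov, phi, method = "recursive")) + mean_nm
  attr(x, "dt_ns") <- dt_ns
  with_truth(x, list(mean_nm = mean_nm, sd_nm = sd_nm,
                     relax_time_ns = relax_time_ns), seed)
}

#' Synthetic two-chain trajectory with scripted contact episodes
#'
#' Builds coordinates for two single-atom-per-residue chains where each
#' listed residue pair sits at 0.3 nm (inside the formation cutoff)
#' during its episode, at 1.5 nm (beyond the breaking cutoff) outside,
#' with one ramp frame at 0.6 nm (inside the hysteresis band)
#' immediately before formation and after breaking. An episode
#' \code{c(start, end)} in 0-based frames yields a detected lifetime of
#' (end - start) frames.
#'
#' @param episodes list of lists with \code{res_a}, \code{res_b}
#'   (residue numbers on chains A and B), \code{start}, \code{end}
#'   (0-based frames; in contact on [start, end), broken at end).
#'   Episodes for the same pair must not overlap.
#' @param n_frames total frames.
#' @param dt_ps frame interval, ps.
#' @param n_res_a,n_res_b residues per chain.
#' @param band_nm distance used for ramp frames inside the hysteresis
#'   band (default 0.6).
#' @return [trajectory_frames()] with truth attributes.
#' @export
make_contact_frames <- function(episodes, n_frames, dt_ps = 5,
                                n_res_a = 4L, n_res_b = 4L, band_nm = 0.6) {
  keys <- vapply(episodes, function(e) paste(e$res_a, e$res_b), "")
  for (k in unique(keys)) {
    eps <- episodes[keys == k]
    if (length(eps) > 1) {
      iv <- t(vapply(eps, function(e) c(e$start, e$end), numeric(2)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] < iv[-nrow(iv), 2] + 2))
        stop_input("overlapping (or unseparated) episodes for pair %s", k)
    }
  }
  # chain A along x at y = 0; chain B along x at a large y offset
  spacing <- 3
  far <- 50
  atoms <- data.frame(
    resid = c(seq_len(n_res_a), seq_len(n_res_b)),
    resname = "GLY", atomname = "CA",
    chain = rep(c("A", "B"), c(n_res_a, n_res_b)),
    element = "C", stringsAsFactors = FALSE)
  base <- rbind(cbind((seq_len(n_res_a) - 1) * spacing, 0, 0),
                cbind((seq_len(n_res_b) - 1) * spacing, far, 0))
  coords <- array(rep(base, n_frames), dim = c(nrow(base), 3, n_frames))
  for (e in episodes) {
    ib <- n_res_a + e$res_b
    ax <- base[e$res_a, 1]
    place <- function(frame, dist) {
      f <- frame + 1L                   # 0-based frame -> index
      if (f >= 1 && f <= n_frames) coords[ib, , f] <<- c(ax, dist, 0)
    }
    if (e$start > 0) place(e$start - 1L, band_nm)   # approach through band
    for (fr in e$start:(e$end - 1L)) place(fr, 0.3)
    place(e$end, 1.5)                               # first frame beyond break
  }
  traj <- trajectory_frames(coords, dt_ps, atoms)
  with_truth(traj, list(episodes = episodes, dt_ps = dt_ps), NA_integer_)
}

#' Synthetic umbrella-sampling windows
#'
#' Per-window samples drawn from the Boltzmann distribution of a free
#' energy profile plus harmonic bias by Metropolis random-walk
#' sampling.
#'
#' @param potential function of r (nm) returning free energy in kJ/mol.
#' @param centers window centers, nm.
#' @param k spring constant, kJ/mol/nm^2.
#' @param n_per_window samples kept per window.
#' @param temperature_K temperature, K.
#' @param seed integer seed.
#' @param burn,thin Metropolis burn-in and thinning.
#' @param r_min lower bound of the coordinate domain (default 0,
#'   reflecting).
#' @return [umbrella_set()] with truth attributes.
#' @export
make_umbrella_samples <- function(potential, centers, k = 10,
                                  n_per_window = 2000L, temperature_K = 283,
                                  seed = 1L, burn = 500L, thin = 2L,
                                  r_min = 0) {
  check_positive(k, "k")
  kT <- KB_KJ * temperature_K
  set.seed(seed)
  windows <- lapply(centers, function(cen) {
    u <- function(r) potential(r) + k / 2 * (r - cen)^2
    sig <- sqrt(kT / k)                 # bias width sets the step scale
    x <- max(cen, r_min + sig)
    ux <- u(x)
    n_iter <- burn + n_per_window * thin
    prop <- rnorm(n_iter, 0, sig)
    uacc <- runif(n_iter)
    keep <- numeric(n_per_window)
    ik <- 0L
    for (i in seq_len(n_iter)) {
      xn <- x + prop[i]
      if (xn < r_min) xn <- 2 * r_min - xn
      un <- u(xn)
      if (uacc[i] < exp(-(un - ux) / kT)) { x <- xn; ux <- un }
      if (i > burn && (i - burn) %% thin == 0L) { ik <- ik + 1L; keep[ik] <- x }
    }
    list(center = cen, k = k, samples = keep)
  })
  us <- umbrella_set(windows, temperature_K)
  with_truth(us, list(k = k, centers = centers,
                      temperature_K = temperature_K), seed)
}

#' Synthetic two-state denaturation curve
#'
#' Signal from the two-state chemical (linear extrapolation) or thermal
#' (van't Hoff) equation plus Gaussian noise.
#'
#' @param mode \code{"thermal"} or \code{"chemical"}.
#' @param true_params named list. Thermal: \code{mN, yN, mD, yD, dH}
#'   (kJ/mol), \code{Tm} (K). Chemical: \code{aN, bN, aD, bD, m}
#'   (kJ/mol/M), \code{cm} (mol/L), optional \code{temperature_K}.
#' @param x_grid monotone x values (K or mol/L).
#' @param noise_sd Gaussian noise SD, signal units.
#' @param seed integer seed.
#' @return [cd_curve()] with truth attributes.
#' @export
make_denaturation_curve <- function(mode = c("thermal", "chemical"),
                                    true_params, x_grid, noise_sd = 0.5,
                                    seed = 1L) {
  if (!is.character(mode) || !all(mode %in% c("thermal", "chemical")))
    stop_input("unknown mode '%s'", paste(mode, collapse = ","))
  mode <- match.arg(mode)
  if (is.unsorted(x_grid) && is.unsorted(rev(x_grid)))
    stop_input("x_grid must be monotone")
  tp <- true_params
  mu <- if (mode == "thermal")
    two_state_thermal(x_grid, tp$mN, tp$yN, tp$mD, tp$yD, tp$dH, tp$Tm)
  else
    two_state_chemical(x_grid, tp$aN, tp$bN, tp$aD, tp$bD, tp$m, tp$cm,
                       tp$temperature_K %||% 298.15)
  set.seed(seed)
  eps <- if (noise_sd > 0) rnorm(length(mu), 0, noise_sd) else 0
  cc <- cd_curve(x_grid, mu + eps, mode = mode)
  if (mode == "chemical")
    attr(cc, "temperature_K") <- tp$temperature_K %||% 298.15
  with_truth(cc, c(tp, list(noise_sd = noise_sd)), seed)
}

#' Synthetic nsFCS correlograms
#'
#' Generates the three channel-pair correlation curves (acceptor and
#' donor autocorrelation, donor-acceptor cross-correlation) from the
#' short or full nsFCS model with multiplicative Gaussian noise.
#'
#' @param pars list with per-curve parameter lists \code{AA}, \code{DD},
#'   \code{AD} (see [nsfcs_model()]), shared \code{tau_cd} (s) and, for
#'   the full model, \code{tau_D} and \code{s}.
#' @param lag_s lag-time grid, seconds.
#' @param model \code{"short"} or \code{"full"}.
#' @param noise_frac relative Gaussian noise on g - 1.
#' @param seed integer seed.
#' @return data.frame with columns \code{lag_s}, \code{g_AA},
#'   \code{g_DD}, \code{g_AD} and truth attributes.
#' @export
make_nsfcs_curves <- function(pars, lag_s, model = c("short", "full"),
                              noise_frac = 0, seed = 1L) {
  model <- match.arg(model)
  set.seed(seed)
  out <- data.frame(lag_s = lag_s)
  for (ch in c("AA", "DD", "AD")) {
    g <- nsfcs_curve(pars[[ch]], lag_s, pars$tau_cd, model,
                     pars$tau_D, pars$s)
    if (noise_frac > 0) g <- 1 + (g - 1) * (1 + rnorm(length(g), 0, noise_frac))
    out[[paste0("g_", ch)]] <- g
  }
  with_truth(out, pars, seed)
}
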