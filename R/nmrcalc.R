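# Chemical-shift perturbation metrics and 15N relaxation: experimental
# decay fitting and back-calculation of R1/R2/hetNOE from amide
# bond-vector trajectories.

#' Amide chemical shift perturbations
#'
#' Weighted combined 1H/15N perturbation per residue,
#' d_NH = sqrt(dH^2 + (0.154 dN)^2), between a free and a bound state.
#' Residues present in only one state are reported in the
#' \code{missing} attribute, never imputed.
#'
#' @param free,bound data.frames with columns \code{residue},
#'   \code{delta_H_ppm}, \code{delta_N_ppm}.
#' @param n_weight nitrogen scaling factor (default 0.154).
#' @return data.frame: \code{residue}, \code{d_H}, \code{d_N},
#'   \code{csp_ppm}; attribute \code{missing} lists residues without a
#'   match.
#' @export
compute_csp <- function(free, bound, n_weight = 0.154) {
  shared <- intersect(free$residue, bound$residue)
  if (!length(shared)) stop_input("no shared residues between states")
  fi <- match(shared, free$residue); bi <- match(shared, bound$residue)
  dH <- bound$delta_H_ppm[bi] - free$delta_H_ppm[fi]
  dN <- bound$delta_N_ppm[bi] - free$delta_N_ppm[fi]
  out <- data.frame(residue = shared, d_H = dH, d_N = dN,
                    csp_ppm = sqrt(dH^2 + (n_weight * dN)^2))
  attr(out, "missing") <- sort(c(setdiff(free$residue, shared),
                                 setdiff(bound$residue, shared)))
  out
}

#' Normalized CSP sum of a variant relative to wild type
#'
#' Ratio of the summed CSPs induced by a ligand variant to the summed
#' CSPs induced by the wild-type ligand at the same stoichiometric
#' ratio, computed over the shared residue set. The error is propagated
#' from the spread over replicate wild-type titrations: the relative
#' standard error of the wild-type sum, sd/mean/sqrt(n_replicates), is
#' applied to the ratio.
#'
#' @param variant_csp data.frame from [compute_csp()] for the variant.
#' @param wt_csp reference wild-type CSP table at the same molar ratio.
#' @param wt_replicates optional list of CSP tables from independent
#'   wild-type titrations used for the error estimate.
#' @return list: \code{ratio}, \code{se}, \code{n_residues},
#'   \code{wt_sum}.
#' @export
normalized_csp_sum <- function(variant_csp, wt_csp, wt_replicates = NULL) {
  shared <- intersect(variant_csp$residue, wt_csp$residue)
  if (!length(shared)) stop_input("no shared residues")
  v_sum <- sum(variant_csp$csp_ppm[match(shared, variant_csp$residue)])
  w_sum <- sum(wt_csp$csp_ppm[match(shared, wt_csp$residue)])
  if (w_sum == 0) stop_input("wild-type CSP sum is zero; ratio undefined")
  ratio <- v_sum / w_sum
  se <- NA_real_
  if (!is.null(wt_replicates) && length(wt_replicates) >= 2) {
    sums <- vapply(wt_replicates, function(tab) {
      sh <- intersect(shared, tab$residue)
      sum(tab$csp_ppm[match(sh, tab$residue)])
    }, numeric(1))
    rel <- sd(sums) / mean(sums) / sqrt(length(sums))
    se <- ratio * rel
  }
  list(ratio = ratio, se = se, n_residues = length(shared), wt_sum = w_sum)
}

#' Fit a single-exponential relaxation decay
#'
#' Nonlinear least squares of I(t) = I0 exp(-R t) to peak intensities
#' versus relaxation delay; replicate delays enter as independent
#' observations. A non-decaying signal is flagged (warning, rate CI
#' containing zero).
#'
#' @param delay_s relaxation delays, seconds.
#' @param intensity peak intensities.
#' @return list: \code{rate_s} (1/s), \code{rate_se}, \code{I0},
#'   \code{I0_se}, \code{flagged} (TRUE when the 95% CI on the rate
#'   includes zero), \code{fit}.
#' @export
fit_exponential_decay <- function(delay_s, intensity) {
  if (length(delay_s) < 3) stop_input("need >= 3 delays")
  pos <- intensity > 0
  r0 <- if (sum(pos) >= 2) {
    lf <- lm(log(intensity[pos]) ~ delay_s[pos])
    max(-coef(lf)[2], 1e-6)
  } else 1
  res <- minpack.lm::nls.lm(c(I0 = max(intensity), R = r0),
                            fn = function(p) intensity - p[1] * exp(-p[2] * delay_s),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  se <- nlslm_se(res)
  rate <- res$par[[2]]; rate_se <- se[2]
  flagged <- !is.finite(rate_se) || (rate - 1.96 * rate_se) <= 0
  if (flagged) warning("decay rate not distinguishable from zero", call. = FALSE)
  list(rate_s = rate, rate_se = rate_se, I0 = res$par[[1]], I0_se = se[1],
       flagged = flagged, fit = res)
}

#' Amide bond-vector trajectory container
#'
#' @param vectors array \code{[n_steps, 3, n_residues]} of N-H unit
#'   vectors (normalized within 1e-6).
#' @param dt_ps sampling interval, ps.
#' @param residues residue numbers (1-based), length n_residues.
#' @return object of class \code{nh_vectors}.
#' @export
nh_vectors <- function(vectors, dt_ps, residues = seq_len(dim(vectors)[3])) {
  check_positive(dt_ps, "dt_ps")
  norms <- sqrt(vectors[, 1, , drop = FALSE]^2 + vectors[, 2, , drop = FALSE]^2 +
                vectors[, 3, , drop = FALSE]^2)
  if (any(abs(norms - 1) > 1e-6)) stop_input("vectors must be unit length (|1 - |mu|| <= 1e-6)")
  structure(list(vectors = vectors, dt_ps = dt_ps, residues = residues),
            class = "nh_vectors")
}

#' Extract N-H bond vectors from a trajectory
#'
#' Builds per-residue amide bond unit vectors r_H - r_N from trajectory
#' frames; residues lacking either atom are skipped.
#'
#' @param traj [trajectory_frames()] object.
#' @param n_name,h_name atom names of the amide nitrogen and hydrogen
#'   (defaults "N", "H").
#' @return [nh_vectors()] object.
#' @export
nh_vectors_from_trajectory <- function(traj, n_name = "N", h_name = "H") {
  at <- traj$atoms
  res_ids <- sort(unique(at$resid))
  keep <- vapply(res_ids, function(r) {
    any(at$resid == r & at$atomname == n_name) &&
      any(at$resid == r & at$atomname == h_name)
  }, logical(1))
  res_ids <- res_ids[keep]
  if (!length(res_ids)) stop_input("no residues with both %s and %s atoms", n_name, h_name)
  nf <- n_frames(traj)
  vec <- array(0, dim = c(nf, 3, length(res_ids)))
  for (k in seq_along(res_ids)) {
    iN <- which(at$resid == res_ids[k] & at$atomname == n_name)[1]
    iH <- which(at$resid == res_ids[k] & at$atomname == h_name)[1]
    v <- t(traj$coords[iH, , ] - traj$coords[iN, , ])   # nf x 3
    v <- v / sqrt(rowSums(v^2))
    vec[, , k] <- v
  }
  nh_vectors(vec, traj$dt_ps, res_ids)
}

#' Orientation correlation function of an amide bond vector
#'
#' C(t) = < P2( mu(t'+t) . mu(t') ) > averaged over time origins, where
#' P2 is the second Legendre polynomial. Computed via FFT
#' cross-correlations of the dyadic products mu_a mu_b, which gives the
#' exact time-origin average at all lags.
#'
#' @param traj [nh_vectors()] object.
#' @param residue residue number (must be in \code{traj$residues}).
#' @param max_lag maximum lag in samples (default and cap: half the
#'   trajectory).
#' @return data.frame: \code{lag_ns}, \code{C}.
#' @export
orientation_correlation <- function(traj, residue, max_lag = NULL) {
  k <- match(residue, traj$residues)
  if (is.na(k)) stop_input("residue %s not in trajectory", residue)
  v <- traj$vectors[, , k]
  n <- nrow(v)
  max_lag <- min(max_lag %||% floor(n / 2), floor(n / 2))
  # <(mu_t . mu_0)^2> = sum_ab <m_a(t) m_b(t) m_a(0) m_b(0)>
  s2 <- 0
  for (a in 1:3) for (b in 1:3) {
    prod_ab <- v[, a] * v[, b]
    s2 <- s2 + ccf_raw_fft(prod_ab, prod_ab, max_lag)
  }
  C <- 1.5 * s2 - 0.5
  data.frame(lag_ns = (0:max_lag) * traj$dt_ps / 1000, C = C)
}

#' Fit a triple-exponential spectral model to an orientation correlation
#'
#' Constrained least squares of C(t) = sum_k a_k exp(-t / tau_k) with
#' a_k >= 0 and tau_k > 0 (k = 1..3); the spectral density is then the
#' analytic transform J(w) = 2 sum_k a_k tau_k / (1 + (w tau_k)^2). The
#' amplitude sum is left free (bounded by C at the first lag) to absorb
#' librational decay faster than the sampling interval.
#'
#' @param corr data.frame from [orientation_correlation()] (needs >= 20
#'   lags).
#' @param fit_window_ns upper lag bound for the fit; defaults to the
#'   full curve supplied.
#' @param n_exp number of exponentials (3; falls back to 2 on
#'   non-convergence, flagged).
#' @return list of class \code{spectral_model}: \code{a}, \code{tau_ns},
#'   \code{J} (function of omega in rad/s), \code{fallback} flag.
#' @export
fit_spectral_model <- function(corr, fit_window_ns = NULL, n_exp = 3L) {
  if (nrow(corr) < 20) stop_input("correlation curve needs >= 20 lags")
  if (!is.null(fit_window_ns)) corr <- corr[corr$lag_ns <= fit_window_ns, , drop = FALSE]
  t_ns <- corr$lag_ns; C <- corr$C
  span <- max(t_ns[t_ns > 0])
  try_fit <- function(ne) {
    tau0 <- span / 10^(seq(ne) - 1)      # decade-spaced guesses
    a0 <- rep(max(C[1], 0.1) / ne, ne)
    par0 <- c(log(a0), log(tau0))
    fn <- function(p) {
      a <- exp(p[seq_len(ne)]); tauv <- exp(p[ne + seq_len(ne)])
      C - rowSums(vapply(seq_len(ne), function(k) a[k] * exp(-t_ns / tauv[k]),
                         numeric(length(t_ns))))
    }
    minpack.lm::nls.lm(par0, fn = fn,
                       control = minpack.lm::nls.lm.control(maxiter = 1000))
  }
  res <- try_fit(n_exp)
  fallback <- FALSE
  if (res$info %in% c(0, 5)) {
    res <- try_fit(2L); n_exp <- 2L; fallback <- TRUE
    if (res$info %in% c(0, 5)) stop_input("spectral model fit did not converge")
  }
  a <- exp(res$par[seq_len(n_exp)])
  tau_ns <- exp(res$par[n_exp + seq_len(n_exp)])
  ord <- order(tau_ns)
  a <- a[ord]; tau_ns <- tau_ns[ord]
  # merge degenerate components (timescales within 5%): an
  # overparameterized fit may split one exponential's amplitude
  keep_a <- a[1]; keep_tau <- tau_ns[1]
  for (k in seq_along(a)[-1]) {
    j <- length(keep_tau)
    if (tau_ns[k] / keep_tau[j] < 1.05) {
      w <- c(keep_a[j], a[k])
      keep_tau[j] <- sum(w * c(keep_tau[j], tau_ns[k])) / sum(w)
      keep_a[j] <- sum(w)
    } else {
      keep_a <- c(keep_a, a[k]); keep_tau <- c(keep_tau, tau_ns[k])
    }
  }
  a <- keep_a; tau_ns <- keep_tau
  tau_s <- tau_ns * 1e-9
  J <- function(omega) {
    vapply(omega, function(w) 2 * sum(a * tau_s / (1 + (w * tau_s)^2)), numeric(1))
  }
  structure(list(a = a, tau_ns = tau_ns, J = J, fallback = fallback, fit = res),
            class = "spectral_model")
}

#' Physical constants for 15N relaxation
#'
#' Dipolar (D) and CSA (C) interaction constants and Larmor frequencies
#' at a stated proton frequency. D = (1/20) (mu0/4pi)^2 hbar^2
#' gammaH^2 gammaN^2 / r_NH^6 and C = (1/15) omegaN^2 Delta_CSA^2, with
#' CODATA gyromagnetic ratios (gammaN negative), r_NH = 0.1041 nm and
#' Delta_CSA = -170 ppm.
#'
#' @param h1_freq_MHz proton Larmor frequency in MHz (600 and 750 are
#'   the shipped presets).
#' @param r_NH_m amide bond length in m.
#' @param csa_ppm chemical shift anisotropy in ppm.
#' @return list: \code{omega_H}, \code{omega_N} (rad/s, signed),
#'   \code{D}, \code{C} (s^-2), \code{gamma_H}, \code{gamma_N}.
#' @export
relax_constants <- function(h1_freq_MHz = 750, r_NH_m = 1.041e-10,
                            csa_ppm = -170) {
  gamma_H <- 2.6752218744e8      # rad/s/T
  gamma_N <- -2.71261804e7       # rad/s/T, 15N
  mu0 <- 1.25663706212e-6
  hbar <- 1.054571817e-34
  omega_H <- 2 * pi * h1_freq_MHz * 1e6
  omega_N <- omega_H * gamma_N / gamma_H
  D <- (1 / 20) * (mu0 / (4 * pi))^2 * hbar^2 * gamma_H^2 * gamma_N^2 / r_NH_m^6
  C <- (1 / 15) * omega_N^2 * (csa_ppm * 1e-6)^2
  list(omega_H = omega_H, omega_N = omega_N, D = D, C = C,
       gamma_H = gamma_H, gamma_N = gamma_N, h1_freq_MHz = h1_freq_MHz)
}

#' 15N relaxation rates from a spectral density
#'
#' Evaluates the standard dipolar + CSA expressions for R1, R2 and the
#' steady-state heteronuclear NOE at the Larmor frequencies of the
#' stated field. The spectral density is treated as an even function.
#'
#' @param model [fit_spectral_model()] result, or any list with an
#'   element \code{J}: function of omega (rad/s).
#' @param constants [relax_constants()].
#' @return list: \code{R1_s}, \code{R2_s}, \code{hetNOE}.
#' @export
relaxation_rates <- function(model, constants = relax_constants()) {
  J <- function(w) model$J(abs(w))
  wH <- constants$omega_H; wN <- constants$omega_N
  D <- constants$D; C <- constants$C
  R1 <- D * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + C * J(wN)
  R2 <- D / 2 * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                   6 * J(wH + wN)) +
    C / 6 * (4 * J(0) + 3 * J(wN))
  noe <- 1 + D * (constants$gamma_H / constants$gamma_N) / R1 *
    (6 * J(wH + wN) - J(wH - wN))
  list(R1_s = R1, R2_s = R2, hetNOE = noe)
}

#' Back-calculate relaxation rates for every residue of a trajectory
#'
#' Full pipeline per residue: orientation correlation, triple-exponential
#' spectral fit, and rate evaluation.
#'
#' @param traj [nh_vectors()] object.
#' @param constants [relax_constants()].
#' @param max_lag_frac fraction of the trajectory length used as the
#'   maximum correlation lag (default 0.1).
#' @return data.frame: residue, R1, R2, hetNOE.
#' @export
backcalc_rates <- function(traj, constants = relax_constants(),
                           max_lag_frac = 0.1) {
  n <- dim(traj$vectors)[1]
  max_lag <- max(20L, floor(n * max_lag_frac))
  out <- lapply(traj$residues, function(res) {
    corr <- orientation_correlation(traj, res, max_lag)
    sm <- fit_spectral_model(corr)
    r <- relaxation_rates(sm, constants)
    data.frame(residue = res, R1 = r$R1_s, R2 = r$R2_s, hetNOE = r$hetNOE)
  })
  do.call(rbind, out)
}

#' Block-averaged uncertainty of a trajectory observable
#'
#' Splits the trajectory into \code{n_blocks} equal non-overlapping
#' windows, evaluates the observable pipeline on each, and reports the
#' block mean and the standard error of the mean
#' sigma_M = sqrt((<O^2> - <O>^2) / N).
#'
#' @param traj [nh_vectors()] or [trajectory_frames()] object (anything
#'   whose first data dimension indexes frames via \code{subset_fun}).
#' @param observable function taking a block of the same class and
#'   returning a numeric scalar or vector.
#' @param n_blocks number of blocks (default 10).
#' @return list: \code{mean}, \code{sigma_M}, \code{blocks} (matrix of
#'   per-block values).
#' @export
block_uncertainty <- function(traj, observable, n_blocks = 10L) {
  nf <- if (inherits(traj, "nh_vectors")) dim(traj$vectors)[1] else n_frames(traj)
  if (nf < n_blocks) stop_input("trajectory shorter than n_blocks")
  edges <- floor(seq(0, nf, length.out = n_blocks + 1))
  vals <- lapply(seq_len(n_blocks), function(b) {
    idx <- (edges[b] + 1):edges[b + 1]
    blk <- if (inherits(traj, "nh_vectors")) {
      nh_vectors(traj$vectors[idx, , , drop = FALSE], traj$dt_ps, traj$residues)
    } else {
      trajectory_frames(traj$coords[, , idx, drop = FALSE], traj$dt_ps,
                        traj$atoms, traj$box)
    }
    as.numeric(observable(blk))
  })
  m <- do.call(rbind, vals)
  mu <- colMeans(m)
  sigma_M <- sqrt(pmax(colMeans(m^2) - mu^2, 0) / n_blocks)
  list(mean = mu, sigma_M = sigma_M, blocks = m)
}
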