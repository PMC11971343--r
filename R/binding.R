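# Burst-level transfer efficiencies, histogram decomposition, binding
# models of 1:1 and sequential 1:N stoichiometry, and salt-dependence
# (counterion release) analysis.

#' Titration series container
#'
#' @param g_tot_M total ligand (globular domain) concentrations, mol/L.
#' @param p_tot_M total chain (labeled + unlabeled) concentrations, mol/L.
#' @param mean_E observed mean transfer efficiencies.
#' @param se_E standard errors of the mean efficiencies.
#' @param ionic_strength_M total ionic strength, mol/L.
#' @param mode \code{"excess"} (trace labeled chain, excess ligand) or
#'   \code{"stoichiometric"} (equimolar ligand and chain).
#' @return data.frame of class \code{titration_series}.
#' @export
titration_series <- function(g_tot_M, p_tot_M, mean_E, se_E = NULL,
                             ionic_strength_M = NA_real_,
                             mode = c("excess", "stoichiometric")) {
  mode <- match.arg(mode)
  check_nonneg(g_tot_M, "g_tot_M")
  check_nonneg(p_tot_M, "p_tot_M")
  if (any(!is.finite(mean_E))) stop_input("mean_E must be finite")
  if (is.null(se_E)) se_E <- rep(NA_real_, length(mean_E))
  df <- data.frame(g_tot_M = g_tot_M, p_tot_M = p_tot_M,
                   mean_E = mean_E, se_E = se_E)
  structure(df, ionic_strength_M = ionic_strength_M, mode = mode,
            class = c("titration_series", "data.frame"))
}

#' Burst transfer efficiencies from photon counts
#'
#' Applies background, crosstalk, direct-excitation and gamma
#' corrections to per-burst donor/acceptor counts and computes the
#' transfer efficiency E = nA'/(nA' + gamma nD'). With identity
#' corrections this is nA/(nA + nD). When a stoichiometry-ratio column
#' \code{S} is present (alternating excitation), bursts outside the
#' selection window are removed.
#'
#' @param bursts data.frame with columns \code{n_A}, \code{n_D},
#'   optionally \code{S} and \code{n_Aex} (acceptor-excitation counts
#'   entering the direct-excitation correction).
#' @param config [analysis_config()] carrying the correction factors.
#' @param s_window stoichiometry selection window, default
#'   \code{c(0.2, 0.75)}.
#' @return data.frame with columns \code{n_A}, \code{n_D}, \code{E} (and
#'   \code{S} if supplied); attributes \code{n_dropped_zero} (bursts with
#'   no signal after correction) and \code{n_dropped_S}.
#' @export
burst_efficiencies <- function(bursts, config = analysis_config(),
                               s_window = c(0.2, 0.75)) {
  if (!all(c("n_A", "n_D") %in% names(bursts)))
    stop_input("burst table needs columns n_A and n_D")
  check_nonneg(bursts$n_A, "n_A")
  check_nonneg(bursts$n_D, "n_D")
  co <- config$corrections
  n_dropped_S <- 0L
  if (!is.null(bursts$S)) {
    keep <- bursts$S > s_window[1] & bursts$S < s_window[2]
    n_dropped_S <- sum(!keep)
    bursts <- bursts[keep, , drop = FALSE]
  }
  nD <- bursts$n_D - co$bg_D
  nAex <- bursts$n_Aex %||% rep(0, nrow(bursts))
  nA <- bursts$n_A - co$bg_A - co$crosstalk * nD - co$direct_exc * nAex
  denom <- nA + co$gamma * nD
  ok <- denom > 0
  out <- bursts[ok, , drop = FALSE]
  out$E <- nA[ok] / denom[ok]
  attr(out, "n_dropped_zero") <- sum(!ok)
  attr(out, "n_dropped_S") <- n_dropped_S
  rownames(out) <- NULL
  out
}

#' Fit Gaussian peaks to a transfer-efficiency histogram
#'
#' Least-squares Gaussian mixture on binned counts, used to extract mean
#' transfer efficiencies and, at low ionic strength, the relative areas
#' of coexisting bound/unbound subpopulations. Peaks are initialized by
#' k-means on the (bin-weighted) efficiency values and reported sorted
#' by ascending mean with areas normalized to sum to 1.
#'
#' @param E burst efficiency values, or a list with \code{mids} and
#'   \code{counts} for a pre-binned histogram.
#' @param n_peaks number of Gaussian components (>= 1).
#' @param breaks histogram breaks used when \code{E} is raw values;
#'   default 0.02-wide bins on [-0.1, 1.1].
#' @return data.frame with one row per peak: \code{mean}, \code{sd},
#'   \code{area} (relative, summing to 1), \code{degenerate} flag for
#'   components with area below 1e-3; attribute \code{fit} holds the
#'   \code{nls.lm} object.
#' @export
fit_gaussian_peaks <- function(E, n_peaks = 1L,
                               breaks = seq(-0.1, 1.1, by = 0.02)) {
  if (is.list(E) && !is.null(E$mids)) {
    mids <- E$mids; counts <- E$counts
  } else {
    h <- graphics::hist(E, breaks = breaks, plot = FALSE)
    mids <- h$mids; counts <- h$counts
  }
  if (sum(counts > 0) <= 3L * n_peaks)
    stop_input("histogram has too few occupied bins for %d peak(s)", n_peaks)
  # k-means initialization on bin centers weighted by counts
  expanded <- rep(mids, pmax(round(counts / max(1, max(counts)) * 200), ifelse(counts > 0, 1, 0)))
  init_mu <- if (n_peaks == 1L) sum(mids * counts) / sum(counts) else
    sort(kmeans(expanded, centers = n_peaks, nstart = 5)$centers[, 1])
  bw <- diff(mids[1:2])
  total <- sum(counts) * bw
  par0 <- c(A = rep(log(total / n_peaks), n_peaks),
            mu = init_mu, lsd = rep(log(0.05), n_peaks))
  model <- function(p, x) {
    A <- exp(p[seq_len(n_peaks)])
    mu <- p[n_peaks + seq_len(n_peaks)]
    sdv <- exp(p[2 * n_peaks + seq_len(n_peaks)])
    rowSums(vapply(seq_len(n_peaks),
                   function(k) A[k] * dnorm(x, mu[k], sdv[k]),
                   numeric(length(x))))
  }
  res <- minpack.lm::nls.lm(par0, fn = function(p) counts - model(p, mids),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (res$info %in% c(0, 5))
    stop_input("Gaussian peak fit did not converge (info=%d, deviance=%.3g)",
               res$info, res$deviance)
  A <- exp(res$par[seq_len(n_peaks)])
  mu <- res$par[n_peaks + seq_len(n_peaks)]
  sdv <- exp(res$par[2 * n_peaks + seq_len(n_peaks)])
  ord <- order(mu)
  out <- data.frame(mean = mu[ord], sd = sdv[ord], area = (A / sum(A))[ord])
  out$degenerate <- out$area < 1e-3
  attr(out, "fit") <- res
  out
}

#' Mean transfer efficiency under the 1:1 binding model
#'
#' Closed-form bound fraction from the quadratic root of the 1:1
#' equilibrium at total concentrations \code{g_tot} and \code{p_tot},
#' scaled between the free-chain efficiency \code{E0} and the saturated
#' change \code{dE_sat}.
#'
#' @param kd_app apparent dissociation constant, mol/L.
#' @param E0 mean transfer efficiency of the free chain.
#' @param dE_sat efficiency difference between saturated and free chain.
#' @param g_tot,p_tot total concentrations, mol/L (vectorized).
#' @return predicted mean transfer efficiency.
#' @export
predict_mean_E_1to1 <- function(kd_app, E0, dE_sat, g_tot, p_tot) {
  check_positive(kd_app, "kd_app")
  check_positive(p_tot, "p_tot")
  s <- g_tot + kd_app + p_tot
  # conjugate form of (s - sqrt(s^2 - 4 g p)) / (2 p): no cancellation
  # when the bound fraction is small
  frac <- 2 * g_tot / (s + sqrt(s^2 - 4 * g_tot * p_tot))
  dE_sat * frac + E0
}

#' Populations of the sequential 1:N binding model
#'
#' Solves the coupled equilibria of sequential ligand binding
#' (macroscopic dissociation constants \code{kds[i]} for the i-th
#' binding step) under ligand mass balance by bracketed bisection on the
#' free ligand concentration in [0, g_tot].
#'
#' @param kds macroscopic dissociation constants K_D1..K_DN, mol/L.
#' @param g_tot total ligand concentration, mol/L.
#' @param p_tot total chain concentration, mol/L.
#' @param tol relative bisection tolerance on free ligand (default:
#'   machine precision).
#' @return list with \code{p} (populations p_0..p_N, summing to 1),
#'   \code{g_free}, \code{p_free}, and \code{pg} (complex concentrations
#'   [PG_1..PG_N], mol/L).
#' @export
solve_sequential_populations <- function(kds, g_tot, p_tot,
                                         tol = 2 * .Machine$double.eps) {
  check_positive(kds, "kds")
  check_nonneg(g_tot, "g_tot")
  check_positive(p_tot, "p_tot")
  N <- length(kds)
  pops <- function(g) {
    # p_i proportional to prod_{j<=i} g / K_j
    w <- cumprod(c(1, g / kds))
    w / sum(w)
  }
  residual <- function(g) {
    p <- pops(g)
    g_tot - g - sum(seq_len(N) * p[-1]) * p_tot
  }
  if (g_tot == 0) {
    g <- 0
  } else {
    lo <- 0; hi <- g_tot
    if (residual(hi) > 0) hi <- g_tot  # residual(g_tot) <= 0 always; guard
    for (it in seq_len(200)) {
      mid <- (lo + hi) / 2
      if (residual(mid) > 0) lo <- mid else hi <- mid
      if ((hi - lo) <= tol * g_tot) break
    }
    g <- (lo + hi) / 2
  }
  p <- pops(g)
  list(p = p, g_free = g, p_free = p[1] * p_tot, pg = p[-1] * p_tot)
}

#' Mean transfer efficiency under the sequential multistate model
#'
#' Population-weighted linear combination of per-stoichiometry
#' efficiencies E_i = alpha_i * dE_sat + E0, with populations from
#' [solve_sequential_populations()].
#'
#' @param kds dissociation constants K_D1..K_DN, mol/L.
#' @param alpha relative efficiency-increase profile alpha_0..alpha_N
#'   (alpha_0 = 0, alpha_N = 1, non-decreasing); see [alpha_profile()].
#' @inheritParams predict_mean_E_1to1
#' @return predicted mean transfer efficiency (vectorized over
#'   \code{g_tot}/\code{p_tot}).
#' @export
predict_mean_E_multistate <- function(kds, alpha, E0, dE_sat, g_tot, p_tot) {
  N <- length(kds)
  if (length(alpha) != N + 1L)
    stop_input("alpha must have length N+1 = %d", N + 1L)
  m <- max(length(g_tot), length(p_tot))
  g_tot <- rep_len(g_tot, m); p_tot <- rep_len(p_tot, m)
  vapply(seq_len(m), function(i) {
    p <- solve_sequential_populations(kds, g_tot[i], p_tot[i])$p
    sum(p * (alpha * dE_sat + E0))
  }, numeric(1))
}

#' Relative efficiency-increase profile for the 1:4 model
#'
#' The profile alpha_i gives the relative increase of the chain's mean
#' transfer efficiency in the 1:i complex, normalized by the difference
#' between the 1:4 complex and the free chain:
#' alpha_i = (E_i^CG - E_0^CG) / (E_4^CG - E_0^CG). The default encodes
#' the coarse-grained simulation result that the first ligand produces
#' ~80% of the total compaction, with ~11% and ~7% added by the second
#' and third.
#'
#' @param values numeric vector alpha_0..alpha_N.
#' @return validated numeric vector of class \code{alpha_profile}.
#' @export
alpha_profile <- function(values = c(0, 0.80, 0.91, 0.98, 1)) {
  if (values[1] != 0) stop_input("alpha_0 must be 0")
  if (values[length(values)] != 1) stop_input("alpha_N must be 1")
  if (any(diff(values) < 0)) stop_input("alpha must be non-decreasing")
  structure(values, class = "alpha_profile")
}

#' Fit a titration with the 1:1 or sequential multistate binding model
#'
#' Weighted nonlinear least squares of the mean transfer efficiency
#' versus total ligand concentration. For the multistate model the
#' alpha profile is fixed from input and the N dissociation constants
#' are fitted (log-parameterized) together with E0 and dE_sat;
#' parameters whose standard error exceeds the estimate are flagged as
#' unidentifiable (overparameterization diagnostic).
#'
#' @param series [titration_series()].
#' @param model \code{"1to1"} or \code{"multistate"}.
#' @param alpha [alpha_profile()] for the multistate model.
#' @param start optional named list of start values (\code{kd_app} or
#'   \code{kds}, \code{E0}, \code{dE_sat}).
#' @return list of class \code{binding_fit} with elements
#'   \code{parameters} (data.frame: parameter, estimate, se,
#'   overparameterized), \code{model}, \code{fitted}, \code{residuals}
#'   and the raw \code{nls.lm} object in \code{fit}.
#' @export
fit_titration <- function(series, model = c("1to1", "multistate"),
                          alpha = alpha_profile(), start = NULL) {
  model <- match.arg(model)
  n_par <- if (model == "1to1") 3L else length(alpha) - 1L + 2L
  if (nrow(series) < n_par)
    stop_input("need at least %d points to fit %d parameters", n_par, n_par)
  if (model == "1to1" && nrow(series) < 4L)
    stop_input("need >= 4 points spanning the transition for the 1:1 model")
  w <- if (all(is.finite(series$se_E)) && all(series$se_E > 0))
    1 / series$se_E else rep(1, nrow(series))
  E0_0 <- start$E0 %||% series$mean_E[which.min(series$g_tot_M)]
  dE_0 <- start$dE_sat %||% (max(series$mean_E) - min(series$mean_E))
  if (dE_0 == 0) dE_0 <- 0.1
  half_E <- E0_0 + dE_0 / 2
  kd_guess <- start$kd_app %||% {
    i <- which.min(abs(series$mean_E - half_E))
    max(series$g_tot_M[i], 1e-9)
  }
  if (model == "1to1") {
    par0 <- c(lkd = log(kd_guess), E0 = E0_0, dE = dE_0)
    fn <- function(p) w * (series$mean_E -
      predict_mean_E_1to1(exp(p[1]), p[2], p[3], series$g_tot_M, series$p_tot_M))
    res <- minpack.lm::nls.lm(par0, fn = fn,
                              control = minpack.lm::nls.lm.control(maxiter = 500))
    se <- nlslm_se(res)
    kd <- exp(res$par[[1]])
    kd_se <- kd * se[1]                    # delta method on log scale
    est <- c(kd_app = kd, E0 = res$par[[2]], dE_sat = res$par[[3]])
    ses <- c(kd_se, se[2], se[3])
  } else {
    N <- length(alpha) - 1L
    kds0 <- start$kds %||% (kd_guess * 4^(seq_len(N) - 1))
    par0 <- c(log(kds0), E0 = E0_0, dE = dE_0)
    fn <- function(p) w * (series$mean_E -
      predict_mean_E_multistate(exp(p[seq_len(N)]), as.numeric(alpha),
                                p[N + 1], p[N + 2],
                                series$g_tot_M, series$p_tot_M))
    res <- minpack.lm::nls.lm(par0, fn = fn,
                              control = minpack.lm::nls.lm.control(maxiter = 1000))
    se <- nlslm_se(res)
    kds <- exp(res$par[seq_len(N)])
    est <- c(setNames(kds, paste0("kd_", seq_len(N))),
             E0 = res$par[[N + 1]], dE_sat = res$par[[N + 2]])
    ses <- c(kds * se[seq_len(N)], se[N + 1], se[N + 2])
  }
  pars <- data.frame(parameter = names(est), estimate = unname(est),
                     se = unname(ses))
  pars$overparameterized <- is.na(pars$se) | pars$se > abs(pars$estimate)
  fitted <- series$mean_E - res$fvec / w
  structure(list(parameters = pars, model = model, alpha = if (model == "multistate") alpha,
                 fitted = fitted, residuals = series$mean_E - fitted, fit = res),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("binding_fit (%s model)\n", x$model))
  print(x$parameters, row.names = FALSE)
  invisible(x)
}

#' Fit sequential dissociation constants to population curves
#'
#' Joint weighted least squares over the population fractions
#' p_i(g_tot) of all stoichiometries at fixed chain concentration,
#' sharing the macroscopic dissociation constants across curves.
#' Anti-cooperativity is not enforced; constants are reported as fitted.
#'
#' @param populations data.frame with columns \code{g_tot_M},
#'   \code{state} (0..N bound ligands), \code{fraction}, optional
#'   \code{se}.
#' @param N maximum stoichiometry.
#' @param p_tot_M fixed total chain concentration, mol/L.
#' @param start optional start values for the K_Di (mol/L).
#' @return data.frame: parameter, estimate, se, \code{unidentifiable}
#'   flag (infinite/NA CI on a flat curve).
#' @export
fit_population_curves <- function(populations, N, p_tot_M, start = NULL) {
  need <- c("g_tot_M", "state", "fraction")
  if (!all(need %in% names(populations)))
    stop_input("populations needs columns %s", paste(need, collapse = ", "))
  w <- if (!is.null(populations$se) && all(populations$se > 0))
    1 / populations$se else rep(1, nrow(populations))
  g_vals <- sort(unique(populations$g_tot_M))
  kd0 <- start %||% {
    # crude: concentration where p_0 drops to 1/2, geometric ladder
    p0 <- populations[populations$state == 0, ]
    ghalf <- if (nrow(p0) > 1) approx(p0$fraction, p0$g_tot_M, xout = 0.5,
                                      ties = "ordered")$y else NA
    if (!is.finite(ghalf)) ghalf <- stats::median(g_vals[g_vals > 0])
    ghalf * 4^(seq_len(N) - 1)
  }
  fn <- function(lp) {
    kds <- exp(lp)
    pred <- vapply(seq_len(nrow(populations)), function(i) {
      p <- solve_sequential_populations(kds, populations$g_tot_M[i], p_tot_M)$p
      p[populations$state[i] + 1L]
    }, numeric(1))
    w * (populations$fraction - pred)
  }
  res <- minpack.lm::nls.lm(log(kd0), fn = fn,
                            control = minpack.lm::nls.lm.control(maxiter = 1000))
  se <- nlslm_se(res)
  kds <- exp(res$par)
  out <- data.frame(parameter = paste0("kd_", seq_len(N)),
                    estimate = kds, se = kds * se)
  out$unidentifiable <- !is.finite(out$se) | out$se > 100 * out$estimate
  attr(out, "fit") <- res
  out
}

#' Salt series container
#'
#' @param ionic_strength_M total ionic strengths (including buffer
#'   contribution), mol/L.
#' @param kd_M apparent dissociation constants, mol/L.
#' @param se_kd_M standard errors on the dissociation constants.
#' @return data.frame of class \code{salt_series}.
#' @export
salt_series <- function(ionic_strength_M, kd_M, se_kd_M = NULL) {
  check_positive(ionic_strength_M, "ionic_strength_M")
  check_positive(kd_M, "kd_M")
  if (is.null(se_kd_M)) se_kd_M <- rep(NA_real_, length(kd_M))
  structure(data.frame(ionic_strength_M = ionic_strength_M, kd_M = kd_M,
                       se_kd_M = se_kd_M),
            class = c("salt_series", "data.frame"))
}

#' Counterion release from the salt dependence of affinity
#'
#' Lohman-Record analysis: weighted linear fit of log10(K_D,app) versus
#' log10(ionic strength). The slope (positive convention) counts the
#' ions released upon binding; the 90% confidence interval comes from
#' the t-distribution on the regression residuals. Errors on K_D are
#' propagated to log space as SE/K_D/ln(10).
#'
#' @param series [salt_series()] with at least 3 distinct ionic
#'   strengths.
#' @return list with \code{ions_released}, \code{ions_released_se},
#'   \code{ci90}, \code{intercept}, \code{intercept_se},
#'   \code{intercept_ci90}, and the underlying \code{lm} fit.
#' @export
fit_salt_dependence <- function(series) {
  if (length(unique(series$ionic_strength_M)) < 3L)
    stop_input("need >= 3 distinct ionic strengths")
  x <- log10(series$ionic_strength_M)
  y <- log10(series$kd_M)
  w <- if (all(is.finite(series$se_kd_M)) && all(series$se_kd_M > 0))
    (series$kd_M * log(10) / series$se_kd_M)^2 else NULL
  lf <- linfit(x, y, w)
  tcrit <- qt(0.95, lf$df)
  list(ions_released = lf$slope, ions_released_se = lf$slope_se,
       ci90 = lf$slope + c(-1, 1) * tcrit * lf$slope_se,
       intercept = lf$intercept, intercept_se = lf$intercept_se,
       intercept_ci90 = lf$intercept + c(-1, 1) * tcrit * lf$intercept_se,
       fit = lf$fit)
}
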