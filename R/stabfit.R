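# CD data conversion and two-state chemical/thermal stability fits.

R_GAS_KJ <- 8.314e-3  # kJ/mol/K

#' CD curve container
#'
#' @param x denaturant concentration (mol/L) or temperature (K),
#'   monotone.
#' @param signal ellipticity (mdeg) or mean residue weight ellipticity.
#' @param mode \code{"chemical"} or \code{"thermal"}.
#' @param se optional per-point standard errors.
#' @return data.frame of class \code{cd_curve}.
#' @export
cd_curve <- function(x, signal, mode = c("chemical", "thermal"), se = NULL) {
  mode <- match.arg(mode)
  if (is.unsorted(x) && is.unsorted(rev(x))) stop_input("x must be monotone")
  structure(data.frame(x = x, signal = signal,
                       se = se %||% rep(NA_real_, length(x))),
            mode = mode, class = c("cd_curve", "data.frame"))
}

#' Mean residue weight ellipticity
#'
#' [theta]_MRW = (MW / (n - 1)) * mdeg / (10 c d).
#'
#' @param mdeg observed ellipticity in millidegrees (vectorized).
#' @param MW molecular weight, Da.
#' @param n number of residues (> 1).
#' @param c_gL protein concentration, g/L.
#' @param d_cm path length, cm.
#' @return mean residue weight ellipticity, deg cm^2 dmol^-1.
#' @export
mrw_convert <- function(mdeg, MW, n, c_gL, d_cm) {
  if (n <= 1) stop_input("n must exceed 1")
  check_positive(c(MW, c_gL, d_cm), "MW/c_gL/d_cm")
  (MW / (n - 1)) * mdeg / (10 * c_gL * d_cm)
}

two_state_chemical <- function(x, aN, bN, aD, bD, m, cm, TK) {
  # aN/aD: baseline slopes; bN/bD: intercepts
  ex <- exp(m * (x - cm) / (R_GAS_KJ * TK))
  ((aN * x + bN) + (aD * x + bD) * ex) / (1 + ex)
}

two_state_thermal <- function(TT, mN, yN, mD, yD, dH, Tm) {
  ex <- exp(-dH * (1 - TT / Tm) / (R_GAS_KJ * TT))
  ((mN * TT + yN) + (mD * TT + yD) * ex) / (1 + ex)
}

fit_two_state <- function(curve, mode) {
  x <- curve$x; y <- curve$signal
  n <- length(x)
  qlo <- y[x <= quantile(x, 0.25)]; qhi <- y[x >= quantile(x, 0.75)]
  mid0 <- x[which.min(abs(y - (mean(qlo) + mean(qhi)) / 2))]
  if (mode == "chemical") {
    par0 <- c(aN = 0, bN = mean(qlo), aD = 0, bD = mean(qhi),
              m = 5, cm = mid0)
    fn <- function(p) y - two_state_chemical(x, p[1], p[2], p[3], p[4],
                                             p[5], p[6], attr(curve, "temperature_K") %||% 298.15)
  } else {
    par0 <- c(mN = 0, yN = mean(qlo), mD = 0, yD = mean(qhi),
              dH = 300, Tm = mid0)
    fn <- function(p) y - two_state_thermal(x, p[1], p[2], p[3], p[4], p[5], p[6])
  }
  res <- minpack.lm::nls.lm(par0, fn = fn,
                            control = minpack.lm::nls.lm.control(maxiter = 1000))
  se <- nlslm_se(res)
  pars <- data.frame(parameter = names(par0), estimate = res$par, se = se,
                     row.names = NULL)
  mid <- res$par[[6]]
  flag <- mid < min(x) || mid > max(x)
  if (flag) warning("transition midpoint outside the data range", call. = FALSE)
  structure(list(parameters = pars, mode = mode,
                 midpoint_outside_range = flag, fit = res),
            class = "two_state_fit")
}

#' Fit a two-state chemical denaturation curve
#'
#' Nonlinear least squares of the linear-extrapolation two-state model
#' with sloping native/denatured baselines: parameters aN, bN
#' (native baseline slope/intercept), aD, bD (denatured), m-value
#' (kJ/mol/M) and midpoint c_m (mol/L).
#'
#' @param curve [cd_curve()] with >= 8 points spanning both baselines;
#'   the attribute \code{temperature_K} (default 298.15) sets RT.
#' @return \code{two_state_fit}: parameter table with SEs, flag when the
#'   transition lies outside the data.
#' @export
fit_chemical_denaturation <- function(curve) {
  if (nrow(curve) < 8) stop_input("need >= 8 points spanning both baselines")
  fit_two_state(curve, "chemical")
}

#' Fit a two-state thermal melting curve
#'
#' Nonlinear least squares of the van't Hoff two-state model with
#' sloping baselines: parameters mN, yN, mD, yD (baseline slopes and
#' intercepts), van't Hoff enthalpy dH (kJ/mol) at Tm, and melting
#' temperature Tm (K).
#'
#' @param curve [cd_curve()] with >= 10 points spanning the transition.
#' @return \code{two_state_fit} object.
#' @export
fit_thermal_melt <- function(curve) {
  if (nrow(curve) < 10) stop_input("need >= 10 points spanning the transition")
  fit_two_state(curve, "thermal")
}

#' Stability change from a melting-temperature shift
#'
#' ddG(T) = -dH_avg^Tm * T / (Tm_WT * Tm_Mut) * dTm with
#' dTm = Tm_Mut - Tm_WT and dH_avg^Tm the mean of the two fitted van't
#' Hoff enthalpies, assuming temperature-independent dCp with
#' negligible change between variants. Errors are propagated from the
#' Tm and dH standard errors.
#'
#' @param fit_wt,fit_mut [fit_thermal_melt()] results (or lists with
#'   \code{Tm}, \code{Tm_se}, \code{dH}, \code{dH_se}).
#' @param T_K evaluation temperature (default 298 K).
#' @return list: \code{ddG_kJmol}, \code{ddG_se}, \code{dTm_K},
#'   \code{dH_avg_kJmol}, \code{Tm_wt}, \code{Tm_mut}.
#' @export
ddg_from_tm_shift <- function(fit_wt, fit_mut, T_K = 298) {
  get <- function(f) {
    if (inherits(f, "two_state_fit")) {
      p <- f$parameters
      list(Tm = p$estimate[p$parameter == "Tm"],
           Tm_se = p$se[p$parameter == "Tm"],
           dH = p$estimate[p$parameter == "dH"],
           dH_se = p$se[p$parameter == "dH"])
    } else f
  }
  wt <- get(fit_wt); mut <- get(fit_mut)
  if (wt$dH <= 0 || mut$dH <= 0) stop_input("both fits must have positive dH")
  dH_avg <- (wt$dH + mut$dH) / 2
  dTm <- mut$Tm - wt$Tm
  ddG <- -dH_avg * T_K / (wt$Tm * mut$Tm) * dTm
  # first-order propagation
  g_dH <- -T_K * dTm / (wt$Tm * mut$Tm) / 2
  g_Tmut <- -dH_avg * T_K / (wt$Tm * mut$Tm) + dH_avg * T_K * dTm / (wt$Tm * mut$Tm^2)
  g_Twt <- dH_avg * T_K / (wt$Tm * mut$Tm) + dH_avg * T_K * dTm / (wt$Tm^2 * mut$Tm)
  var <- (g_dH * (wt$dH_se %||% 0))^2 + (g_dH * (mut$dH_se %||% 0))^2 +
    (g_Twt * (wt$Tm_se %||% 0))^2 + (g_Tmut * (mut$Tm_se %||% 0))^2
  list(ddG_kJmol = ddG, ddG_se = sqrt(var), dTm_K = dTm,
       dH_avg_kJmol = dH_avg, Tm_wt = wt$Tm, Tm_mut = mut$Tm)
}
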