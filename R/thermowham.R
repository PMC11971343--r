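# WHAM reconstruction of potentials of mean force from umbrella
# sampling, dissociation constants by volume integration of the PMF,
# and van't Hoff enthalpy/entropy decomposition.

KB_KJ <- 8.314e-3        # kJ/mol/K
N_AVOGADRO <- 6.02214076e23

#' Umbrella sampling window set
#'
#' @param windows list of lists, each with \code{center} (nm), \code{k}
#'   (spring constant, kJ/mol/nm^2) and \code{samples} (reaction
#'   coordinate values, nm).
#' @param temperature_K temperature, K.
#' @return object of class \code{umbrella_set}; warns when adjacent
#'   window sample ranges fail to overlap (ill-conditioned WHAM).
#' @export
umbrella_set <- function(windows, temperature_K = 283) {
  check_positive(temperature_K, "temperature_K")
  ks <- vapply(windows, `[[`, numeric(1), "k")
  check_positive(ks, "spring constants")
  centers <- vapply(windows, `[[`, numeric(1), "center")
  ord <- order(centers)
  windows <- windows[ord]
  rng <- t(vapply(windows, function(w) range(w$samples), numeric(2)))
  gap <- rng[-nrow(rng), 2] < rng[-1, 1]
  if (any(gap))
    warning(sprintf("adjacent windows without sample overlap after center(s) %s; WHAM may be ill-conditioned",
                    paste(signif(centers[ord][which(gap)], 3), collapse = ", ")),
            call. = FALSE)
  structure(list(windows = windows, temperature_K = temperature_K),
            class = "umbrella_set")
}

#' Umbrella window centers used for coarse-grained binding runs
#'
#' Default layout: centers every 0.5 nm from 0 to 2.5 nm, then every
#' 1 nm out to 24.5 nm (28 windows), with a spring constant of
#' 10 kJ/mol/nm^2.
#'
#' @return list with \code{centers} (nm) and \code{k} (kJ/mol/nm^2).
#' @export
umbrella_layout_default <- function() {
  list(centers = c(seq(0, 2.5, by = 0.5), seq(3.5, 24.5, by = 1)), k = 10)
}

#' Reconstruct a PMF from umbrella windows by WHAM
#'
#' Self-consistent weighted-histogram iteration over binned samples
#' until the largest change in the window free energies falls below
#' \code{tol} (in kT). The PMF is reported in kT units and zeroed on
#' the outer 20% of the grid (the unbound plateau); per-bin statistical
#' uncertainties come from the effective histogram counts.
#'
#' @param set [umbrella_set()].
#' @param bins number of bins (default 100) or explicit break vector,
#'   nm.
#' @param tol convergence tolerance on the window free energies, kT.
#' @param max_iter iteration cap.
#' @return data.frame of class \code{pmf_profile}: \code{r_nm},
#'   \code{W_kT}, \code{se_kT}; attributes \code{f_window} (window free
#'   energies) and \code{iterations}.
#' @export
wham_pmf <- function(set, bins = 100L, tol = 1e-8, max_iter = 50000L) {
  kT <- KB_KJ * set$temperature_K
  all_s <- unlist(lapply(set$windows, `[[`, "samples"))
  # trim extreme sample quantiles so edge bins are populated
  brks <- if (length(bins) > 1L) bins else
    seq(quantile(all_s, 0.001), quantile(all_s, 0.999),
        length.out = bins + 1L)
  mids <- (brks[-1] + brks[-length(brks)]) / 2
  nb <- length(mids); nw <- length(set$windows)
  H <- matrix(0, nw, nb)     # histogram counts per window
  for (i in seq_len(nw)) {
    cutv <- cut(set$windows[[i]]$samples, brks, include.lowest = TRUE, labels = FALSE)
    cutv <- cutv[!is.na(cutv)]
    H[i, ] <- tabulate(cutv, nb)
  }
  n_tot <- colSums(H)
  if (any(n_tot == 0)) {
    gaps <- range(mids[n_tot == 0])
    stop_input("uncovered bins between r = %.3g and %.3g nm", gaps[1], gaps[2])
  }
  N_i <- rowSums(H)
  # bias energies in kT: U_i(x) = k/2 (x - c_i)^2 / kT
  B <- t(vapply(set$windows, function(w)
    exp(-(w$k / 2) * (mids - w$center)^2 / kT), numeric(nb)))
  f <- rep(0, nw)            # exp(f_i / kT) normalization, log form
  for (it in seq_len(max_iter)) {
    denom <- colSums(N_i * exp(f) * B)
    p <- n_tot / denom
    f_new <- -log(as.numeric(B %*% p))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  p <- n_tot / colSums(N_i * exp(f) * B)
  W <- -log(p)
  plateau <- mids >= (min(mids) + 0.8 * diff(range(mids)))
  W <- W - mean(W[plateau])
  se <- sqrt(1 / pmax(n_tot, 1))   # Poisson counting error, kT
  out <- data.frame(r_nm = mids, W_kT = W, se_kT = se)
  attr(out, "f_window") <- f
  attr(out, "iterations") <- it
  attr(out, "temperature_K") <- set$temperature_K
  class(out) <- c("pmf_profile", "data.frame")
  out
}

#' Dissociation constant by volume integration of a PMF
#'
#' Kd^-1 = N_A int_0^rc 4 pi r^2 exp(-W(r)/kT) dr relative to the 1 M
#' standard state (volume in L). The default bound-region cutoff is the
#' distance where the PMF first returns to within 0.5 kT of the unbound
#' plateau; the PMF must be plateaued (zeroed) beyond the cutoff.
#' Uncertainty is propagated by resampling the per-bin PMF errors.
#'
#' @param pmf [wham_pmf()] result or data.frame with \code{r_nm},
#'   \code{W_kT} (zeroed on the plateau), optional \code{se_kT}.
#' @param bound_cut_nm bound-region cutoff; \code{NULL} for automatic.
#' @param n_boot resamples for the uncertainty (0 disables).
#' @param seed seed for the resampling.
#' @return list: \code{kd_M}, \code{kd_se_M}, \code{bound_cut_nm},
#'   \code{dG_kT} (well depth at the minimum).
#' @export
kd_from_pmf <- function(pmf, bound_cut_nm = NULL, n_boot = 200L, seed = 1L) {
  r <- pmf$r_nm; W <- pmf$W_kT
  if (is.null(bound_cut_nm)) {
    imin <- which.min(W)
    past <- which(W > -0.5 & seq_along(W) > imin)
    if (!length(past)) stop_input("no plateau detected beyond the well")
    bound_cut_nm <- r[past[1]]
  }
  sel <- r <= bound_cut_nm
  if (sum(sel) < 3) stop_input("fewer than 3 PMF bins inside bound_cut")
  tail_W <- W[r >= bound_cut_nm]
  if (length(tail_W) && mean(abs(tail_W)) > 0.5)
    warning("PMF not plateaued near zero beyond bound_cut", call. = FALSE)
  integrand <- function(Wv) {
    y <- 4 * pi * r[sel]^2 * exp(-Wv[sel])
    sum((y[-1] + y[-length(y)]) / 2 * diff(r[sel]))      # nm^3
  }
  vol_nm3 <- integrand(W)
  kd <- 1 / (N_AVOGADRO * vol_nm3 * 1e-24)               # nm^3 -> L
  kd_se <- NA_real_
  if (n_boot > 0 && !is.null(pmf$se_kT)) {
    set.seed(seed)
    ks <- vapply(seq_len(n_boot), function(b) {
      Wb <- W + rnorm(length(W), 0, pmf$se_kT)
      1 / (N_AVOGADRO * integrand(Wb) * 1e-24)
    }, numeric(1))
    kd_se <- sd(ks)
  }
  list(kd_M = kd, kd_se_M = kd_se, bound_cut_nm = bound_cut_nm,
       dG_kT = min(W))
}

#' Van't Hoff decomposition of a temperature-dependent Kd
#'
#' Linear fit of ln Kd (standard-state units) versus 1/T:
#' dH = R * slope and dS = -R * intercept, since
#' ln Kd = dG_binding/(RT) = dH/(RT) - dS/R for the dissociation
#' direction.
#'
#' @param kd_by_temperature data.frame with columns \code{T_K} and
#'   \code{kd_M}, optional \code{se_kd_M}.
#' @return list: \code{dH_kJmol}, \code{dH_se}, \code{dS_JmolK},
#'   \code{dS_se}, \code{fit}.
#' @export
vant_hoff_decomposition <- function(kd_by_temperature) {
  if (nrow(kd_by_temperature) < 2) stop_input("need >= 2 temperatures")
  x <- 1 / kd_by_temperature$T_K
  y <- log(kd_by_temperature$kd_M)
  w <- if (!is.null(kd_by_temperature$se_kd_M))
    (kd_by_temperature$kd_M / kd_by_temperature$se_kd_M)^2 else NULL
  lf <- linfit(x, y, w)
  list(dH_kJmol = KB_KJ * lf$slope, dH_se = KB_KJ * lf$slope_se,
       dS_JmolK = -8.314 * lf$intercept, dS_se = 8.314 * lf$intercept_se,
       fit = lf$fit)
}
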