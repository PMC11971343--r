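# Contact detection with a dual-cutoff (hysteresis) scheme, contact
# lifetime statistics, binding-state counting and global chain
# relaxation from trajectories.

# Minimum-image displacement for an orthorhombic box (box = NULL: none).
min_image <- function(dx, box) {
  if (is.null(box)) return(dx)
  for (k in 1:3) dx[, k] <- dx[, k] - box[k] * round(dx[, k] / box[k])
  dx
}

# Per-frame minimum heavy-atom distance for each residue pair.
# Returns matrix [n_pairs, n_frames]; pairs is a data.frame.
pair_min_distances <- function(traj, pairs, atoms_by_res) {
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nrow(pairs), nf)
  for (i in seq_len(nrow(pairs))) {
    ia <- atoms_by_res[[pairs$key_a[i]]]
    ib <- atoms_by_res[[pairs$key_b[i]]]
    for (f in seq_len(nf)) {
      xa <- traj$coords[ia, , f, drop = FALSE]; dim(xa) <- c(length(ia), 3L)
      xb <- traj$coords[ib, , f, drop = FALSE]; dim(xb) <- c(length(ib), 3L)
      dx <- xa[rep(seq_along(ia), each = length(ib)), , drop = FALSE] -
        xb[rep(seq_along(ib), times = length(ia)), , drop = FALSE]
      dx <- min_image(dx, traj$box)
      out[i, f] <- sqrt(min(rowSums(dx^2)))
    }
  }
  out
}

#' Detect residue contacts with a dual-cutoff scheme
#'
#' A contact between two residues forms when any two heavy atoms, one
#' from each residue, come within \code{form_cut}; it breaks only when
#' the closest heavy-atom distance exceeds \code{break_cut}. The
#' hysteresis band between the cutoffs suppresses boundary-recrossing
#' artifacts. Intra-chain residue pairs closer than \code{min_seq_sep}
#' in sequence are excluded (inter-chain pairs have no sequence
#' separation and are always considered).
#'
#' @param traj [trajectory_frames()] object.
#' @param chains length-2 character vector of chain ids to search
#'   between, or a single chain id for intra-chain contacts.
#' @param form_cut formation cutoff, nm (default 0.38).
#' @param break_cut breaking cutoff, nm (default 0.8).
#' @param min_seq_sep minimum sequence separation for intra-chain pairs
#'   (default 4).
#' @return list of class \code{contact_set}: \code{events} (data.frame
#'   chain_a, res_a, chain_b, res_b, form_frame, break_frame,
#'   lifetime_ns; open-ended events have NA break_frame), \code{state}
#'   (logical matrix pairs x frames of the hysteresis contact state),
#'   \code{pairs}, \code{dt_ps}.
#' @export
detect_contacts <- function(traj, chains, form_cut = 0.38, break_cut = 0.8,
                            min_seq_sep = 4L) {
  if (break_cut <= form_cut) stop_input("break_cut must exceed form_cut")
  at <- traj$atoms
  heavy <- toupper(substr(at$element, 1, 1)) != "H"
  intra <- length(chains) == 1L
  cha <- chains[1]; chb <- if (intra) chains[1] else chains[2]
  res_a <- sort(unique(at$resid[at$chain == cha & heavy]))
  res_b <- sort(unique(at$resid[at$chain == chb & heavy]))
  if (!length(res_a) || !length(res_b))
    stop_input("no heavy atoms found for the requested chains")
  pairs <- expand.grid(res_a = res_a, res_b = res_b)
  pairs$chain_a <- cha; pairs$chain_b <- chb
  if (intra) {
    pairs <- pairs[pairs$res_b - pairs$res_a >= min_seq_sep, , drop = FALSE]
  }
  if (!nrow(pairs)) stop_input("no residue pairs to evaluate")
  pairs$key_a <- paste(pairs$chain_a, pairs$res_a)
  pairs$key_b <- paste(pairs$chain_b, pairs$res_b)
  keys <- unique(c(pairs$key_a, pairs$key_b))
  atoms_by_res <- lapply(keys, function(k) {
    parts <- strsplit(k, " ")[[1]]
    which(at$chain == parts[1] & at$resid == as.integer(parts[2]) & heavy)
  })
  names(atoms_by_res) <- keys
  dmin <- pair_min_distances(traj, pairs, atoms_by_res)
  nf <- ncol(dmin)
  state <- matrix(FALSE, nrow(pairs), nf)
  events <- list()
  for (i in seq_len(nrow(pairs))) {
    formed <- FALSE; t_form <- NA_integer_
    for (f in seq_len(nf)) {
      d <- dmin[i, f]
      if (!formed && d < form_cut) { formed <- TRUE; t_form <- f - 1L }
      else if (formed && d > break_cut) {
        events[[length(events) + 1L]] <-
          data.frame(chain_a = pairs$chain_a[i], res_a = pairs$res_a[i],
                     chain_b = pairs$chain_b[i], res_b = pairs$res_b[i],
                     form_frame = t_form, break_frame = f - 1L)
        formed <- FALSE
      }
      state[i, f] <- formed
    }
    if (formed) {
      events[[length(events) + 1L]] <-
        data.frame(chain_a = pairs$chain_a[i], res_a = pairs$res_a[i],
                   chain_b = pairs$chain_b[i], res_b = pairs$res_b[i],
                   form_frame = t_form, break_frame = NA_integer_)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(chain_a = character(), res_a = integer(), chain_b = character(),
               res_b = integer(), form_frame = integer(), break_frame = integer())
  events$lifetime_ns <- (events$break_frame - events$form_frame) * traj$dt_ps / 1000
  structure(list(events = events, state = state,
                 pairs = pairs[, c("chain_a", "res_a", "chain_b", "res_b")],
                 dt_ps = traj$dt_ps, n_frames = nf),
            class = "contact_set")
}

#' Contact lifetime statistics
#'
#' Lifetimes in ns with a probability-density histogram and a
#' block-resampled error on the mean (events assigned to temporal
#' blocks by formation time). Events truncated by either trajectory end
#' (formed in the first frame or unbroken at the last) are censored and
#' excluded by default.
#'
#' @param contacts [detect_contacts()] result.
#' @param censoring \code{"exclude"} (default) or \code{"include"}
#'   (right-censored events enter at their observed duration).
#' @param bin_ns histogram bin width, ns.
#' @param n_blocks temporal blocks for the error on the mean.
#' @return list of class \code{contact_summary}: \code{lifetimes_ns},
#'   \code{mean_ns}, \code{mean_se_ns}, \code{histogram} (data.frame
#'   mid_ns, density), \code{n_events}, \code{n_censored}.
#' @export
contact_lifetimes <- function(contacts, censoring = c("exclude", "include"),
                              bin_ns = NULL, n_blocks = 10L) {
  censoring <- match.arg(censoring)
  ev <- contacts$events
  censored <- is.na(ev$break_frame) | ev$form_frame == 0L
  n_censored <- sum(censored)
  if (censoring == "exclude") ev <- ev[!censored, , drop = FALSE]
  else {
    ev$break_frame[is.na(ev$break_frame)] <- contacts$n_frames - 1L
    ev$lifetime_ns <- (ev$break_frame - ev$form_frame) * contacts$dt_ps / 1000
  }
  if (!nrow(ev)) {
    warning("no (uncensored) contact events", call. = FALSE)
    return(structure(list(lifetimes_ns = numeric(), mean_ns = NA_real_,
                          mean_se_ns = NA_real_, histogram = NULL,
                          n_events = 0L, n_censored = n_censored),
                     class = "contact_summary"))
  }
  lt <- ev$lifetime_ns
  bin_ns <- bin_ns %||% max(contacts$dt_ps / 1000, diff(range(lt)) / 30)
  brks <- seq(0, max(lt) + bin_ns, by = bin_ns)
  h <- graphics::hist(lt, breaks = brks, plot = FALSE)
  blk <- pmin(floor(ev$form_frame / (contacts$n_frames / n_blocks)) + 1L, n_blocks)
  bm <- tapply(lt, blk, mean)
  bm <- bm[!is.na(bm)]
  se <- if (length(bm) > 1) sd(bm) / sqrt(length(bm)) else NA_real_
  structure(list(lifetimes_ns = lt, mean_ns = mean(lt), mean_se_ns = se,
                 histogram = data.frame(mid_ns = h$mids, density = h$density),
                 n_events = nrow(ev), n_censored = n_censored),
            class = "contact_summary")
}

#' Per-residue average contact count profile
#'
#' Time-average, for every residue of the first chain, of the number of
#' partner residues simultaneously in contact (by the hysteresis state
#' of [detect_contacts()]).
#'
#' @param contacts [detect_contacts()] result.
#' @return data.frame: \code{residue}, \code{mean_contacts}.
#' @export
residue_contact_profile <- function(contacts) {
  res <- sort(unique(contacts$pairs$res_a))
  prof <- vapply(res, function(r) {
    rows <- which(contacts$pairs$res_a == r)
    mean(colSums(contacts$state[rows, , drop = FALSE]))
  }, numeric(1))
  data.frame(residue = res, mean_contacts = prof)
}

#' Count bound ligand chains over time
#'
#' A ligand chain is counted as interacting when its minimum inter-chain
#' heavy-atom distance to the reference chain is below \code{cutoff}.
#' Distances are evaluated every \code{stride_ps} of trajectory time.
#'
#' @param traj [trajectory_frames()] object.
#' @param chain_p reference chain id.
#' @param ligand_chains character vector of ligand chain ids.
#' @param cutoff interaction cutoff, nm (default 1.3).
#' @param stride_ps evaluation interval, ps (default 100).
#' @return list: \code{time_ps}, \code{count} (bound ligands per
#'   evaluated frame), \code{occupancy} (fraction of time at each
#'   stoichiometry 0..n_ligands).
#' @export
count_bound_ligands <- function(traj, chain_p, ligand_chains, cutoff = 1.3,
                                stride_ps = 100) {
  if (!length(ligand_chains)) stop_input("need >= 1 ligand chain")
  at <- traj$atoms
  heavy <- toupper(substr(at$element, 1, 1)) != "H"
  ip <- which(at$chain == chain_p & heavy)
  if (!length(ip)) stop_input("chain %s has no heavy atoms", chain_p)
  stride <- max(1L, round(stride_ps / traj$dt_ps))
  frames <- seq(1L, n_frames(traj), by = stride)
  count <- vapply(frames, function(f) {
    xp <- traj$coords[ip, , f, drop = FALSE]; dim(xp) <- c(length(ip), 3L)
    sum(vapply(ligand_chains, function(ch) {
      il <- which(at$chain == ch & heavy)
      xl <- traj$coords[il, , f, drop = FALSE]; dim(xl) <- c(length(il), 3L)
      dx <- xp[rep(seq_along(ip), each = length(il)), , drop = FALSE] -
        xl[rep(seq_along(il), times = length(ip)), , drop = FALSE]
      dx <- min_image(dx, traj$box)
      sqrt(min(rowSums(dx^2))) < cutoff
    }, logical(1)))
  }, integer(1))
  occ <- tabulate(count + 1L, nbins = length(ligand_chains) + 1L) / length(count)
  list(time_ps = (frames - 1L) * traj$dt_ps, count = count,
       occupancy = setNames(occ, 0:length(ligand_chains)))
}

# Standard atomic masses for mass-weighted Rg; unknown elements fall
# back to carbon.
element_mass <- function(el) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974)
  m <- tab[toupper(substr(el, 1, 1))]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Radius-of-gyration series of a chain
#'
#' Mass-weighted Rg per frame.
#'
#' @param traj [trajectory_frames()] object.
#' @param chain chain id (default: all atoms).
#' @return numeric vector, nm.
#' @export
rg_series <- function(traj, chain = NULL) {
  at <- traj$atoms
  idx <- if (is.null(chain)) seq_len(nrow(at)) else which(at$chain == chain)
  m <- element_mass(at$element[idx])
  vapply(seq_len(n_frames(traj)), function(f) {
    x <- traj$coords[idx, , f, drop = FALSE]
    com <- colSums(x * m) / sum(m)
    sqrt(sum(m * rowSums((x - rep(com, each = length(idx)))^2)) / sum(m))
  }, numeric(1))
}

#' Autocorrelation time of radius-of-gyration fluctuations
#'
#' Normalized autocorrelation of the Rg series (or any scalar series)
#' with the package's integrated correlation-time definition
#' ([integrated_correlation_time()]) and a block error over
#' \code{n_blocks} temporal segments.
#'
#' @param x [trajectory_frames()] object or a numeric series.
#' @param dt_ns sampling interval in ns (taken from the trajectory when
#'   frames are given).
#' @param chain chain id for the Rg calculation.
#' @param n_blocks blocks for the error estimate.
#' @return list: \code{tau_ns}, \code{tau_se_ns}, \code{n}.
#' @export
rg_autocorrelation_time <- function(x, dt_ns = NULL, chain = NULL,
                                    n_blocks = 10L) {
  if (inherits(x, "trajectory_frames")) {
    dt_ns <- x$dt_ps / 1000
    x <- rg_series(x, chain)
  }
  if (is.null(dt_ns)) stop_input("dt_ns required for a plain series")
  if (sd(x) == 0) stop_input("constant series: correlation time undefined")
  rho <- acf_fft(x, floor(length(x) / 2))
  tau <- as.numeric(integrated_correlation_time(rho, dt_ns))
  if (length(x) < 20 * tau / dt_ns)
    warning("series shorter than 20x the estimated correlation time", call. = FALSE)
  edges <- floor(seq(0, length(x), length.out = n_blocks + 1))
  bt <- vapply(seq_len(n_blocks), function(b) {
    xs <- x[(edges[b] + 1):edges[b + 1]]
    if (sd(xs) == 0) return(NA_real_)
    r <- acf_fft(xs, floor(length(xs) / 2))
    as.numeric(integrated_correlation_time(r, dt_ns))
  }, numeric(1))
  bt <- bt[is.finite(bt)]
  se <- if (length(bt) > 1) sd(bt) / sqrt(length(bt)) else NA_real_
  list(tau_ns = tau, tau_se_ns = se, n = length(x))
}
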