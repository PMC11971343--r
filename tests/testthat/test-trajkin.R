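test_that("dual-cutoff detection honors hysteresis and constructed truth", {
  # all far apart: no events
  tr0 <- make_contact_frames(list(), n_frames = 30)
  cs0 <- detect_contacts(tr0, c("A", "B"))
  expect_equal(nrow(cs0$events), 0)
  expect_equal(dim(cs0$state)[2], 30)
  # one 100-frame episode at 5 ps: one event of 0.5 ns
  tr <- make_contact_frames(list(list(res_a = 2, res_b = 3, start = 50, end = 150)),
                            n_frames = 300, dt_ps = 5)
  cs <- detect_contacts(tr, c("A", "B"))
  expect_equal(nrow(cs$events), 1)
  expect_equal(cs$events$lifetime_ns, 0.5)
  expect_equal(cs$events$form_frame, 50)
  # excursion into the hysteresis band does not break the contact
  tr2 <- make_contact_frames(list(list(res_a = 1, res_b = 1, start = 10, end = 60)),
                             n_frames = 100, dt_ps = 5)
  tr2$coords[5, 2, 31] <- 0.6       # mid-episode frame into (0.38, 0.8) band
  cs2 <- detect_contacts(tr2, c("A", "B"))
  expect_equal(nrow(cs2$events), 1)
  expect_equal(cs2$events$lifetime_ns, 0.25)
  expect_error(detect_contacts(tr, c("A", "B"), form_cut = 0.9, break_cut = 0.8),
               "exceed")
})

test_that("contact detection is invariant to atom ordering", {
  tr <- make_contact_frames(list(list(res_a = 1, res_b = 2, start = 10, end = 40),
                                 list(res_a = 3, res_b = 1, start = 20, end = 70)),
                            n_frames = 100, dt_ps = 5)
  perm <- sample(seq_len(dim(tr$coords)[1]))
  trp <- trajectory_frames(tr$coords[perm, , , drop = FALSE], tr$dt_ps,
                           tr$atoms[perm, ])
  ev1 <- detect_contacts(tr, c("A", "B"))$events
  ev2 <- detect_contacts(trp, c("A", "B"))$events
  key <- function(e) e[order(e$res_a, e$res_b, e$form_frame),
                       c("res_a", "res_b", "form_frame", "break_frame")]
  expect_equal(key(ev1), key(ev2), ignore_attr = TRUE)
})

test_that("intra-chain pairs respect the sequence-separation exclusion", {
  # two residues 2 apart on one chain, permanently close: excluded
  atoms <- data.frame(resid = c(1L, 3L, 8L), resname = "GLY", atomname = "CA",
                      chain = "A", element = "C")
  coords <- array(0, dim = c(3, 3, 10))
  coords[2, 1, ] <- 0.3           # residue 3 at 0.3 nm from residue 1
  coords[3, 1, ] <- 0.35          # residue 8 at 0.05 nm from residue 3
  tr <- trajectory_frames(coords, 5, atoms)
  cs <- detect_contacts(tr, "A")
  expect_true(all(cs$pairs$res_b - cs$pairs$res_a >= 4))
  # the 1-8 pair (sep 7) is eligible and close
  expect_true(any(cs$state))
})

test_that("lifetime statistics match the events and handle censoring", {
  eps <- list(list(res_a = 1, res_b = 1, start = 10, end = 210),   # 1 ns
              list(res_a = 2, res_b = 2, start = 50, end = 450),   # 2 ns
              list(res_a = 3, res_b = 3, start = 100, end = 700))  # 3 ns
  tr <- make_contact_frames(eps, n_frames = 1000, dt_ps = 5)
  cs <- detect_contacts(tr, c("A", "B"))
  cl <- contact_lifetimes(cs)
  expect_equal(sort(cl$lifetimes_ns), c(1, 2, 3))
  expect_equal(cl$mean_ns, 2)
  # histogram mean equals the direct mean
  hist_mean <- with(cl$histogram, sum(mid_ns * density) / sum(density))
  expect_lt(abs(hist_mean - cl$mean_ns), max(diff(cl$histogram$mid_ns)))
  # censored event excluded by default, included on request
  eps_c <- c(eps, list(list(res_a = 4, res_b = 4, start = 900, end = 1100)))
  tr_c <- make_contact_frames(eps_c, n_frames = 1000, dt_ps = 5)
  cs_c <- detect_contacts(tr_c, c("A", "B"))
  expect_equal(contact_lifetimes(cs_c)$n_events, 3)
  expect_equal(contact_lifetimes(cs_c)$n_censored, 1)
  expect_equal(contact_lifetimes(cs_c, censoring = "include")$n_events, 4)
  # zero events: flagged empty summary
  tr0 <- make_contact_frames(list(), n_frames = 10)
  expect_warning(cl0 <- contact_lifetimes(detect_contacts(tr0, c("A", "B"))),
                 "no ")
  expect_equal(cl0$n_events, 0)
})

test_that("residue contact profiles average simultaneous partners", {
  # one permanent contact pair: profile 1 at that residue
  atoms <- data.frame(resid = c(1L, 2L, 1L), resname = "GLY", atomname = "CA",
                      chain = c("A", "A", "B"), element = "C")
  coords <- array(0, dim = c(3, 3, 20))
  coords[2, 1, ] <- 3              # A2 away from everything
  coords[3, 2, ] <- 0.2            # B1 permanently 0.2 nm from A1
  tr <- trajectory_frames(coords, 5, atoms)
  cs <- detect_contacts(tr, c("A", "B"))
  prof <- residue_contact_profile(cs)
  expect_equal(prof$mean_contacts[prof$residue == 1], 1)
  expect_equal(prof$mean_contacts[prof$residue == 2], 0)
  # random occupancy p: profile ~ p * n_partners
  set.seed(12)
  p_occ <- 0.3; nf <- 4000
  state <- matrix(runif(2 * nf) < p_occ, 2, nf)
  fake <- structure(list(events = NULL, state = state,
                         pairs = data.frame(chain_a = "A", res_a = c(1, 1),
                                            chain_b = "B", res_b = c(1, 2)),
                         dt_ps = 5, n_frames = nf), class = "contact_set")
  prof2 <- residue_contact_profile(fake)
  expect_lt(abs(prof2$mean_contacts - p_occ * 2), 0.05)
})

test_that("bound-ligand counting tracks scripted approach and retreat", {
  tr <- make_contact_frames(list(list(res_a = 1, res_b = 1, start = 20, end = 60)),
                            n_frames = 100, dt_ps = 5)
  cnt <- count_bound_ligands(tr, "A", "B", cutoff = 1.3, stride_ps = 5)
  expect_equal(length(cnt$count), 100)
  # bound exactly during the episode frames (plus the 0.6 nm ramp frame)
  expect_true(all(cnt$count[21:60] == 1))
  expect_true(all(cnt$count[63:100] == 0))
  expect_equal(sum(cnt$occupancy), 1)
  # permanently-far ligand: zero
  tr0 <- make_contact_frames(list(), n_frames = 10)
  expect_true(all(count_bound_ligands(tr0, "A", "B")$count == 0))
})

test_that("Rg correlation time recovers the OU relaxation time", {
  x <- make_ou_trace(1.5, 0.2, 35, dt_ns = 0.5, n_steps = 4e5, seed = 7)
  rt <- rg_autocorrelation_time(as.numeric(x), dt_ns = 0.5)
  expect_rel(rt$tau_ns, 35, 0.12)
  # white noise: correlation time on the sampling-interval scale
  set.seed(5)
  wn <- rnorm(5e4)
  rtw <- rg_autocorrelation_time(wn, dt_ns = 0.5)
  expect_lt(rtw$tau_ns, 2 * 0.5)
  # amplitude invariance
  rt2 <- rg_autocorrelation_time(3 * as.numeric(x), dt_ns = 0.5)
  expect_equal(rt2$tau_ns, rt$tau_ns, tolerance = 1e-12)
  expect_error(rg_autocorrelation_time(rep(1, 100), dt_ns = 0.5), "constant")
})

test_that("Rg of frames is mass-weighted and feeds the correlation machinery", {
  # two atoms (C, O) 1 nm apart: Rg from the definition
  atoms <- data.frame(resid = c(1L, 2L), resname = "GLY",
                      atomname = c("C", "O"), chain = "A",
                      element = c("C", "O"))
  coords <- array(0, dim = c(2, 3, 3))
  coords[2, 1, ] <- 1
  tr <- trajectory_frames(coords, 5, atoms)
  m <- c(12.011, 15.999)
  com <- m[2] / sum(m)
  rg_expect <- sqrt((m[1] * com^2 + m[2] * (1 - com)^2) / sum(m))
  expect_equal(rg_series(tr), rep(rg_expect, 3), tolerance = 1e-12)
})
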