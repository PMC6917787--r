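# HS-AFM movie quantification: FWHM measurement, state classification,
# dwell-rate estimators and subunit-randomness tests.

test_that("FWHM of an isotropic Gaussian spot equals 2.3548 sigma", {
  px <- 0.5; sigma_px <- 4
  g <- outer(seq_len(41) - 21, seq_len(41) - 21,
             function(i, j) 3 * exp(-(i^2 + j^2) / (2 * sigma_px^2)))
  fw <- measure_fwhm(g, pixel_size = px, min_area_px = 5)
  expect_equal(fw$n, 1)
  expect_equal(fw$per_particle_fwhm,
               2 * sqrt(2 * log(2)) * sigma_px * px, tolerance = 0.02)
  # half-maximum is relative: scaling heights leaves the width unchanged
  fw2 <- measure_fwhm(2 * g, pixel_size = px, min_area_px = 5)
  expect_equal(fw2$per_particle_fwhm, fw$per_particle_fwhm, tolerance = 1e-9)
})

test_that("an empty field yields an empty FWHM result, not an error", {
  set.seed(41)
  img <- matrix(rnorm(900, 0, 0.1), 30, 30)
  fw <- measure_fwhm(img, pixel_size = 1)
  expect_equal(fw$n, 0)
  expect_true(is.na(fw$fit_mean))
})

test_that("population FWHM recovers the planted width distribution", {
  p <- ring_dynamics_params(k_open = 0, n_frames = 1, n_molecules = 60,
                            ring_outer_fwhm = 19.8, ring_fwhm_sd = 2.6,
                            noise_sd = 0.2, seed = 7)
  rm <- simulate_ring_movie(p)
  fw <- measure_fwhm(rm)
  expect_gte(fw$n, 55)
  truth_mean <- mean(rm$molecules$fwhm_true)
  expect_lt(abs(fw$fit_mean - truth_mean), 2 * fw$se_mean + 0.15)
  expect_lt(abs(fw$fit_sd - 2.6), 1.0)
})

test_that("ring-state classification recovers planted open subunits", {
  # all-closed movie classifies closed everywhere
  p0 <- ring_dynamics_params(k_open = 0, n_frames = 10, n_molecules = 1,
                             noise_sd = 0.15, seed = 43)
  rm0 <- simulate_ring_movie(p0)
  s0 <- classify_ring_states(rm0)[[1]]
  expect_true(all(vapply(s0$open, length, 1L) == 0))
  # dynamic movie: per-frame state matches ground truth when the lobe
  # phase is known (labels are only defined up to rotation otherwise)
  p1 <- ring_dynamics_params(k_open = 1.5, k_close = 0.99, n_frames = 150,
                             n_molecules = 1, noise_sd = 0.2, seed = 44)
  rm1 <- simulate_ring_movie(p1)
  s1 <- classify_ring_states(rm1$movie[, , , drop = FALSE],
                             frame_rate = rm1$frame_rate,
                             phase = rm1$molecules$phase[1])
  expect_identical(lapply(s1$open, as.integer),
                   lapply(rm1$truth[[1]]$open, as.integer))
  # classification is invariant to global height scaling
  s2 <- classify_ring_states(2.5 * rm1$movie, frame_rate = rm1$frame_rate,
                             phase = rm1$molecules$phase[1])
  expect_identical(s2$open, s1$open)
})

test_that("simultaneous two-lobe openings are reported as open pairs", {
  p <- ring_dynamics_params(k_open = 3, k_close = 0.8, n_frames = 600,
                            n_molecules = 1, allow_double_open = TRUE,
                            noise_sd = 0.15, seed = 45)
  rm <- simulate_ring_movie(p)
  s <- classify_ring_states(rm$movie, frame_rate = rm$frame_rate,
                            phase = rm$molecules$phase[1])
  truth_sizes <- vapply(rm$truth[[1]]$open, length, 1L)
  est_sizes <- vapply(s$open, length, 1L)
  expect_true(any(truth_sizes == 2))
  expect_gt(mean(est_sizes == truth_sizes), 0.95)
  two <- which(truth_sizes == 2)[1]
  expect_identical(as.integer(s$open[[two]]),
                   as.integer(rm$truth[[1]]$open[[two]]))
})

test_that("geometric estimator evaluates its closed form on exact dwells", {
  # deterministic alternation with 10-frame dwells at 5 Hz:
  # q = 0.1, k = -5 log(0.9) for both rates
  open <- rep(rep(c(FALSE, TRUE), each = 10), 12)
  ser <- series_from_logical(open, frame_rate = 5)
  est <- estimate_rates(ser, estimator = "geometric", n_boot = 5)
  expect_equal(est$k_open, -5 * log(0.9), tolerance = 1e-9)
  expect_equal(est$k_close, -5 * log(0.9), tolerance = 1e-9)
  expect_equal(est$censored_count, 2L)
})

test_that("rate estimation censors boundaries and flags missing states", {
  # a single dwell of each state only: everything is boundary-censored
  ser <- series_from_logical(rep(c(FALSE, TRUE), each = 5))
  expect_error(estimate_rates(ser), "closed")
  # missing frames split segments; dwells across the gap are discarded
  open <- rep(c(FALSE, TRUE), 20)
  open[15] <- NA
  ser2 <- series_from_logical(open)
  est <- estimate_rates(ser2, estimator = "geometric", n_boot = 5)
  expect_true(est$n_events_open > 0)
})

test_that("sampled-chain inversion is less biased than naive rates", {
  # fast regime, rates comparable to the frame rate: within-frame round
  # trips bias dwell-based estimators; compare against Gillespie truth
  k_open <- 2.5; k_close <- 2.0
  set.seed(46)
  tr <- hexamertools:::simulate_ring_trajectory(k_open, k_close, 4000)
  st <- hexamertools:::sample_trajectory(tr, (seq_len(20000) - 1) / 5)
  ser <- ring_state_series(st, 5)
  e_ctmc <- estimate_rates(ser, estimator = "ctmc", n_boot = 2)
  e_geom <- estimate_rates(ser, estimator = "geometric", n_boot = 2)
  e_naive <- estimate_rates(ser, estimator = "naive", n_boot = 2)
  err <- function(e) abs(e$k_open - k_open) + abs(e$k_close - k_close)
  expect_lt(err(e_ctmc), err(e_geom))
  expect_lt(err(e_geom), err(e_naive))
  expect_lt(abs(e_ctmc$k_open - k_open) / k_open, 0.10)
})

test_that("dwell-estimator bias shrinks as event count grows", {
  k_open <- 1.5; k_close <- 0.99
  err_at <- function(n_frames, seed) {
    set.seed(seed)
    tr <- hexamertools:::simulate_ring_trajectory(k_open, k_close,
                                                  n_frames / 5)
    ser <- ring_state_series(
      hexamertools:::sample_trajectory(tr, (seq_len(n_frames) - 1) / 5), 5)
    e <- estimate_rates(ser, n_boot = 2)
    abs(e$k_open - k_open) / k_open
  }
  small <- mean(vapply(1:6, function(s) err_at(300, s), 1))
  large <- mean(vapply(1:6, function(s) err_at(12000, s + 50), 1))
  expect_lt(large, small)
  expect_lt(large, 0.05)
})

test_that("randomness tests flag ordered activation and accept uniform", {
  # strictly sequential openings: step test concentrates on delta = 1
  seq_ser <- series_from_events(rep(1:6, 8))
  rep_seq <- randomness_tests(seq_ser)
  expect_lt(rep_seq$step$p, 0.05)
  # all openings at one subunit: uniformity rejected
  one_ser <- series_from_events(rep(3, 40))
  rep_one <- randomness_tests(one_ser)
  expect_lt(rep_one$uniformity$p, 1e-6)
  # few events: exact multinomial branch engages and is flagged
  few <- randomness_tests(series_from_events(c(1, 4, 2, 6, 3)))
  expect_equal(few$uniformity$method, "exact multinomial")
  expect_gte(few$uniformity$p, 0)
  expect_lte(few$uniformity$p, 1)
})

test_that("uniformity test is calibrated at the nominal level", {
  set.seed(47)
  n_rep <- 400
  rejects <- vapply(seq_len(n_rep), function(i) {
    ev <- sample.int(6, 60, replace = TRUE)
    randomness_tests(series_from_events(ev))$uniformity$p < 0.05
  }, logical(1))
  rate <- mean(rejects)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 3 * se + 0.01)
})

test_that("exact multinomial p-value agrees with chi-square for medium n", {
  counts <- c(10, 6, 5, 9, 7, 5)
  p_exact <- hexamertools:::exact_multinomial_p(counts)
  p_chi <- chisq.test(counts, p = rep(1 / 6, 6))$p.value
  expect_lt(abs(p_exact - p_chi), 0.12)
  # a wildly non-uniform configuration has a tiny exact p
  expect_lt(hexamertools:::exact_multinomial_p(c(20, 0, 0, 0, 0, 0)), 1e-8)
})
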