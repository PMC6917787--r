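# Generators: parameter validation, seeded determinism, and agreement of
# rendered data with the planted ground truth.

test_that("parameter constructors reject invalid inputs", {
  expect_error(ring_dynamics_params(frame_rate = 0), "frame_rate")
  expect_error(ring_dynamics_params(pixel_size = -1), "pixel_size")
  expect_error(ring_dynamics_params(open_drop_fraction = 0), "open_drop")
  expect_error(ring_dynamics_params(k_open = -1), "k_open")
  expect_error(curtain_scene_params(occupancy_p = 1.2), "occupancy_p")
  expect_error(titration_params(kd_true = -5), "kd_true")
  expect_error(titration_params(r_free = 0.3, r_bound = 0.2), "r_bound")
  expect_error(atpase_trace_params(dt = 0), "dt")
  expect_error(toy_hexamer_spec(n_subunits = 2), "n_subunits")
})

test_that("absorbing closed state: k_open = 0 keeps every frame closed", {
  p <- ring_dynamics_params(k_open = 0, n_frames = 40, n_molecules = 2,
                            seed = 5)
  rm <- simulate_ring_movie(p)
  for (tr in rm$truth) {
    expect_true(all(vapply(tr$open, length, 1L) == 0))
    expect_equal(open_fraction(tr), 0)
  }
})

test_that("identical seeds give bit-identical movies", {
  p <- ring_dynamics_params(n_frames = 15, n_molecules = 2, seed = 9)
  m1 <- simulate_ring_movie(p)
  m2 <- simulate_ring_movie(p)
  expect_identical(m1$movie, m2$movie)
  expect_identical(m1$truth, m2$truth)
  c1 <- simulate_curtain_movie(curtain_scene_params(n_dna = 5, seed = 3))
  c2 <- simulate_curtain_movie(curtain_scene_params(n_dna = 5, seed = 3))
  expect_identical(c1$red, c2$red)
  t1 <- simulate_atpase_trace(atpase_trace_params(seed = 2))
  t2 <- simulate_atpase_trace(atpase_trace_params(seed = 2))
  expect_identical(t1$absorbance_360, t2$absorbance_360)
})

test_that("open-state occupancy matches the two-state stationary fraction", {
  k_open <- 1.5; k_close <- 0.99
  stat_frac <- k_open / (k_open + k_close)          # 0.602
  p <- ring_dynamics_params(k_open = k_open, k_close = k_close,
                            frame_rate = 5, n_frames = 12000,
                            n_molecules = 1, noise_sd = 0, seed = 11)
  rm <- simulate_ring_movie(p)
  frac <- open_fraction(rm$truth[[1]])
  # autocorrelation-aware standard error: effective samples ~ T (ko + kc)
  t_total <- p$n_frames / p$frame_rate
  se <- sqrt(stat_frac * (1 - stat_frac) / (t_total * (k_open + k_close)))
  expect_lt(abs(frac - stat_frac), 3 * se)
  # independent discrete-time Monte-Carlo count agrees too
  mc <- oracle_open_fraction(k_open, k_close, t_total = 1500, seed = 4)
  expect_lt(abs(frac - mc), 4 * se)
})

test_that("double-open branch produces two-subunit open states", {
  p <- ring_dynamics_params(k_open = 3, k_close = 0.8, n_frames = 2000,
                            n_molecules = 1, allow_double_open = TRUE,
                            noise_sd = 0, seed = 13)
  rm <- simulate_ring_movie(p)
  sizes <- vapply(rm$truth[[1]]$open, length, 1L)
  expect_true(any(sizes == 2))
  expect_true(all(sizes <= 2))
})

test_that("curtain ground truth matches the rendered scene", {
  # occupancy 1: every DNA carries at least one spot
  p1 <- curtain_scene_params(n_dna = 12, occupancy_p = 1, seed = 7)
  m1 <- simulate_curtain_movie(p1)
  expect_true(all(m1$dna$n_spots >= 1))
  # planted spots are local maxima of the flow-on red signal
  on_frame <- which(m1$flow_schedule)[1]
  for (s in seq_len(nrow(m1$spots))) {
    x <- m1$dna$x_px[m1$spots$dna_id[s]]
    y <- round(m1$barrier_row + m1$spots$pos_px[s])
    y <- min(max(y, 3), dim(m1$red)[1] - 2)
    patch <- m1$red[(y - 2):(y + 2), x, on_frame]
    far <- m1$red[max(1, y - 8), x, on_frame]
    expect_gt(max(patch), far)
  }
  # occupancy 0, no distractors: red channel is background noise
  p0 <- curtain_scene_params(n_dna = 12, occupancy_p = 0,
                             n_stuck_distractors = 0, seed = 8)
  m0 <- simulate_curtain_movie(p0)
  expect_lt(abs(mean(m0$red) - p0$background), 1)
  expect_equal(nrow(m0$spots), 0)
})

test_that("stuck distractors persist at flow-off; DNA-bound signal does not", {
  p <- curtain_scene_params(n_dna = 4, occupancy_p = 1,
                            n_stuck_distractors = 1, seed = 15,
                            position_distribution = 0.5)
  m <- simulate_curtain_movie(p)
  on_f <- which(m$flow_schedule)[5]
  off_f <- which(!m$flow_schedule)[2]
  px_at <- function(x, y, f) mean(m$red[round(y) + (-1:1), round(x), f])
  d <- m$distractors
  lvl_on <- px_at(d$x_px[1], d$y_px[1], on_f) - p$background
  lvl_off <- px_at(d$x_px[1], d$y_px[1], off_f) - p$background
  expect_gt(lvl_off, 0.5 * lvl_on)          # distractor unchanged
  s <- m$spots[1, ]
  sy <- m$barrier_row + s$pos_px
  sp_on <- px_at(m$dna$x_px[s$dna_id], sy, on_f) - p$background
  sp_off <- px_at(m$dna$x_px[s$dna_id], sy, off_f) - p$background
  expect_lt(sp_off, 0.3 * sp_on)            # bound spot vanishes
})

test_that("titration generator: boundary cases and noiseless round trip", {
  # titrant 0, noiseless: anisotropy is exactly r_free
  p <- titration_params(noise_sd = 0, seed = 1)
  tt <- simulate_titration(p)
  expect_equal(tt$anisotropy[tt$titrant_conc == 0], p$r_free)
  # stoichiometric limit kd = 0: saturation exactly once titrant >= labeled
  p0 <- titration_params(kd_true = 0, noise_sd = 0,
                         titrant_concs = c(0, 5, 10, 20, 50, 100))
  t0 <- simulate_titration(p0)
  sat <- t0$titrant_conc >= p0$labeled_conc
  expect_equal(t0$anisotropy[sat], rep(p0$r_bound, sum(sat)))
  expect_true(all(t0$anisotropy[!sat & t0$titrant_conc > 0] < p0$r_bound))
  # cross-module round trip: noiseless refit recovers kd to machine precision
  pk <- titration_params(kd_true = 37.5, noise_sd = 0)
  fit <- fit_binding(simulate_titration(pk), labeled_conc = pk$labeled_conc,
                     n_boot = 0)
  expect_lt(abs(fit$kd - 37.5) / 37.5, 1e-6)
})

test_that("phosphate-release traces are affine with the planted slope", {
  p <- atpase_trace_params(rate_true = 0, noise_sd = 0)
  tr <- simulate_atpase_trace(p)
  expect_equal(tr$absorbance_360, rep(p$baseline, p$n_points))
  p2 <- atpase_trace_params(rate_true = 0.7, hexamer_conc = 80,
                            calib_slope = 0.02, noise_sd = 0)
  tr2 <- simulate_atpase_trace(p2)
  slope <- unname(coef(lm(absorbance_360 ~ time_s, tr2))[2])
  # absorbance/s = calib (A/uM) * rate (1/s) * [hexamer] (uM)
  expect_equal(slope, 0.02 * 0.7 * 80 / 1000, tolerance = 1e-10)
  expect_equal(tr2$time_s[1:3], c(5, 15, 25))
})

test_that("toy hexamer geometry is exact and round-trips through PDB", {
  spec <- toy_hexamer_spec(ring_radius = 5, rise_per_subunit = 0, seed = 21)
  f <- withr::local_tempfile(fileext = ".pdb")
  th <- make_toy_hexamer(spec, path = f)
  cent <- th$truth
  # equal angular spacing: adjacent centroid distances all equal
  d_adj <- sqrt(diff(cent$cx)^2 + diff(cent$cy)^2 + diff(cent$cz)^2)
  expect_equal(max(d_adj) - min(d_adj), 0, tolerance = 1e-9)
  expect_equal(cent$cz, rep(0, 6))
  # centroids are exact by centro-symmetric construction
  got <- aggregate(cbind(x, y, z) ~ chain, th$model$atoms, mean)
  expect_equal(unname(as.matrix(got[, 2:4])),
               unname(as.matrix(cent[, c("cx", "cy", "cz")])),
               tolerance = 1e-9)
  # file round trip preserves coordinates to PDB precision
  back <- read_structure(f)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(th$model$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})
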