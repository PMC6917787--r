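# Pseudo-AFM simulation: closed-form contact heights against analytic
# limits and the brute-force tip-lowering oracle; filter response.

test_that("sharp-tip limit reproduces the sphere envelope", {
  a <- 2
  m <- sphere_model(c(0, 0, a), a)
  tp <- tip_model(apex_radius = 1e-6, half_cone_angle = 1e-4)
  hm <- simulate_height_map(m, tp, pixel_size = 0.05,
                            bounds = list(xlim = c(-3, 3), ylim = c(0, 0)))
  xs <- seq(hm$origin[1], by = 0.05, length.out = ncol(hm$heights))
  h_expect <- ifelse(abs(xs) < a, a + sqrt(pmax(a^2 - xs^2, 0)), 0)
  # the envelope jumps at |x| = a (needle grazing the equator); compare
  # away from that measure-zero boundary
  keep <- abs(abs(xs) - a) > 0.026
  expect_equal(hm$heights[1, keep], h_expect[keep], tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("spherical-cap regime matches its closed form", {
  a <- 1.5; R <- 0.5; alpha <- 10
  m <- sphere_model(c(0, 0, a), a)
  hm <- simulate_height_map(m, tip_model(R, alpha), pixel_size = 0.1,
                            bounds = list(xlim = c(-1.6, 1.6),
                                          ylim = c(0, 0)))
  xs <- seq(hm$origin[1], by = 0.1, length.out = ncol(hm$heights))
  cap <- abs(xs) <= (R + a) * cos(alpha * pi / 180)
  h_expect <- a + sqrt((R + a)^2 - xs[cap]^2) - R
  expect_equal(hm$heights[1, cap], h_expect, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("dilation distributes over union as pointwise max", {
  tp <- tip_model(0.5, 10)
  b <- list(xlim = c(-4, 7), ylim = c(-4, 4))
  m1 <- sphere_model(c(0, 0, 1.2), 1.2)
  m2 <- sphere_model(c(3, 0.5, 0.8), 0.8)
  mu <- sphere_model(rbind(c(0, 0, 1.2), c(3, 0.5, 0.8)), c(1.2, 0.8))
  h1 <- simulate_height_map(m1, tp, 0.2, b)$heights
  h2 <- simulate_height_map(m2, tp, 0.2, b)$heights
  hu <- simulate_height_map(mu, tp, 0.2, b)$heights
  expect_equal(hu, pmax(h1, h2), tolerance = 1e-12)
})

test_that("closed form matches the brute-force tip-lowering oracle", {
  set.seed(31)
  for (rep in 1:2) {
    n <- sample(3:6, 1)
    centers <- cbind(runif(n, -1.5, 1.5), runif(n, -1.5, 1.5),
                     runif(n, 0.5, 2))
    radii <- runif(n, 0.3, 0.8)
    centers[, 3] <- pmax(centers[, 3], radii)  # above the substrate
    xs <- seq(-2, 2, by = 0.4)
    ys <- seq(-2, 2, by = 0.4)
    hm <- simulate_height_map(sphere_model(centers, radii),
                              tip_model(0.5, 10), pixel_size = 0.4,
                              bounds = list(xlim = range(xs), ylim = range(ys)))
    orc <- oracle_height_map(centers, radii, 0.5, 10, xs, ys,
                             offset_step = 0.02)
    # oracle resolves contacts to its offset step; slope is at most ~O(few)
    expect_lt(max(abs(hm$heights - orc)), 0.08)
  }
})

test_that("larger tips broaden but never change the peak height", {
  set.seed(32)
  centers <- cbind(runif(5, -1, 1), runif(5, -1, 1), runif(5, 0.8, 1.6))
  radii <- runif(5, 0.4, 0.7)
  m <- sphere_model(centers, radii)
  b <- list(xlim = c(-4, 4), ylim = c(-4, 4))
  h_small <- simulate_height_map(m, tip_model(0.3, 10), 0.2, b)$heights
  h_big <- simulate_height_map(m, tip_model(1.5, 10), 0.2, b)$heights
  expect_true(all(h_big >= h_small - 1e-9))
  z_top <- max(centers[, 3] + radii)
  expect_equal(max(h_small), z_top, tolerance = 0.01)
  expect_equal(max(h_big), z_top, tolerance = 0.01)
})

test_that("the height map is translation-equivariant", {
  tp <- tip_model(0.5, 10)
  m0 <- sphere_model(c(0, 0, 1), 1)
  m1 <- sphere_model(c(2, 0, 1), 1)
  h0 <- simulate_height_map(m0, tp, 0.25,
                            list(xlim = c(-3, 3), ylim = c(-2, 2)))$heights
  h1 <- simulate_height_map(m1, tp, 0.25,
                            list(xlim = c(-1, 5), ylim = c(-2, 2)))$heights
  expect_equal(h0, h1, tolerance = 1e-12)
})

test_that("sphere-model construction handles orientation and radii", {
  at <- data.frame(chain = "A", resno = 1:3, resid = "ALA",
                   elety = c("CA", "CB", "N"), elesy = c("C", "C", "N"),
                   x = c(0, 5, 0), y = c(0, 0, 5), z = c(0, 3, 10))
  sm <- structure_model(at, source = "demo")
  top <- build_sphere_model(sm, "top")
  bot <- build_sphere_model(sm, "bottom")
  # bottom view equals top view rotated 180 degrees about x (then re-grounded)
  flip <- top$centers %*% diag(c(1, -1, -1))
  flip[, 2] <- flip[, 2] - mean(range(flip[, 2]))
  flip[, 3] <- flip[, 3] - min(flip[, 3] - top$radii)
  expect_equal(unname(bot$centers), unname(flip), tolerance = 1e-12)
  # single atom with uniform radius a rests with centre at z = a
  one <- structure_model(at[1, ], source = "one")
  u <- build_sphere_model(one, "top", radius_scheme = "uniform",
                          uniform_radius = 0.4)
  expect_equal(unname(u$centers[1, 3]), 0.4)
  # element scheme recorded in provenance, carbon radius applied
  expect_equal(top$provenance$radius_scheme, "element")
  expect_equal(top$radii[1], 0.17)
  expect_error(build_sphere_model(structure_model(at[0, , drop = FALSE])),
               "no atoms")
})

test_that("low-pass filter: DC gain, identity limit, half-power point", {
  img <- matrix(3.7, 32, 32)
  lp <- lowpass_filter(height_map(img, 0.5), cutoff_wavelength = 2)
  expect_equal(lp$heights, img, tolerance = 1e-12)
  set.seed(33)
  ran <- matrix(runif(32 * 32), 32, 32)
  # cutoff wavelength far below the pixel scale: nothing to remove,
  # the filter approaches the identity (and warns that it is ineffective)
  lp_id <- suppressWarnings(
    lowpass_filter(height_map(ran, 0.5), cutoff_wavelength = 0.001))
  expect_equal(lp_id$heights, ran, tolerance = 1e-5)
  # cutoff wavelength far above every feature: only the mean survives
  lp_dc <- lowpass_filter(height_map(ran, 0.5), cutoff_wavelength = 1e6)
  expect_equal(lp_dc$heights, matrix(mean(ran), 32, 32), tolerance = 1e-6)
  # sinusoid at the cutoff wavelength is attenuated by exactly 1/sqrt(2)
  px <- 0.25; lam <- 2
  x <- matrix(rep(seq_len(64), each = 64), 64, 64)
  s <- 1 + 0.5 * sin(2 * pi * x * px / lam)
  lps <- lowpass_filter(height_map(s, px), lam)
  ratio <- (max(lps$heights) - min(lps$heights)) / (max(s) - min(s))
  expect_equal(ratio, 1 / sqrt(2), tolerance = 1e-6)
  expect_warning(lowpass_filter(height_map(img, 1.5), 2), "Nyquist")
})
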