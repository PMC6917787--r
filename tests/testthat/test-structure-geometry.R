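# Structure geometry: coordinate I/O, superposition against the quaternion
# oracle, domain metrics with planted ground truth, ring metrics.

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

test_that("PDB round trip preserves chains, gaps and coordinates", {
  at <- data.frame(chain = rep(c("A", "B"), each = 4),
                   resno = c(1, 2, 5, 6, 1, 2, 3, 9),  # deliberate gaps
                   resid = "ALA", elety = "CA", elesy = "C",
                   x = rnorm(8) * 10, y = rnorm(8) * 10, z = rnorm(8) * 10)
  m <- structure_model(at, source = "gapped")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  back <- read_structure(f)
  expect_equal(back$atoms$chain, at$chain)
  expect_equal(back$atoms$resno, at$resno)     # gaps preserved, not filled
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(at[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_error(read_structure("does_not_exist.pdb"), "no such file")
})

test_that("superposition: identity, rotation recovery, inverse consistency", {
  th <- make_toy_hexamer(toy_hexamer_spec(seed = 71))
  m <- th$model
  sp_id <- superpose(m, m)
  expect_equal(sp_id$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp_id$rotation, diag(3), tolerance = 1e-9)
  R <- random_rotation(72)
  mr <- m
  mr$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(m$atoms[, c("x", "y", "z")]) %*% R, 2, c(7, -4, 12), `+`)
  sp <- superpose(mr, m)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  moved <- sp$transform(mr)
  expect_equal(as.matrix(moved$atoms[, c("x", "y", "z")]),
               as.matrix(m$atoms[, c("x", "y", "z")]), tolerance = 1e-9,
               ignore_attr = TRUE)
  # inverse consistency
  sp_fwd <- superpose(m, mr)
  comp <- sp$rotation %*% sp_fwd$rotation
  expect_equal(comp, diag(3), tolerance = 1e-9)
  # selection restricting to chain A only still superposes
  spA <- superpose(mr, m, selection = list(chain = "A"))
  expect_equal(spA$rmsd, 0, tolerance = 1e-9)
  expect_error(superpose(m, mr, selection = list(chain = "A", resno = 1)),
               "3 paired")
})

test_that("superposition RMSD matches the quaternion oracle on noisy pairs", {
  set.seed(73)
  for (rep in 1:4) {
    X <- matrix(rnorm(150, sd = 8), ncol = 3)
    Y <- X %*% random_rotation(rep) + matrix(rnorm(150, sd = 1.5), ncol = 3)
    mx <- structure_model(data.frame(chain = "A", resno = 1:50, resid = "ALA",
                                     elety = "CA", elesy = "C",
                                     x = X[, 1], y = X[, 2], z = X[, 3]))
    my <- structure_model(data.frame(chain = "A", resno = 1:50, resid = "ALA",
                                     elety = "CA", elesy = "C",
                                     x = Y[, 1], y = Y[, 2], z = Y[, 3]))
    expect_equal(superpose(mx, my)$rmsd, oracle_superpose_rmsd(X, Y),
                 tolerance = 1e-6)
  }
})

test_that("subunit metrics recover planted distances and angles exactly", {
  d_true <- c(A = 40, B = 40, C = 41.2, D = 40, E = 40, F = 44.9)
  th_true <- c(A = 95, B = 95, C = 96, D = 95, E = 95, F = 106)
  m <- make_synthetic_spiral_hexamer(d_true, th_true, seed = 74)
  sm <- subunit_metrics(m, synthetic_hexamer_domains())
  expect_equal(sm$d_NBD, unname(d_true), tolerance = 1e-9)
  expect_equal(sm$theta_HBD, unname(th_true), tolerance = 1e-9)
  expect_equal(sm$delta_d_NBD[sm$chain == "F"], 4.9, tolerance = 1e-9)
  expect_equal(sm$delta_theta[sm$chain == "C"], 1, tolerance = 1e-9)
  # metrics are invariant under a global rigid-body transform
  R <- random_rotation(75)
  mr <- m
  mr$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(m$atoms[, c("x", "y", "z")]) %*% R, 2, c(3, 5, -9), `+`)
  sm_r <- subunit_metrics(mr, synthetic_hexamer_domains())
  expect_equal(sm_r$d_NBD, sm$d_NBD, tolerance = 1e-9)
  expect_equal(sm_r$theta_HBD, sm$theta_HBD, tolerance = 1e-9)
  # deltas are antisymmetric under reference-chain swap
  sm_F <- subunit_metrics(m, synthetic_hexamer_domains(), ref_chain = "F")
  expect_equal(sm_F$delta_d_NBD[sm_F$chain == "A"],
               -sm$delta_d_NBD[sm$chain == "F"], tolerance = 1e-9)
  # an unresolvable domain names the chain and domain in its error
  bad <- domain_definition(AAA1_NBD = c(1, 8), AAA2_NBD = c(101, 108),
                           AAA2_HBD = c(900, 950))
  expect_error(subunit_metrics(m, bad), "AAA2_HBD.*chain A")
})

test_that("collinear centroids give a 180-degree angle by convention", {
  mk <- function(centre, chain, res0) {
    off <- rbind(diag(3), -diag(3)) * 1.5
    data.frame(chain = chain, resno = res0 + 1:6, resid = "ALA",
               elety = "CA", elesy = "C",
               x = centre[1] + off[, 1], y = centre[2] + off[, 2],
               z = centre[3] + off[, 3])
  }
  at <- rbind(mk(c(-20, 0, 0), "A", 0), mk(c(20, 0, 0), "A", 100),
              mk(c(0, 0, 0), "A", 200))
  m <- structure_model(at)
  dom <- domain_definition(AAA1_NBD = c(1, 6), AAA2_NBD = c(101, 106),
                           AAA2_HBD = c(201, 206))
  sm <- subunit_metrics(m, dom, ref_chain = "A")
  expect_equal(sm$theta_HBD, 180, tolerance = 1e-9)
  expect_equal(sm$d_NBD, 40, tolerance = 1e-9)
})

test_that("ring metrics: planar rings, spiral rises, analytic pore", {
  planar <- make_toy_hexamer(toy_hexamer_spec(rise_per_subunit = 0, seed = 76))
  rm0 <- ring_metrics(planar$model)
  expect_lt(diff(range(rm0$rise)), 1e-6)
  spiral <- make_toy_hexamer(toy_hexamer_spec(rise_per_subunit = 0.7, seed = 77))
  rm1 <- ring_metrics(spiral$model)
  expect_equal(unname(diff(rm1$rise)), rep(7, 5), tolerance = 1e-3)
  # six single-sphere subunits at ring radius r: pore diameter 2 (r - a)
  ang <- 2 * pi * (0:5) / 6
  at <- data.frame(chain = LETTERS[1:6], resno = 1, resid = "ALA",
                   elety = "CA", elesy = "C",
                   x = 50 * cos(ang), y = 50 * sin(ang), z = 0)
  pm <- ring_metrics(structure_model(at), slab_width = 10)
  expect_equal(pm$pore_diameter, 2 * (50 - 1.7), tolerance = 1e-6)
  # adjacent gaps of the single-atom ring are all equal by symmetry
  expect_lt(diff(range(pm$adjacent_gap)), 1e-6)
  expect_equal(unname(pm$adjacent_gap[1]), 50, tolerance = 1e-6)
  expect_error(ring_metrics(structure_model(at[1:2, ])), "3 chains")
})
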