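# Independent oracles used to validate the closed-form implementations.
# These deliberately share no code with the package internals.

# Brute-force pseudo-AFM oracle: numerically lower a discretised tip until
# first overlap with the sphere model. Equivalent formulation: grey-scale
# dilation h(x) = max_u [ top(u) - tip(u - x) ] over a fine offset grid.
oracle_height_map <- function(centers, radii, apex_radius, half_cone_deg,
                              xs, ys, offset_step = 0.05) {
  alpha <- half_cone_deg * pi / 180
  reach <- max(radii + apex_radius) + max(centers[, 3] + radii) *
    tan(alpha) + 1
  off <- seq(-reach, reach, by = offset_step)
  og <- expand.grid(dx = off, dy = off)
  rho <- sqrt(og$dx^2 + og$dy^2)
  # tip surface height above the apex at lateral distance rho
  rt <- apex_radius * cos(alpha)
  tipz <- ifelse(rho <= rt,
                 apex_radius - sqrt(pmax(apex_radius^2 - rho^2, 0)),
                 apex_radius * (1 - sin(alpha)) + (rho - rt) / tan(alpha))
  H <- matrix(0, length(ys), length(xs))
  for (iy in seq_along(ys)) for (ix in seq_along(xs)) {
    ux <- xs[ix] + og$dx
    uy <- ys[iy] + og$dy
    best <- 0
    for (s in seq_len(nrow(centers))) {
      d2 <- (ux - centers[s, 1])^2 + (uy - centers[s, 2])^2
      inside <- d2 < radii[s]^2
      if (!any(inside)) next
      top <- centers[s, 3] + sqrt(radii[s]^2 - d2[inside])
      best <- max(best, max(top - tipz[inside]))
    }
    H[iy, ix] <- best
  }
  H
}

# Horn's quaternion method for optimal rigid superposition; returns the
# RMSD after the best rotation. Independent of the SVD route.
oracle_superpose_rmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- t(Xc) %*% Yc
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
              3, 3, byrow = TRUE)
  sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
}

# Long-run discrete-time Monte-Carlo count of the open-state fraction of
# the two-state process, on a time grid much finer than both rates.
oracle_open_fraction <- function(k_open, k_close, t_total = 3000, dt = 0.005,
                                 seed = 1) {
  set.seed(seed)
  n <- ceiling(t_total / dt)
  p_oc <- k_close * dt
  p_co <- k_open * dt
  u <- runif(n)
  state <- logical(n)
  s <- FALSE
  for (i in seq_len(n)) {
    s <- if (s) u[i] >= p_oc else u[i] < p_co
    state[i] <- s
  }
  mean(state)
}

# Brute-force two-Gaussian fit by grid search over the two centres with
# per-grid-point linear least squares for amplitudes + baseline.
oracle_two_gauss_centers <- function(y, width, step = 0.25) {
  xs <- seq_along(y)
  grid <- seq(2, length(y) - 1, by = step)
  best <- c(NA, NA); best_rss <- Inf
  for (i in seq_along(grid)) for (j in seq_along(grid)) {
    if (grid[j] <= grid[i]) next
    g1 <- exp(-(xs - grid[i])^2 / (2 * width^2))
    g2 <- exp(-(xs - grid[j])^2 / (2 * width^2))
    ft <- lm.fit(cbind(1, g1, g2), y)
    rss <- sum(ft$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best <- c(grid[i], grid[j]) }
  }
  sort(best)
}
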