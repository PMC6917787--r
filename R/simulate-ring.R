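# Synthetic HS-AFM movies of hexameric rings with stochastic subunit opening.
#
# State dynamics are simulated exactly in continuous time (Gillespie draws)
# and then sampled at the frame instants, so frame-rate censoring enters only
# through the observation step — the dwell-time estimators can then be
# studied against clean ground truth.

# -- continuous-time state simulation ---------------------------------------

#' Simulate one molecule's subunit open/close trajectory
#'
#' States: closed (no subunit open), one subunit open, or (optionally) two
#' subunits open. Transition rates: closed -> open at `k_open` (opened
#' subunit drawn uniformly), open -> closed at `k_close`; with the
#' double-open branch enabled, open -> double-open at `k_open` and
#' double-open -> open at `2 * k_close` (each open subunit closes
#' independently).
#'
#' @return data.frame with columns `time` (s, entry time) and `open`
#'   (comma-separated open subunit indices, "" = closed).
#' @noRd
simulate_ring_trajectory <- function(k_open, k_close, t_end,
                                     allow_double_open = FALSE,
                                     n_subunits = 6L) {
  times <- 0
  open_sets <- list(integer(0))
  t <- 0
  open <- integer(0)
  while (t < t_end) {
    n_open <- length(open)
    if (n_open == 0L) {
      rate_total <- k_open
      if (rate_total <= 0) break
      t <- t + stats::rexp(1, rate_total)
      open <- sample.int(n_subunits, 1L)
    } else if (n_open == 1L) {
      r_open2 <- if (allow_double_open) k_open else 0
      rate_total <- k_close + r_open2
      t <- t + stats::rexp(1, rate_total)
      if (stats::runif(1) < k_close / rate_total) {
        open <- integer(0)
      } else {
        open <- sort(c(open, sample(setdiff(seq_len(n_subunits), open), 1L)))
      }
    } else {
      rate_total <- n_open * k_close
      t <- t + stats::rexp(1, rate_total)
      open <- sort(sample(open, n_open - 1L))
    }
    if (t >= t_end) break
    times <- c(times, t)
    open_sets <- c(open_sets, list(open))
  }
  list(times = times, open_sets = open_sets)
}

#' Sample a trajectory at frame instants
#' @noRd
sample_trajectory <- function(traj, frame_times) {
  idx <- findInterval(frame_times, traj$times)
  traj$open_sets[idx]
}

# -- rendering --------------------------------------------------------------

#' Render geometry cache for one ring particle
#' @noRd
ring_render_cache <- function(patch_px, pixel_size, cx, cy, fwhm,
                              radial_sigma, lobe_contrast, phase) {
  xs <- (seq_len(patch_px) - 0.5) * pixel_size
  gx <- matrix(xs, patch_px, patch_px, byrow = TRUE) - cx
  gy <- matrix(xs, patch_px, patch_px, byrow = FALSE) - cy
  d <- sqrt(gx^2 + gy^2)
  theta <- atan2(gy, gx)
  r_ring <- fwhm / 2 - radial_sigma * sqrt(2 * log(2))
  stop_if(r_ring <= 0,
          "ring_outer_fwhm %.3g nm too small for radial_sigma %.3g nm",
          fwhm, radial_sigma)
  radial <- exp(-(d - r_ring)^2 / (2 * radial_sigma^2))
  modulation <- 1 - lobe_contrast * (1 - cos(6 * (theta - phase))) / 2
  sector <- (round((theta - phase) / (pi / 3)) %% 6) + 1
  list(radial = radial, modulation = modulation,
       sector = array(as.integer(sector), dim(radial)), r_ring = r_ring)
}

#' Simulate an HS-AFM movie of hexameric rings with stochastic opening
#'
#' Each molecule's subunit dynamics follow an exact continuous-time Markov
#' chain sampled at the frame rate; an open subunit is rendered with its
#' lobe height scaled by `1 - open_drop_fraction`. The rendered surface is a
#' six-fold angularly modulated Gaussian annulus, so the distance between
#' the outermost half-maximum crossings through the centre equals the
#' planted apparent width along every direction.
#'
#' @param params a [ring_dynamics_params()] object.
#' @return A list of class `ring_movie`:
#'   \item{movie}{numeric array (rows, cols, frames) of heights in nm}
#'   \item{pixel_size, frame_rate}{imaging geometry}
#'   \item{molecules}{data.frame of ground-truth particle centres (nm),
#'     planted apparent widths and lobe phases}
#'   \item{truth}{list (one per molecule) of `ring_state_series` ground
#'     truth: per-frame open-subunit sets}
#' @export
simulate_ring_movie <- function(params) {
  stopifnot(inherits(params, "ring_dynamics_params"))
  p <- params
  set.seed(p$seed)
  patch_nm <- p$ring_outer_fwhm + max(3 * p$ring_fwhm_sd, 0) + 8 * p$radial_sigma
  patch_px <- as.integer(ceiling(patch_nm / p$pixel_size))
  n_col <- as.integer(ceiling(sqrt(p$n_molecules)))
  n_row <- as.integer(ceiling(p$n_molecules / n_col))
  ny <- n_row * patch_px
  nx <- n_col * patch_px
  frame_times <- (seq_len(p$n_frames) - 1L) / p$frame_rate
  t_end <- p$n_frames / p$frame_rate

  movie <- array(0, dim = c(ny, nx, p$n_frames))
  truth <- vector("list", p$n_molecules)
  mol <- data.frame(id = seq_len(p$n_molecules), row0 = 0L, col0 = 0L,
                    cx = 0, cy = 0, fwhm_true = 0, phase = 0)

  for (m in seq_len(p$n_molecules)) {
    gr <- (m - 1L) %/% n_col
    gc <- (m - 1L) %% n_col
    fwhm_m <- p$ring_outer_fwhm +
      if (p$ring_fwhm_sd > 0) stats::rnorm(1, 0, p$ring_fwhm_sd) else 0
    fwhm_m <- max(fwhm_m, 6 * p$radial_sigma * sqrt(2 * log(2)) / 2)
    phase <- stats::runif(1, 0, pi / 3)
    centre <- patch_px * p$pixel_size / 2
    cache <- ring_render_cache(patch_px, p$pixel_size, centre, centre,
                               fwhm_m, p$radial_sigma, p$lobe_contrast, phase)
    traj <- simulate_ring_trajectory(p$k_open, p$k_close, t_end,
                                     p$allow_double_open)
    states <- sample_trajectory(traj, frame_times)
    truth[[m]] <- ring_state_series(states, p$frame_rate)
    base <- p$lobe_height * cache$radial * cache$modulation
    rows <- gr * patch_px + seq_len(patch_px)
    cols <- gc * patch_px + seq_len(patch_px)
    for (f in seq_len(p$n_frames)) {
      open <- states[[f]]
      if (length(open) == 0L) {
        movie[rows, cols, f] <- movie[rows, cols, f] + base
      } else {
        amp <- rep(1, 6)
        amp[open] <- 1 - p$open_drop_fraction
        movie[rows, cols, f] <- movie[rows, cols, f] +
          base * amp[cache$sector]
      }
    }
    mol$row0[m] <- gr * patch_px
    mol$col0[m] <- gc * patch_px
    mol$cy[m] <- gr * patch_px * p$pixel_size + centre
    mol$cx[m] <- gc * patch_px * p$pixel_size + centre
    mol$fwhm_true[m] <- fwhm_m
    mol$phase[m] <- phase
  }
  if (p$noise_sd > 0)
    movie <- movie + array(stats::rnorm(length(movie), 0, p$noise_sd), dim(movie))

  structure(list(movie = movie, pixel_size = p$pixel_size,
                 frame_rate = p$frame_rate, patch_px = patch_px,
                 molecules = mol, truth = truth, params = p),
            class = "ring_movie")
}

#' Construct a per-frame ring-state series
#'
#' @param open_sets list (one per frame) of integer vectors of open subunit
#'   indices in 1..6; `integer(0)` or `NULL` marks a closed frame; `NA`
#'   marks a missing frame (particle not detectable).
#' @param frame_rate frames per second.
#' @param registration optional per-frame angular offsets (degrees).
#' @return An object of class `ring_state_series`.
#' @export
ring_state_series <- function(open_sets, frame_rate, registration = NULL) {
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  open_sets <- lapply(open_sets, function(s) {
    if (length(s) == 1L && is.na(s)) return(NA_integer_)
    s <- as.integer(s)
    stop_if(any(s < 1L | s > 6L), "subunit indices must be in 1..6")
    sort(s)
  })
  structure(list(open = open_sets, n_frames = length(open_sets),
                 frame_rate = frame_rate, registration = registration),
            class = "ring_state_series")
}

#' @export
print.ring_state_series <- function(x, ...) {
  n_open <- sum(vapply(x$open, function(s) length(s) > 0 && !anyNA(s), TRUE))
  cat(sprintf("Ring-state series: %d frames at %g Hz, %d open frame(s)\n",
              x$n_frames, x$frame_rate, n_open))
  invisible(x)
}

#' @export
print.ring_movie <- function(x, ...) {
  d <- dim(x$movie)
  cat(sprintf("Synthetic ring movie: %d x %d px, %d frames at %g Hz, %d molecule(s)\n",
              d[1], d[2], d[3], x$frame_rate, nrow(x$molecules)))
  invisible(x)
}

#' Fraction of frames with at least one open subunit (ground truth)
#' @param series a `ring_state_series`.
#' @return scalar in `[0, 1]`.
#' @export
open_fraction <- function(series) {
  stopifnot(inherits(series, "ring_state_series"))
  obs <- !vapply(series$open, anyNA, TRUE)
  opn <- vapply(series$open, function(s) length(s) > 0 && !anyNA(s), TRUE)
  sum(opn) / sum(obs)
}
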