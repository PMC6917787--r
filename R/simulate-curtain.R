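# Synthetic two-channel DNA-curtain movies.
#
# Geometry: DNA molecules hang from a barrier row and extend down the image
# while buffer flows; the green channel carries the DNA stain, the red
# channel the labelled histone spots. When flow stops the DNA recoils out
# of the evanescent field, so DNA columns and DNA-bound spots vanish while
# surface-stuck distractor spots persist — the physical basis of flow-off
# validation. Detector model: Poisson shot noise plus Gaussian read noise.

#' Simulate a two-channel DNA-curtain movie with ground truth
#'
#' @param params a [curtain_scene_params()] object.
#' @return A list of class `curtain_movie`:
#'   \item{green,red}{numeric arrays (rows, cols, frames), counts}
#'   \item{flow_schedule}{logical per frame, TRUE = flow on}
#'   \item{dna}{data.frame: `dna_id`, `x_px` (column), `occupied`
#'     (ground truth), `n_spots`}
#'   \item{spots}{ground-truth table: `dna_id`, `pos_px` (distance from the
#'     barrier, pixels), `pos_bp`}
#'   \item{distractors}{table of surface-stuck spot positions}
#'   \item{bp_per_px}{base pairs per pixel along the DNA}
#' @export
simulate_curtain_movie <- function(params) {
  stopifnot(inherits(params, "curtain_scene_params"))
  p <- params
  set.seed(p$seed)
  nx <- (p$n_dna + 1L) * p$dna_spacing_px
  ny <- p$barrier_row + p$dna_length_px + 10L
  nf <- p$n_frames
  bp_per_px <- p$dna_length_bp / p$dna_length_px

  dna <- data.frame(dna_id = seq_len(p$n_dna),
                    x_px = seq_len(p$n_dna) * p$dna_spacing_px,
                    occupied = FALSE, n_spots = 0L)
  # ground-truth spot placement; the occupied count is planted exactly
  # (stratified assignment) so the scene realises the stated occupancy
  # rather than a binomial draw around it
  n_occ <- round(p$occupancy_p * p$n_dna)
  occupied <- sample(rep(c(TRUE, FALSE), c(n_occ, p$n_dna - n_occ)))
  spot_list <- list()
  for (i in which(occupied)) {
    n_sp <- 1L + stats::rpois(1, max(p$spots_per_dna - 1, 0))
    if (is.numeric(p$position_distribution)) {
      frac <- p$position_distribution
      n_sp <- length(frac)
    } else {
      frac <- stats::runif(n_sp)
    }
    pos_px <- frac * p$dna_length_px
    stop_if(any(pos_px < 0 | pos_px >= p$dna_length_px),
            "spot position outside DNA length")
    spot_list[[length(spot_list) + 1L]] <-
      data.frame(dna_id = i, pos_px = pos_px, pos_bp = pos_px * bp_per_px)
  }
  spots <- if (length(spot_list)) do.call(rbind, spot_list) else
    data.frame(dna_id = integer(0), pos_px = numeric(0), pos_bp = numeric(0))
  dna$occupied <- occupied
  dna$n_spots <- as.integer(tabulate(spots$dna_id, nbins = p$n_dna))

  distractors <- data.frame(
    x_px = stats::runif(p$n_stuck_distractors, 1, nx),
    y_px = stats::runif(p$n_stuck_distractors, 1, ny))

  # noiseless per-frame signal templates (flow-on vs flow-off)
  xs <- seq_len(nx); ys <- seq_len(ny)
  gauss2d <- function(x0, y0, amp, sigma) {
    gx <- exp(-(xs - x0)^2 / (2 * sigma^2))
    gy <- exp(-(ys - y0)^2 / (2 * sigma^2))
    amp * outer(gy, gx)
  }
  dna_rows <- p$barrier_row + seq_len(p$dna_length_px) - 1L
  green_on <- matrix(0, ny, nx)
  for (i in seq_len(p$n_dna)) {
    lat <- exp(-(xs - dna$x_px[i])^2 / (2 * p$psf_sigma^2))
    green_on[dna_rows, ] <- green_on[dna_rows, ] +
      matrix(lat * p$photon_rate * 0.5, length(dna_rows), nx, byrow = TRUE)
  }
  red_bound <- matrix(0, ny, nx)
  if (nrow(spots) > 0) for (s in seq_len(nrow(spots))) {
    red_bound <- red_bound + gauss2d(dna$x_px[spots$dna_id[s]],
                                     p$barrier_row + spots$pos_px[s],
                                     p$photon_rate, p$psf_sigma)
  }
  red_stuck <- matrix(0, ny, nx)
  if (nrow(distractors) > 0) for (s in seq_len(nrow(distractors))) {
    red_stuck <- red_stuck + gauss2d(distractors$x_px[s], distractors$y_px[s],
                                     p$photon_rate, p$psf_sigma)
  }

  green <- array(0, dim = c(ny, nx, nf))
  red <- array(0, dim = c(ny, nx, nf))
  for (f in seq_len(nf)) {
    g_sig <- if (p$flow_schedule[f]) green_on else matrix(0, ny, nx)
    r_sig <- red_stuck + if (p$flow_schedule[f]) red_bound else 0
    green[, , f] <- stats::rpois(ny * nx, g_sig + p$background)
    red[, , f] <- stats::rpois(ny * nx, r_sig + p$background)
  }
  if (p$read_noise_sd > 0) {
    green <- green + array(stats::rnorm(length(green), 0, p$read_noise_sd), dim(green))
    red <- red + array(stats::rnorm(length(red), 0, p$read_noise_sd), dim(red))
    green[green < 0] <- 0
    red[red < 0] <- 0
  }

  structure(list(green = green, red = red, flow_schedule = p$flow_schedule,
                 dna = dna, spots = spots, distractors = distractors,
                 barrier_row = p$barrier_row, dna_length_px = p$dna_length_px,
                 bp_per_px = bp_per_px, params = p),
            class = "curtain_movie")
}

#' @export
print.curtain_movie <- function(x, ...) {
  d <- dim(x$red)
  cat(sprintf(paste0("Synthetic DNA-curtain movie: %d x %d px, %d frames, ",
                     "%d DNA (%d occupied), %d stuck distractor(s)\n"),
              d[1], d[2], d[3], nrow(x$dna), sum(x$dna$occupied),
              nrow(x$distractors)))
  invisible(x)
}
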