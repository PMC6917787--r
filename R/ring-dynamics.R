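# Quantification of HS-AFM ring movies: particle detection, apparent-width
# (FWHM) statistics, per-frame ring-state classification into six angular
# sectors, dwell-time rate estimation under frame-rate censoring, and tests
# of subunit-activation randomness.

#' Detect particles in a height image
#'
#' Thresholds the image at `threshold_sd` robust standard deviations above
#' the robust background, labels connected components, and returns
#' intensity-weighted centroids. Particles touching the image border are
#' dropped (their profiles would be truncated).
#'
#' @param image numeric matrix of heights.
#' @param threshold_sd detection threshold in units of the background MAD.
#' @param min_area_px minimum component area (pixels).
#' @param rel_floor lower bound on the threshold as a fraction of the
#'   background-to-peak range, so that (near-)noiseless images, whose
#'   background MAD collapses to zero, still threshold sensibly.
#' @return data.frame: `id`, `cx`, `cy` (pixel coordinates, x = column),
#'   `area`, plus the label matrix as attribute `labels`.
#' @export
detect_particles <- function(image, threshold_sd = 5, min_area_px = 25,
                             rel_floor = 0.2) {
  bg <- robust_background(image)
  # floor keeps the threshold meaningful for (near-)noiseless images,
  # where the background MAD collapses to zero
  thr <- bg$center + max(threshold_sd * bg$spread,
                         rel_floor * (max(image) - bg$center))
  mask <- image > thr
  labels <- EBImage::bwlabel(mask)
  n <- max(labels)
  if (n == 0)
    return(structure(data.frame(id = integer(0), cx = numeric(0),
                                cy = numeric(0), area = integer(0)),
                     labels = labels, background = bg$center))
  rows <- lapply(seq_len(n), function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    if (nrow(idx) < min_area_px) return(NULL)
    if (any(idx[, 1] %in% c(1L, nrow(image))) ||
        any(idx[, 2] %in% c(1L, ncol(image)))) return(NULL)  # touches border
    w <- image[idx] - bg$center
    w <- pmax(w, 0)
    data.frame(id = k, cx = sum(idx[, 2] * w) / sum(w),
               cy = sum(idx[, 1] * w) / sum(w), area = nrow(idx))
  })
  out <- do.call(rbind, rows) %||%
    data.frame(id = integer(0), cx = numeric(0), cy = numeric(0),
               area = integer(0))
  structure(out, labels = labels, background = bg$center)
}

#' Measure particle apparent widths (FWHM) and their population Gaussian
#'
#' Per particle, the FWHM is the distance between the outermost
#' half-maximum crossings of the background-subtracted height profile
#' through the particle centroid, averaged over the two orthogonal image
#' axes and converted to nm. The per-particle widths are then summarised by
#' a single-Gaussian fit (normal maximum likelihood), matching the usual
#' presentation of AFM width histograms. The profile itself is never fitted
#' with a Gaussian — a ring profile is not Gaussian.
#'
#' @param x a numeric matrix, a (rows, cols, frames) array, or a
#'   `ring_movie` object.
#' @param pixel_size pixel size in nm (taken from the object if available).
#' @param frame frame index used when `x` has multiple frames.
#' @param threshold_sd,min_area_px detection settings, see
#'   [detect_particles()].
#' @return An object of class `fwhm_result`: `per_particle_fwhm` (nm),
#'   `fit_mean`, `fit_sd`, `n`, `se_mean`.
#' @export
measure_fwhm <- function(x, pixel_size = NULL, frame = 1L,
                         threshold_sd = 5, min_area_px = 25) {
  if (inherits(x, "ring_movie")) {
    pixel_size <- x$pixel_size
    img <- x$movie[, , frame]
  } else if (is.array(x) && length(dim(x)) == 3) {
    img <- x[, , frame]
  } else {
    img <- as.matrix(x)
  }
  stop_if(is.null(pixel_size), "pixel_size required")
  parts <- detect_particles(img, threshold_sd, min_area_px)
  bg <- attr(parts, "background")
  labels <- attr(parts, "labels")
  widths <- vapply(seq_len(nrow(parts)), function(i) {
    k <- parts$id[i]
    idx <- which(labels == k, arr.ind = TRUE)
    # profile window: component bounding box expanded by half its extent
    ry <- range(idx[, 1]); rx <- range(idx[, 2])
    ey <- ceiling(diff(ry) / 2); ex <- ceiling(diff(rx) / 2)
    ry <- c(max(1, ry[1] - ey), min(nrow(img), ry[2] + ey))
    rx <- c(max(1, rx[1] - ex), min(ncol(img), rx[2] + ex))
    cy <- parts$cy[i]; cx <- parts$cx[i]
    # profiles through the exact centroid (bilinear between adjacent rows/cols)
    wy0 <- cy - floor(cy); iy <- floor(cy)
    prof_x <- (1 - wy0) * img[iy, rx[1]:rx[2]] +
      wy0 * img[min(iy + 1L, nrow(img)), rx[1]:rx[2]] - bg
    wx0 <- cx - floor(cx); ix <- floor(cx)
    prof_y <- (1 - wx0) * img[ry[1]:ry[2], ix] +
      wx0 * img[ry[1]:ry[2], min(ix + 1L, ncol(img))] - bg
    # fold the four half-profiles about the centroid into one radial
    # profile: the orientation average of the two orthogonal directions
    d_x <- (rx[1]:rx[2]) - cx
    d_y <- (ry[1]:ry[2]) - cy
    dmax <- max(abs(c(d_x, d_y)))
    grid <- seq(0, dmax, by = 0.5)
    halves <- list(list(d = -d_x[d_x <= 0], y = prof_x[d_x <= 0]),
                   list(d = d_x[d_x >= 0], y = prof_x[d_x >= 0]),
                   list(d = -d_y[d_y <= 0], y = prof_y[d_y <= 0]),
                   list(d = d_y[d_y >= 0], y = prof_y[d_y >= 0]))
    acc <- matrix(NA_real_, length(halves), length(grid))
    for (h in seq_along(halves)) {
      hh <- halves[[h]]
      if (length(hh$d) < 2) next
      o <- order(hh$d)
      acc[h, ] <- stats::approx(hh$d[o], hh$y[o], xout = grid, rule = 1)$y
    }
    radial <- colMeans(acc, na.rm = TRUE)
    ok <- is.finite(radial)
    # FWHM = twice the outermost half-maximum crossing distance
    level <- max(radial[ok]) / 2
    above <- which(ok & radial >= level)
    if (length(above) == 0) return(NA_real_)
    i2 <- above[length(above)]
    r_cross <- if (i2 == length(grid) || !ok[i2 + 1L]) grid[i2] else
      grid[i2] + (radial[i2] - level) / (radial[i2] - radial[i2 + 1L]) *
        (grid[i2 + 1L] - grid[i2])
    2 * r_cross * pixel_size
  }, numeric(1))
  widths <- widths[is.finite(widths)]
  n <- length(widths)
  structure(list(per_particle_fwhm = widths,
                 fit_mean = if (n) mean(widths) else NA_real_,
                 fit_sd = if (n > 1) stats::sd(widths) else NA_real_,
                 se_mean = if (n > 1) stats::sd(widths) / sqrt(n) else NA_real_,
                 n = n),
            class = "fwhm_result")
}

#' @export
plot.fwhm_result <- function(x, breaks = 15, ...) {
  h <- graphics::hist(x$per_particle_fwhm, breaks = breaks, freq = FALSE,
            xlab = "FWHM (nm)", main = sprintf(
              "Apparent width: %.1f +/- %.1f nm (n = %d)",
              x$fit_mean, x$fit_sd, x$n), ...)
  grid <- seq(min(h$breaks), max(h$breaks), length.out = 200)
  graphics::lines(grid, stats::dnorm(grid, x$fit_mean, x$fit_sd), col = "red3")
  invisible(x)
}

#' @export
print.fwhm_result <- function(x, ...) {
  cat(sprintf("FWHM of %d particle(s): Gaussian fit mean %.2f nm, sd %.2f nm\n",
              x$n, x$fit_mean, x$fit_sd))
  invisible(x)
}

# -- ring-state classification ----------------------------------------------

#' Classify per-frame ring states into angular sectors
#'
#' Heights around the tracked particle centre are summarised in
#' `n_sectors` angular sectors of an annulus centred on the ring's radial
#' peak; a sector is called "open" when its robust peak height falls below
#' `open_threshold` times the median of the sector heights — a relative
#' criterion, invariant to global height scaling. The sector frame of
#' reference (lobe phase) is either supplied, estimated once from the mean
#' frame ("static"), or tracked frame-to-frame by maximising the six-fold
#' angular component within +/- 30 degrees of the previous frame ("track").
#'
#' @param x a (rows, cols, frames) array containing one tracked particle,
#'   or a `ring_movie` (then every molecule is classified and a list of
#'   series is returned).
#' @param frame_rate frames per second (taken from a `ring_movie`).
#' @param n_sectors number of angular sectors (6 for a hexamer).
#' @param open_threshold open-call threshold relative to the median sector
#'   height.
#' @param register `"static"`, `"track"`, or `"none"`.
#' @param phase optional known lobe phase (radians) overriding registration.
#' @param detection_floor frames whose maximum height falls below this are
#'   marked missing; default `0.25 *` the median per-frame maximum.
#' @return A [ring_state_series()] (or list of them for a `ring_movie`).
#' @export
classify_ring_states <- function(x, frame_rate = NULL, n_sectors = 6L,
                                 open_threshold = 0.5,
                                 register = c("static", "track", "none"),
                                 phase = NULL, detection_floor = NULL) {
  register <- match.arg(register)
  if (inherits(x, "ring_movie")) {
    pp <- x$patch_px
    out <- lapply(seq_len(nrow(x$molecules)), function(m) {
      r0 <- x$molecules$row0[m]; c0 <- x$molecules$col0[m]
      classify_ring_states(x$movie[r0 + seq_len(pp), c0 + seq_len(pp), ,
                                   drop = FALSE],
                           frame_rate = x$frame_rate, n_sectors = n_sectors,
                           open_threshold = open_threshold,
                           register = register, phase = phase,
                           detection_floor = detection_floor)
    })
    return(out)
  }
  stopifnot(is.array(x), length(dim(x)) == 3)
  stop_if(is.null(frame_rate), "frame_rate required")
  nf <- dim(x)[3]
  mean_frame <- apply(x, c(1, 2), mean)
  bg <- robust_background(mean_frame)$center
  mf <- pmax(mean_frame - bg, 0)
  wsum <- sum(mf)
  stop_if(wsum <= 0, "no particle signal in movie")
  cy <- sum(row(mf) * mf) / wsum
  cx <- sum(col(mf) * mf) / wsum
  d <- sqrt((row(mf) - cy)^2 + (col(mf) - cx)^2)
  theta <- atan2(row(mf) - cy, col(mf) - cx)
  # ring radius from the radial profile of the mean frame
  rb <- floor(d) + 1L
  prof <- tapply(mf, rb, mean)
  r_peak <- as.numeric(names(prof))[which.max(prof)] - 0.5
  annulus <- d >= 0.5 * r_peak & d <= 1.5 * r_peak

  phase_of <- function(img) {
    v <- pmax(img - bg, 0)[annulus]
    Arg(sum(v * exp(1i * 6 * theta[annulus]))) / 6
  }
  phases <- rep(if (is.null(phase)) phase_of(mean_frame) else phase, nf)
  if (is.null(phase) && register == "track") {
    for (f in seq_len(nf)) {
      raw <- phase_of(x[, , f])
      prev <- if (f == 1L) phases[1] else phases[f - 1L]
      # choose the 60-degree alias nearest the previous frame's phase
      k <- round((prev - raw) / (pi / 3))
      cand <- raw + k * pi / 3
      if (abs(cand - prev) <= pi / 6) phases[f] <- cand else phases[f] <- prev
    }
  }

  sector_angles <- function(ph) (round((theta - ph) / (pi / 3)) %% n_sectors) + 1
  floor_med <- stats::median(apply(x, 3, max))
  detection_floor <- detection_floor %||% (0.25 * floor_med)

  open_sets <- vector("list", nf)
  for (f in seq_len(nf)) {
    img <- x[, , f]
    if (max(img) < detection_floor) { open_sets[[f]] <- NA_integer_; next }
    sec <- sector_angles(phases[f])
    h <- vapply(seq_len(n_sectors), function(s) {
      v <- img[annulus & sec == s] - bg
      if (length(v) == 0) return(NA_real_)
      stats::quantile(v, 0.9, names = FALSE)
    }, numeric(1))
    med <- stats::median(h, na.rm = TRUE)
    open_sets[[f]] <- which(h < open_threshold * med)
  }
  ring_state_series(open_sets, frame_rate,
                    registration = phases * 180 / pi)
}

# -- dwell-time rate estimation ---------------------------------------------

#' Extract complete (uncensored) dwell lengths from a state series
#' @noRd
extract_dwells <- function(series) {
  obs <- vapply(series$open, function(s) !anyNA(s), TRUE)
  opn <- vapply(series$open, function(s) length(s) > 0 && !anyNA(s), TRUE)
  segs <- split(seq_len(series$n_frames), cumsum(!obs))
  closed <- integer(0); open <- integer(0); censored <- 0L
  for (seg in segs) {
    seg <- seg[obs[seg]]
    if (length(seg) < 3L) next
    r <- rle(opn[seg])
    k <- length(r$lengths)
    censored <- censored + min(k, 2L)
    if (k <= 2L) next
    keep <- 2:(k - 1)  # boundary-truncated dwells are censored
    closed <- c(closed, r$lengths[keep][!r$values[keep]])
    open <- c(open, r$lengths[keep][r$values[keep]])
  }
  list(closed = closed, open = open, censored = censored)
}

#' Estimate opening and closing rates from ring-state series
#'
#' Dwell times are extracted in frames, with boundary-truncated dwells (and
#' dwells abutting missing frames) censored. Three estimators of the
#' underlying continuous-time rates are exposed:
#' \describe{
#'   \item{`"ctmc"` (default)}{exact inversion of the frame-sampled
#'     two-state chain: with per-frame leave probabilities `q_c`, `q_o`
#'     estimated as 1/mean dwell, the chain eigenvalue
#'     `lambda = 1 - q_c - q_o` equals `exp(-(k_open + k_close) / f)`, so
#'     `k_open + k_close = -f log(lambda)` split by the stationary odds
#'     `q_c : q_o`. Consistent even when transitions complete within a
#'     single frame interval.}
#'   \item{`"geometric"`}{per-state discrete correction
#'     `k = -f log(1 - 1/mean_dwell_frames)`; ignores within-frame round
#'     trips, biased low when rates approach the frame rate.}
#'   \item{`"naive"`}{`k = 1 / mean_dwell_seconds`.}
#' }
#' Confidence intervals are percentile bootstrap over the dwell lists.
#'
#' @param series a [ring_state_series()] or a list of them.
#' @param estimator which estimator to report.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @return An object of class `rate_estimate`: `k_open`, `k_close` (1/s),
#'   `ci_open`, `ci_close`, event counts, `censored_count`, `estimator`.
#' @export
estimate_rates <- function(series, estimator = c("ctmc", "geometric", "naive"),
                           n_boot = 200L, conf = 0.95) {
  estimator <- match.arg(estimator)
  if (inherits(series, "ring_state_series")) series <- list(series)
  frame_rate <- series[[1]]$frame_rate
  dw <- lapply(series, extract_dwells)
  closed <- unlist(lapply(dw, `[[`, "closed"))
  open <- unlist(lapply(dw, `[[`, "open"))
  censored <- sum(vapply(dw, `[[`, integer(1), "censored"))
  stop_if(length(closed) == 0, "no complete dwells in state 'closed'")
  stop_if(length(open) == 0, "no complete dwells in state 'open'")

  rates_from <- function(mean_c, mean_o) {
    q_c <- min(1 / mean_c, 1 - 1e-9)
    q_o <- min(1 / mean_o, 1 - 1e-9)
    if (estimator == "naive")
      return(c(frame_rate / mean_c, frame_rate / mean_o))
    if (estimator == "geometric")
      return(c(-frame_rate * log(1 - q_c), -frame_rate * log(1 - q_o)))
    lam <- 1 - q_c - q_o
    if (lam <= 0)  # sampled faster than resolvable; geometric fallback
      return(c(-frame_rate * log(1 - q_c), -frame_rate * log(1 - q_o)))
    k_sum <- -frame_rate * log(lam)
    c(k_sum * q_c / (q_c + q_o), k_sum * q_o / (q_c + q_o))
  }
  est <- rates_from(mean(closed), mean(open))
  boot <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    boot[b, ] <- rates_from(
      mean(sample(closed, replace = TRUE)),
      mean(sample(open, replace = TRUE)))
  }
  alpha <- (1 - conf) / 2
  structure(list(k_open = est[1], k_close = est[2],
                 ci_open = stats::quantile(boot[, 1], c(alpha, 1 - alpha),
                                           names = FALSE),
                 ci_close = stats::quantile(boot[, 2], c(alpha, 1 - alpha),
                                            names = FALSE),
                 n_events_open = length(closed),  # closed dwell ends in opening
                 n_events_close = length(open),
                 censored_count = censored, estimator = estimator,
                 frame_rate = frame_rate, conf = conf,
                 dwell_frames = list(closed = closed, open = open)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Dwell-time rates (%s estimator, %d/%d events, %d censored)\n",
              x$estimator, x$n_events_open, x$n_events_close,
              x$censored_count))
  cat(sprintf("  k_open  %.3f /s  [%.3f, %.3f] %d%% CI\n", x$k_open,
              x$ci_open[1], x$ci_open[2], round(100 * x$conf)))
  cat(sprintf("  k_close %.3f /s  [%.3f, %.3f] %d%% CI\n", x$k_close,
              x$ci_close[1], x$ci_close[2], round(100 * x$conf)))
  invisible(x)
}

#' @export
coef.rate_estimate <- function(object, ...) {
  c(k_open = object$k_open, k_close = object$k_close)
}

# -- randomness of subunit activation ---------------------------------------

#' Opening events (newly opened subunits, time-ordered) of a series
#' @noRd
opening_events <- function(series) {
  ev <- integer(0)
  prev <- integer(0)
  for (f in seq_len(series$n_frames)) {
    s <- series$open[[f]]
    if (anyNA(s)) { prev <- integer(0); next }
    ev <- c(ev, setdiff(s, prev))
    prev <- s
  }
  ev
}

#' Tests of random (orderless) subunit activation
#'
#' Two chi-square goodness-of-fit tests on the opening events pooled over
#' series: (a) uniformity of the opened-subunit identity over the six
#' subunits; (b) a step test on consecutive openings within each series,
#' `delta = (s[t+1] - s[t]) mod 6`, against uniformity over {0..5} — a
#' sequential (rotary) mechanism concentrates mass on a single step. When
#' expected cell counts fall below `min_expected`, an exact multinomial
#' test is substituted and flagged in the report.
#'
#' @param series a [ring_state_series()] or list of them.
#' @param min_expected minimum expected count per cell for the chi-square
#'   approximation.
#' @return An object of class `randomness_report` with components
#'   `uniformity` and `step`, each `list(counts, p, method)`.
#' @export
randomness_tests <- function(series, min_expected = 6) {
  if (inherits(series, "ring_state_series")) series <- list(series)
  evs <- lapply(series, opening_events)
  all_ev <- unlist(evs)
  stop_if(length(all_ev) == 0, "no opening events")
  gof <- function(counts) {
    n <- sum(counts)
    if (n / length(counts) < min_expected) {
      list(counts = counts, p = exact_multinomial_p(counts),
           method = "exact multinomial")
    } else {
      list(counts = counts,
           p = stats::chisq.test(counts, p = rep(1 / length(counts),
                                                 length(counts)))$p.value,
           method = "chi-square")
    }
  }
  uni <- gof(tabulate(all_ev, nbins = 6L))
  steps <- unlist(lapply(evs, function(e) {
    if (length(e) < 2) integer(0) else (diff(e) %% 6L)
  }))
  stp <- if (length(steps) == 0) {
    list(counts = tabulate(integer(0), 6L), p = NA_real_,
         method = "insufficient events")
  } else {
    gof(tabulate(steps + 1L, nbins = 6L))
  }
  structure(list(uniformity = uni, step = stp,
                 n_events = length(all_ev)),
            class = "randomness_report")
}

#' @export
print.randomness_report <- function(x, ...) {
  cat(sprintf("Subunit-activation randomness (%d opening events)\n", x$n_events))
  cat(sprintf("  subunit uniformity: p = %.4g (%s), counts %s\n",
              x$uniformity$p, x$uniformity$method,
              paste(x$uniformity$counts, collapse = " ")))
  cat(sprintf("  step distribution:  p = %.4g (%s), counts %s\n",
              x$step$p, x$step$method, paste(x$step$counts, collapse = " ")))
  invisible(x)
}
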