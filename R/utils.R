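# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

#' Check a scalar numeric argument
#' @noRd
check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         lo = -Inf, hi = Inf) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          "'%s' must be a finite numeric scalar", name)
  if (positive) stop_if(x <= 0, "'%s' must be > 0 (got %g)", name, x)
  if (nonneg) stop_if(x < 0, "'%s' must be >= 0 (got %g)", name, x)
  stop_if(x < lo || x > hi, "'%s' must be in [%g, %g] (got %g)", name, lo, hi, x)
  invisible(x)
}

#' van der Waals radii (nm) by element, for sphere models and pore profiles
#' @noRd
vdw_radius_nm <- function(elements) {
  tab <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
           P = 0.180, FE = 0.194, ZN = 0.139, MG = 0.173)
  r <- tab[toupper(elements)]
  r[is.na(r)] <- 0.170  # unknown elements treated as carbon-like
  unname(r)
}

# FWHM of a unit-sd Gaussian
FWHM_SIGMA <- 2 * sqrt(2 * log(2))

#' Linear-interpolated outermost half-maximum crossings of a 1-D profile
#'
#' Returns the distance (in sample units) between the outermost crossings of
#' level = half the profile maximum, or NA when the profile never rises above
#' the level at an interior point.
#' @noRd
half_max_width <- function(y, x = seq_along(y)) {
  if (all(!is.finite(y)) || max(y, na.rm = TRUE) <= 0) return(NA_real_)
  level <- max(y, na.rm = TRUE) / 2
  above <- which(y >= level)
  if (length(above) == 0L) return(NA_real_)
  i1 <- above[1L]; i2 <- above[length(above)]
  # interpolate the left crossing
  xl <- if (i1 == 1L) x[1L] else {
    x[i1 - 1L] + (level - y[i1 - 1L]) / (y[i1] - y[i1 - 1L]) * (x[i1] - x[i1 - 1L])
  }
  xr <- if (i2 == length(y)) x[length(y)] else {
    x[i2] + (y[i2] - level) / (y[i2] - y[i2 + 1L]) * (x[i2 + 1L] - x[i2])
  }
  xr - xl
}

#' Robust background statistics of an image (median and MAD)
#' @noRd
robust_background <- function(img) {
  v <- as.numeric(img)
  list(center = stats::median(v), spread = stats::mad(v))
}

#' Exact multinomial goodness-of-fit p-value against given cell probabilities
#'
#' Enumerates all compositions of n into k cells and sums the probability of
#' outcomes no more probable than the observed one. Intended for small n
#' where the chi-square approximation is unreliable.
#' @noRd
exact_multinomial_p <- function(counts, prob = rep(1 / length(counts), length(counts))) {
  n <- sum(counts)
  k <- length(counts)
  p_obs <- stats::dmultinom(counts, prob = prob)
  tol <- 1e-12
  total <- 0
  cfg <- integer(k)
  recurse <- function(cell, left) {
    if (cell == k) {
      cfg[k] <<- left
      p <- stats::dmultinom(cfg, prob = prob)
      if (p <= p_obs * (1 + tol)) total <<- total + p
      return(invisible())
    }
    for (c_i in 0:left) {
      cfg[cell] <<- c_i
      recurse(cell + 1L, left - c_i)
    }
  }
  recurse(1L, n)
  min(1, total)
}
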