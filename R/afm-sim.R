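# Pseudo-AFM image simulation: exact hard-contact dilation of a sphere
# model by a sphere-capped conical tip, plus the spatial low-pass filter
# applied to both simulated and instrument images.
#
# For a probe with apex radius R and half-cone angle alpha scanning a
# sphere of radius a centred at (x0, y0, z0), the apex height at first
# contact has two analytic regimes in the lateral offset d:
#   spherical cap (d <= (R + a) cos alpha):
#       h = z0 + sqrt((R + a)^2 - d^2) - R
#   conical flank (d >  (R + a) cos alpha):
#       h = z0 + (a - (d - R cos alpha) cos alpha) / sin alpha
#              - R (1 - sin alpha)
# which meet continuously at the tangency offset. The image of a union of
# spheres is the pointwise maximum (dilation distributes over union).

#' Sphere-capped conical tip model
#'
#' @param apex_radius tip apex radius (nm).
#' @param half_cone_angle cone half-angle (degrees), in (0, 90).
#' @return An object of class `tip_model`.
#' @export
tip_model <- function(apex_radius = 0.5, half_cone_angle = 10) {
  check_scalar(apex_radius, "apex_radius", positive = TRUE)
  check_scalar(half_cone_angle, "half_cone_angle")
  stop_if(half_cone_angle <= 0 || half_cone_angle >= 90,
          "'half_cone_angle' must be in (0, 90) degrees")
  structure(list(apex_radius = apex_radius,
                 half_cone_angle = half_cone_angle),
            class = "tip_model")
}

#' A 2-D grid of surface heights
#'
#' @param heights numeric matrix (rows = y, cols = x), nm.
#' @param pixel_size lateral pixel size (nm).
#' @param origin (x, y) of the first pixel centre (nm).
#' @param meta optional metadata list (tip, filter, provenance).
#' @return An object of class `height_map`.
#' @export
height_map <- function(heights, pixel_size, origin = c(0, 0), meta = list()) {
  stop_if(!is.matrix(heights) || !all(is.finite(heights)),
          "heights must be a finite numeric matrix")
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  structure(list(heights = heights, pixel_size = pixel_size,
                 origin = origin, meta = meta), class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("Height map %d x %d px @ %.3g nm/px, range [%.3g, %.3g] nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Build a sphere model from an atomic structure
#'
#' Converts a coordinate model (Angstrom) to a set of hard spheres (nm) for
#' pseudo-AFM simulation: the chosen face is rotated to point up (+z), the
#' model is translated so its lowest sphere touches the substrate plane
#' z = 0 and its footprint is centred laterally on the origin.
#'
#' @param structure a [structure_model()].
#' @param orientation `"top"` (identity), `"bottom"` (180-degree rotation
#'   about x, so the former underside faces the probe), or a 3x3 rotation
#'   matrix applied to the coordinates.
#' @param radius_scheme `"element"` (per-element van der Waals table) or
#'   `"uniform"`.
#' @param uniform_radius sphere radius (nm) for `radius_scheme = "uniform"`.
#' @param calpha_only use one sphere per residue at the C-alpha position
#'   (coarse-grained; pair with a larger uniform radius).
#' @return An object of class `sphere_model` with `centers` (n x 3, nm),
#'   `radii` (nm) and `provenance`.
#' @export
build_sphere_model <- function(structure, orientation = "top",
                               radius_scheme = c("element", "uniform"),
                               uniform_radius = 0.25, calpha_only = FALSE) {
  stopifnot(inherits(structure, "structure_model"))
  radius_scheme <- match.arg(radius_scheme)
  a <- structure$atoms
  if (calpha_only) a <- a[a$elety == "CA", , drop = FALSE]
  stop_if(nrow(a) == 0, "structure has no atoms after selection")
  xyz <- as.matrix(a[, c("x", "y", "z")]) / 10  # Angstrom -> nm
  rot <- if (is.matrix(orientation)) {
    orientation
  } else if (identical(orientation, "top")) {
    diag(3)
  } else if (identical(orientation, "bottom")) {
    diag(c(1, -1, -1))  # 180 degrees about x
  } else stop_if(TRUE, "orientation must be \"top\", \"bottom\" or a 3x3 matrix")
  xyz <- xyz %*% t(rot)
  radii <- if (radius_scheme == "element") vdw_radius_nm(a$elesy)
           else rep(uniform_radius, nrow(a))
  xyz[, 1] <- xyz[, 1] - mean(range(xyz[, 1]))
  xyz[, 2] <- xyz[, 2] - mean(range(xyz[, 2]))
  xyz[, 3] <- xyz[, 3] - min(xyz[, 3] - radii)  # lowest sphere touches z = 0
  structure(list(centers = xyz, radii = radii,
                 provenance = list(source = structure$source,
                                   orientation = if (is.matrix(orientation))
                                     "matrix" else orientation,
                                   radius_scheme = radius_scheme,
                                   uniform_radius = if (radius_scheme ==
                                     "uniform") uniform_radius else NA,
                                   calpha_only = calpha_only)),
            class = "sphere_model")
}

#' Construct a sphere model directly from centres and radii
#' @param centers n x 3 matrix (nm).
#' @param radii length-n radii (nm).
#' @param provenance free-form list.
#' @return An object of class `sphere_model`.
#' @export
sphere_model <- function(centers, radii, provenance = list()) {
  centers <- rbind(centers)
  stop_if(ncol(centers) != 3, "centers must be n x 3")
  radii <- rep_len(radii, nrow(centers))
  stop_if(any(radii <= 0), "sphere radii must be > 0")
  structure(list(centers = centers, radii = radii, provenance = provenance),
            class = "sphere_model")
}

#' Tip-contact height for one sphere at lateral offsets d (closed form)
#' @noRd
tip_contact_height <- function(d, z0, a, R, alpha_rad) {
  ca <- cos(alpha_rad); sa <- sin(alpha_rad)
  d_tan <- (R + a) * ca
  h <- numeric(length(d))
  cap <- d <= d_tan
  h[cap] <- z0 + sqrt(pmax((R + a)^2 - d[cap]^2, 0)) - R
  h[!cap] <- z0 + (a - (d[!cap] - R * ca) * ca) / sa - R * (1 - sa)
  h
}

#' Simulate a pseudo-AFM height map by exact tip dilation
#'
#' At each grid point the recorded height is the lowest apex position at
#' which the sphere-capped conical tip first contacts any sphere of the
#' model, clipped at the substrate plane; both contact regimes use their
#' closed forms.
#'
#' @param model a [sphere_model()] (or [build_sphere_model()] output).
#' @param tip a [tip_model()].
#' @param pixel_size grid spacing (nm); default 0.2 nm, finer than typical
#'   experimental sampling so grid bias is negligible in width statistics.
#' @param bounds optional `list(xlim =, ylim =)` (nm); default covers the
#'   model footprint plus the full tip reach.
#' @return A [height_map()], with tip and model provenance in `meta`.
#' @export
simulate_height_map <- function(model, tip = tip_model(), pixel_size = 0.2,
                                bounds = NULL) {
  stopifnot(inherits(model, "sphere_model"), inherits(tip, "tip_model"))
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  R <- tip$apex_radius
  alpha <- tip$half_cone_angle * pi / 180
  ctr <- model$centers; rad <- model$radii
  if (is.null(bounds)) {
    # lateral reach where the flank contact height falls to zero
    reach <- R * cos(alpha) +
      (rad + (ctr[, 3] - R * (1 - sin(alpha))) * sin(alpha)) / cos(alpha)
    reach <- pmax(reach, rad + R)
    bounds <- list(xlim = range(ctr[, 1] - reach, ctr[, 1] + reach),
                   ylim = range(ctr[, 2] - reach, ctr[, 2] + reach))
  }
  xs <- seq(bounds$xlim[1], bounds$xlim[2], by = pixel_size)
  ys <- seq(bounds$ylim[1], bounds$ylim[2], by = pixel_size)
  H <- matrix(0, length(ys), length(xs))
  for (i in seq_len(nrow(ctr))) {
    dx <- xs - ctr[i, 1]; dy <- ys - ctr[i, 2]
    d <- sqrt(outer(dy^2, dx^2, `+`))
    H <- pmax(H, tip_contact_height(d, ctr[i, 3], rad[i], R, alpha))
  }
  height_map(H, pixel_size, origin = c(xs[1], ys[1]),
             meta = list(tip = tip, provenance = model$provenance))
}

#' Spatial low-pass filter of a height map
#'
#' Gaussian transfer function in the frequency domain with its half-power
#' point at spatial frequency `1 / cutoff_wavelength`: the amplitude at the
#' cutoff is attenuated by exactly `1/sqrt(2)` and the DC gain is exactly 1.
#'
#' @param image a [height_map()], or a numeric matrix (then `pixel_size`
#'   must be given).
#' @param cutoff_wavelength cutoff wavelength (nm), default 2.0.
#' @param pixel_size pixel size (nm) when `image` is a bare matrix.
#' @return A [height_map()] with the filter recorded in `meta$lowpass`.
#' @export
lowpass_filter <- function(image, cutoff_wavelength = 2.0, pixel_size = NULL) {
  if (inherits(image, "height_map")) {
    hm <- image
  } else {
    stop_if(is.null(pixel_size), "pixel_size required for a bare matrix")
    hm <- height_map(image, pixel_size)
  }
  check_scalar(cutoff_wavelength, "cutoff_wavelength", positive = TRUE)
  if (cutoff_wavelength < 2 * hm$pixel_size)
    warning(sprintf(paste0("cutoff wavelength %.3g nm is below the Nyquist ",
                           "wavelength %.3g nm; the filter is ineffective"),
                    cutoff_wavelength, 2 * hm$pixel_size))
  z <- hm$heights
  ny <- nrow(z); nx <- ncol(z)
  fftfreq <- function(n, d) {
    k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
    k / (n * d)
  }
  fy <- fftfreq(ny, hm$pixel_size)
  fx <- fftfreq(nx, hm$pixel_size)
  f2 <- outer(fy^2, fx^2, `+`)
  fc <- 1 / cutoff_wavelength
  Hf <- exp(-(log(2) / 2) * f2 / fc^2)  # |H(fc)| = 2^(-1/2)
  zf <- stats::fft(z)
  out <- Re(stats::fft(zf * Hf, inverse = TRUE)) / (nx * ny)
  hm$heights <- out
  hm$meta$lowpass <- list(kind = "gaussian",
                          cutoff_wavelength = cutoff_wavelength,
                          convention = "half-power amplitude 1/sqrt(2) at 1/cutoff")
  hm
}
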