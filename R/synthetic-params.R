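# Parameter constructors for the synthetic-data generators. Each constructor
# validates its arguments once so the generators can assume a well-formed
# object, and each carries the seed so that a generator is a pure function of
# its parameter object.

#' Parameters for synthetic hexamer-ring HS-AFM movies
#'
#' Defines a field of hexameric ring particles whose subunits stochastically
#' open (height drop) and close as a continuous-time Markov process, imaged
#' at a fixed frame rate with additive Gaussian height noise.
#'
#' @param k_open closed-to-open transition rate per molecule (1/s).
#' @param k_close open-to-closed rate (1/s).
#' @param frame_rate imaging rate (Hz).
#' @param n_frames number of frames.
#' @param n_molecules number of ring particles in the field of view.
#' @param ring_outer_fwhm ground-truth apparent width of a closed ring:
#'   distance between the outermost half-maximum crossings of the height
#'   profile through the particle centre (nm).
#' @param ring_fwhm_sd per-molecule standard deviation of the apparent
#'   width (nm); 0 gives identical rings.
#' @param lobe_height peak lobe height above the substrate (nm).
#' @param open_drop_fraction fractional height reduction of an open lobe,
#'   in (0, 1].
#' @param pixel_size lateral pixel size (nm).
#' @param noise_sd additive Gaussian height noise per pixel (nm).
#' @param allow_double_open if TRUE a second subunit may open while one is
#'   already open (rare double-opening branch).
#' @param radial_sigma radial Gaussian width of the ring annulus (nm).
#' @param lobe_contrast depth of the six-fold angular modulation in (0, 1).
#' @param seed integer seed; identical parameters imply identical output.
#' @return An object of class `ring_dynamics_params`.
#' @export
ring_dynamics_params <- function(k_open = 1.5, k_close = 0.99,
                                 frame_rate = 5, n_frames = 100,
                                 n_molecules = 1,
                                 ring_outer_fwhm = 19.8, ring_fwhm_sd = 0,
                                 lobe_height = 4, open_drop_fraction = 0.8,
                                 pixel_size = 1, noise_sd = 0.2,
                                 allow_double_open = FALSE,
                                 radial_sigma = 2.5, lobe_contrast = 0.35,
                                 seed = 1L) {
  check_scalar(k_open, "k_open", nonneg = TRUE)
  check_scalar(k_close, "k_close", nonneg = TRUE)
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  check_scalar(n_frames, "n_frames", positive = TRUE)
  check_scalar(n_molecules, "n_molecules", positive = TRUE)
  check_scalar(ring_outer_fwhm, "ring_outer_fwhm", positive = TRUE)
  check_scalar(ring_fwhm_sd, "ring_fwhm_sd", nonneg = TRUE)
  check_scalar(lobe_height, "lobe_height", positive = TRUE)
  check_scalar(open_drop_fraction, "open_drop_fraction")
  stop_if(open_drop_fraction <= 0 || open_drop_fraction > 1,
          "'open_drop_fraction' must be in (0, 1]")
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(radial_sigma, "radial_sigma", positive = TRUE)
  check_scalar(lobe_contrast, "lobe_contrast", lo = 0, hi = 0.95)
  structure(list(
    k_open = k_open, k_close = k_close, frame_rate = frame_rate,
    n_frames = as.integer(n_frames), n_molecules = as.integer(n_molecules),
    ring_outer_fwhm = ring_outer_fwhm, ring_fwhm_sd = ring_fwhm_sd,
    lobe_height = lobe_height, open_drop_fraction = open_drop_fraction,
    pixel_size = pixel_size, noise_sd = noise_sd,
    allow_double_open = isTRUE(allow_double_open),
    radial_sigma = radial_sigma, lobe_contrast = lobe_contrast,
    seed = as.integer(seed)
  ), class = "ring_dynamics_params")
}

#' Parameters for synthetic two-channel DNA-curtain movies
#'
#' A field of barrier-anchored DNA molecules imaged in a DNA-stain (green)
#' channel and a labelled-histone (red) channel. DNA columns and DNA-bound
#' spots are visible only while buffer flow extends the DNA; surface-stuck
#' distractor spots persist when flow stops.
#'
#' @param n_dna number of DNA molecules.
#' @param dna_length_bp DNA contour length in bp (default lambda-phage DNA).
#' @param dna_length_px extended DNA length in pixels.
#' @param occupancy_p probability that a DNA carries at least one bound
#'   histone spot, in `[0, 1]`.
#' @param spots_per_dna mean number of spots on an occupied DNA (>= 1);
#'   realised as 1 + Poisson(spots_per_dna - 1).
#' @param position_distribution `"uniform"`, or a numeric vector of fixed
#'   fractional positions in `[0, 1)` used for every occupied DNA.
#' @param n_stuck_distractors number of surface-stuck spots placed uniformly
#'   over the field of view.
#' @param psf_sigma Gaussian point-spread-function sigma (pixels).
#' @param photon_rate expected peak signal photons per frame at a spot centre.
#' @param background expected background photons per pixel per frame.
#' @param read_noise_sd Gaussian read noise (counts).
#' @param flow_schedule logical vector, one element per frame, TRUE = flow on;
#'   or a list of `list(frames = a:b, on = TRUE/FALSE)` blocks.
#' @param n_frames number of frames (used with a block-style flow schedule
#'   or the default schedule).
#' @param dna_spacing_px lateral spacing of DNA columns (pixels).
#' @param barrier_row row index (1-based) of the anchoring barrier.
#' @param seed integer seed.
#' @return An object of class `curtain_scene_params`.
#' @export
curtain_scene_params <- function(n_dna = 50, dna_length_bp = 48502,
                                 dna_length_px = 48, occupancy_p = 0.85,
                                 spots_per_dna = 1.5,
                                 position_distribution = "uniform",
                                 n_stuck_distractors = 5,
                                 psf_sigma = 1.2, photon_rate = 300,
                                 background = 100, read_noise_sd = 2,
                                 flow_schedule = NULL, n_frames = 30,
                                 dna_spacing_px = 5, barrier_row = 8,
                                 seed = 1L) {
  check_scalar(n_dna, "n_dna", positive = TRUE)
  check_scalar(dna_length_bp, "dna_length_bp", positive = TRUE)
  check_scalar(dna_length_px, "dna_length_px", positive = TRUE)
  check_scalar(occupancy_p, "occupancy_p", lo = 0, hi = 1)
  check_scalar(spots_per_dna, "spots_per_dna", lo = 1)
  check_scalar(n_stuck_distractors, "n_stuck_distractors", nonneg = TRUE)
  check_scalar(psf_sigma, "psf_sigma", positive = TRUE)
  check_scalar(photon_rate, "photon_rate", positive = TRUE)
  check_scalar(background, "background", nonneg = TRUE)
  check_scalar(read_noise_sd, "read_noise_sd", nonneg = TRUE)
  check_scalar(n_frames, "n_frames", positive = TRUE)
  n_frames <- as.integer(n_frames)
  if (is.null(flow_schedule)) {
    # default: flow on, then a flow-off validation window, then flow resumed
    n_off <- max(3L, n_frames %/% 4L)
    n_on <- n_frames - n_off
    flow_schedule <- rep(c(TRUE, FALSE), c(n_on, n_off))
  } else if (is.list(flow_schedule)) {
    fs <- rep(NA, n_frames)
    for (blk in flow_schedule) fs[blk$frames] <- isTRUE(blk$on)
    stop_if(anyNA(fs), "flow_schedule does not cover all %d frames", n_frames)
    flow_schedule <- as.logical(fs)
  } else {
    flow_schedule <- as.logical(flow_schedule)
    n_frames <- length(flow_schedule)
  }
  if (is.numeric(position_distribution)) {
    stop_if(any(position_distribution < 0 | position_distribution >= 1),
            "fixed spot positions must lie in [0, 1) along the DNA")
  } else {
    stop_if(!identical(position_distribution, "uniform"),
            "position_distribution must be \"uniform\" or numeric fractions")
  }
  structure(list(
    n_dna = as.integer(n_dna), dna_length_bp = dna_length_bp,
    dna_length_px = as.integer(dna_length_px), occupancy_p = occupancy_p,
    spots_per_dna = spots_per_dna,
    position_distribution = position_distribution,
    n_stuck_distractors = as.integer(n_stuck_distractors),
    psf_sigma = psf_sigma, photon_rate = photon_rate,
    background = background, read_noise_sd = read_noise_sd,
    flow_schedule = flow_schedule, n_frames = length(flow_schedule),
    dna_spacing_px = as.integer(dna_spacing_px),
    barrier_row = as.integer(barrier_row),
    seed = as.integer(seed)
  ), class = "curtain_scene_params")
}

#' Parameters for synthetic fluorescence-anisotropy titrations
#'
#' Single-site binding of a titrant (the chaperone) to a fixed concentration
#' of labelled histone, under the exact ligand-depletion (quadratic) bound
#' fraction — appropriate because the labelled concentration is comparable
#' to the dissociation constant.
#'
#' @param labeled_conc fixed labelled-species concentration (nM).
#' @param titrant_concs titrant concentrations (nM), must include 0.
#' @param kd_true ground-truth dissociation constant (nM).
#' @param r_free anisotropy of the free labelled species.
#' @param r_bound anisotropy of the bound complex; must exceed `r_free`.
#' @param noise_sd additive Gaussian noise per measurement (anisotropy units).
#' @param seed integer seed.
#' @return An object of class `titration_params`.
#' @export
titration_params <- function(labeled_conc = 20,
                             titrant_concs = c(0, 5, 10, 20, 50, 100,
                                               200, 400, 700, 1000),
                             kd_true = 23, r_free = 0.15, r_bound = 0.32,
                             noise_sd = 0.004, seed = 1L) {
  check_scalar(labeled_conc, "labeled_conc", positive = TRUE)
  stop_if(!is.numeric(titrant_concs) || any(titrant_concs < 0),
          "titrant concentrations must be >= 0")
  check_scalar(kd_true, "kd_true", nonneg = TRUE)
  check_scalar(r_free, "r_free")
  check_scalar(r_bound, "r_bound")
  stop_if(r_bound <= r_free, "'r_bound' must exceed 'r_free'")
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(
    labeled_conc = labeled_conc, titrant_concs = as.numeric(titrant_concs),
    kd_true = kd_true, r_free = r_free, r_bound = r_bound,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "titration_params")
}

#' Parameters for synthetic phosphate-release absorbance traces
#'
#' Steady-state ATP hydrolysis monitored as a linear increase of absorbance
#' (coupled phosphate-detection assay), sampled from `t_start` onward at
#' `dt` intervals.
#'
#' @param hexamer_conc hexamer concentration (nM).
#' @param rate_true ground-truth turnover (ATP per hexamer per second).
#' @param calib_slope absorbance per micromolar phosphate.
#' @param t_start first sampling time (s).
#' @param dt sampling interval (s).
#' @param n_points number of time points.
#' @param baseline absorbance at time zero.
#' @param noise_sd additive Gaussian absorbance noise.
#' @param seed integer seed.
#' @return An object of class `atpase_trace_params`.
#' @export
atpase_trace_params <- function(hexamer_conc = 50, rate_true = 0.83,
                                calib_slope = 0.011, t_start = 5, dt = 10,
                                n_points = 30, baseline = 0.2,
                                noise_sd = 0.003, seed = 1L) {
  check_scalar(hexamer_conc, "hexamer_conc", positive = TRUE)
  check_scalar(rate_true, "rate_true", nonneg = TRUE)
  check_scalar(calib_slope, "calib_slope", positive = TRUE)
  check_scalar(t_start, "t_start", nonneg = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(n_points, "n_points", positive = TRUE)
  check_scalar(baseline, "baseline")
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(
    hexamer_conc = hexamer_conc, rate_true = rate_true,
    calib_slope = calib_slope, t_start = t_start, dt = dt,
    n_points = as.integer(n_points), baseline = baseline,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "atpase_trace_params")
}

#' Specification of a toy hexamer coordinate model
#'
#' A ring of `n_subunits` pseudo-atomic lobes at equal angular spacing, with
#' an optional constant rise per subunit (0 = planar ring, > 0 = spiral
#' staircase). Used as a fixture for pseudo-AFM simulation and geometry
#' metrics; not a real protein model.
#'
#' @param n_subunits number of subunits (>= 3).
#' @param ring_radius distance of lobe centroids from the ring axis (nm).
#' @param lobe_radius radius of the atom cloud around each centroid (nm).
#' @param rise_per_subunit axial offset between consecutive subunits (nm).
#' @param atoms_per_lobe atoms per subunit (rounded up to an even count so
#'   lobe centroids are exact by symmetry).
#' @param seed integer seed.
#' @return An object of class `toy_hexamer_spec`.
#' @export
toy_hexamer_spec <- function(n_subunits = 6, ring_radius = 5,
                             lobe_radius = 1.5, rise_per_subunit = 0,
                             atoms_per_lobe = 20, seed = 1L) {
  check_scalar(n_subunits, "n_subunits", lo = 3)
  check_scalar(ring_radius, "ring_radius", positive = TRUE)
  check_scalar(lobe_radius, "lobe_radius", positive = TRUE)
  check_scalar(rise_per_subunit, "rise_per_subunit", nonneg = TRUE)
  check_scalar(atoms_per_lobe, "atoms_per_lobe", positive = TRUE)
  structure(list(
    n_subunits = as.integer(n_subunits), ring_radius = ring_radius,
    lobe_radius = lobe_radius, rise_per_subunit = rise_per_subunit,
    atoms_per_lobe = as.integer(ceiling(atoms_per_lobe / 2) * 2),
    seed = as.integer(seed)
  ), class = "toy_hexamer_spec")
}

#' @export
print.ring_dynamics_params <- function(x, ...) {
  cat("Ring-dynamics movie parameters\n")
  cat(sprintf("  k_open %.3g /s, k_close %.3g /s, %g Hz, %d frames, %d molecule(s)\n",
              x$k_open, x$k_close, x$frame_rate, x$n_frames, x$n_molecules))
  cat(sprintf("  apparent width %.3g +/- %.3g nm, lobe height %.3g nm, pixel %.3g nm\n",
              x$ring_outer_fwhm, x$ring_fwhm_sd, x$lobe_height, x$pixel_size))
  invisible(x)
}
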