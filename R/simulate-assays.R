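# Synthetic ensemble-assay data: anisotropy titrations under the exact
# single-site ligand-depletion model, and linear phosphate-release traces.

#' Exact single-site bound fraction with ligand depletion
#'
#' Fraction of the labelled species bound when `titrant` at concentration L
#' binds labelled species at concentration P with dissociation constant Kd:
#' the physical root of the binding quadratic,
#' bound = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / 2, divided by P.
#' Valid (and necessary) when P is comparable to Kd, where the hyperbolic
#' approximation is biased.
#'
#' @param titrant titrant concentration(s) (same units as `labeled` and `kd`).
#' @param labeled labelled-species concentration.
#' @param kd dissociation constant (>= 0; 0 gives the stoichiometric limit).
#' @return bound fraction(s) in `[0, 1]`.
#' @export
bound_fraction_quadratic <- function(titrant, labeled, kd) {
  stop_if(kd < 0, "Kd must be >= 0")
  check_scalar(labeled, "labeled", positive = TRUE)
  s <- titrant + labeled + kd
  disc <- s^2 - 4 * titrant * labeled
  disc[disc < 0] <- 0  # guard rounding
  bound <- (s - sqrt(disc)) / 2
  pmin(pmax(bound / labeled, 0), 1)
}

#' Simulate a fluorescence-anisotropy titration
#'
#' @param params a [titration_params()] object.
#' @param n_replicates number of independent noisy replicates.
#' @return data.frame with columns `replicate`, `titrant_conc` (nM) and
#'   `anisotropy`, plus attribute `params`.
#' @export
simulate_titration <- function(params, n_replicates = 1L) {
  stopifnot(inherits(params, "titration_params"))
  p <- params
  set.seed(p$seed)
  fb <- bound_fraction_quadratic(p$titrant_concs, p$labeled_conc, p$kd_true)
  r0 <- p$r_free + (p$r_bound - p$r_free) * fb
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(k) {
    data.frame(replicate = k, titrant_conc = p$titrant_concs,
               anisotropy = r0 + if (p$noise_sd > 0)
                 stats::rnorm(length(r0), 0, p$noise_sd) else 0)
  }))
  attr(out, "params") <- p
  out
}

#' Simulate a phosphate-release absorbance trace
#'
#' Absorbance(t) = baseline + calib_slope * [Pi](t) with
#' [Pi](t) = rate_true * hexamer_conc * t (phosphate in uM, concentrations
#' reconciled from nM), sampled at `t_start` and every `dt` thereafter.
#'
#' @param params an [atpase_trace_params()] object.
#' @param n_replicates number of independent noisy replicates.
#' @return data.frame with columns `replicate`, `time_s`, `absorbance_360`,
#'   plus attribute `params`.
#' @export
simulate_atpase_trace <- function(params, n_replicates = 1L) {
  stopifnot(inherits(params, "atpase_trace_params"))
  p <- params
  set.seed(p$seed)
  t <- p$t_start + p$dt * (seq_len(p$n_points) - 1L)
  pi_uM <- p$rate_true * (p$hexamer_conc / 1000) * t  # nM hexamer -> uM Pi
  a0 <- p$baseline + p$calib_slope * pi_uM
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(k) {
    data.frame(replicate = k, time_s = t,
               absorbance_360 = a0 + if (p$noise_sd > 0)
                 stats::rnorm(length(a0), 0, p$noise_sd) else 0)
  }))
  attr(out, "params") <- p
  out
}
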