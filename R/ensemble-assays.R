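# Ensemble assay fitting and crosslink-table filtering: the anisotropy
# binding fit under the exact ligand-depletion model, the steady-state
# ATPase rate from linear phosphate-release traces, and the rule-based
# filter for crosslinking mass-spectrometry search results.

#' Fit an anisotropy titration with the ligand-depletion binding model
#'
#' Nonlinear least squares of
#' `anisotropy = r_free + (r_bound - r_free) * fbound(titrant)`, where
#' `fbound` is the exact single-site quadratic solution
#' ([bound_fraction_quadratic()]). The quadratic model is required, not a
#' refinement, when the labelled concentration is comparable to Kd; the
#' hyperbolic approximation `L / (L + Kd)` is available for the dilute
#' regime and for comparison.
#'
#' @param data data.frame with columns `titrant_conc` (nM) and
#'   `anisotropy` (an optional `replicate` column is carried through).
#' @param labeled_conc fixed labelled-species concentration (nM).
#' @param model `"quadratic"` (ligand depletion, default) or
#'   `"hyperbolic"`.
#' @param n_boot bootstrap replicates for the Kd confidence interval
#'   (case resampling).
#' @param conf confidence level.
#' @return An object of class `binding_fit`: `kd` (nM), `kd_ci`, `r_free`,
#'   `r_bound`, `sse`, `model`, `warning_flag` (degenerate/non-monotone
#'   data), and the underlying `data`.
#' @export
fit_binding <- function(data, labeled_conc = 20,
                        model = c("quadratic", "hyperbolic"),
                        n_boot = 200L, conf = 0.95) {
  model <- match.arg(model)
  stop_if(!all(c("titrant_conc", "anisotropy") %in% names(data)),
          "data must have columns 'titrant_conc' and 'anisotropy'")
  L <- data$titrant_conc; r <- data$anisotropy
  stop_if(length(unique(L)) < 4 || !any(L == 0),
          "need >= 4 distinct titrant concentrations including 0")
  fb_fun <- if (model == "quadratic") {
    function(x, kd) bound_fraction_quadratic(x, labeled_conc, kd)
  } else {
    function(x, kd) x / (x + kd)
  }
  fit_once <- function(L, r) {
    r0 <- mean(r[L == 0]); r1 <- max(r)
    half <- r0 + (r1 - r0) / 2
    kd0 <- max(stats::approx(r, L, xout = half, ties = mean)$y, 1e-3,
               na.rm = TRUE)
    fn <- function(p) r - (p[2] + (p[3] - p[2]) * fb_fun(L, p[1]))
    ft <- minpack.lm::nls.lm(par = c(kd = kd0, r_free = r0, r_bound = r1),
                             fn = fn, lower = c(0, -Inf, -Inf),
                             control = minpack.lm::nls.lm.control(maxiter = 300))
    c(ft$par, sse = sum(ft$fvec^2))
  }
  est <- fit_once(L, r)
  warning_flag <- est["r_bound"] <= est["r_free"] ||
    stats::cor(L, r, method = "spearman") < 0.5
  boot <- rep(NA_real_, max(n_boot, 0))
  n <- length(L)
  for (b in seq_len(max(n_boot, 0))) {
    idx <- sample.int(n, replace = TRUE)
    boot[b] <- tryCatch(fit_once(L[idx], r[idx])["kd"],
                        error = function(e) NA_real_)
  }
  if (all(is.na(boot))) boot <- est["kd"]
  alpha <- (1 - conf) / 2
  structure(list(kd = unname(est["kd"]),
                 kd_ci = stats::quantile(boot, c(alpha, 1 - alpha),
                                         na.rm = TRUE, names = FALSE),
                 r_free = unname(est["r_free"]),
                 r_bound = unname(est["r_bound"]),
                 sse = unname(est["sse"]), model = model,
                 labeled_conc = labeled_conc, conf = conf,
                 warning_flag = warning_flag, data = data),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Binding fit (%s ligand model, labelled %.3g nM)\n",
              x$model, x$labeled_conc))
  cat(sprintf("  Kd = %.3g nM  [%.3g, %.3g] %d%% CI\n", x$kd,
              x$kd_ci[1], x$kd_ci[2], round(100 * x$conf)))
  cat(sprintf("  r_free = %.4f, r_bound = %.4f, SSE = %.3g%s\n",
              x$r_free, x$r_bound, x$sse,
              if (x$warning_flag) "  [WARNING: degenerate or non-monotone data]"
              else ""))
  invisible(x)
}

#' @export
plot.binding_fit <- function(x, ...) {
  d <- x$data
  L <- sort(unique(d$titrant_conc))
  grid <- exp(seq(log(max(min(L[L > 0]) / 3, 1e-3)), log(max(L)),
                  length.out = 120))
  plot(pmax(d$titrant_conc, min(grid)), d$anisotropy, log = "x",
       xlab = "titrant (nM)", ylab = "anisotropy",
       main = sprintf("Kd = %.1f nM (%s model)", x$kd, x$model), ...)
  graphics::lines(grid, predict(x, data.frame(titrant_conc = grid)), col = "red3")
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(kd = object$kd, r_free = object$r_free, r_bound = object$r_bound)
}

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$data$titrant_conc else newdata$titrant_conc
  fb <- if (object$model == "quadratic")
    bound_fraction_quadratic(L, object$labeled_conc, object$kd)
  else L / (L + object$kd)
  object$r_free + (object$r_bound - object$r_free) * fb
}

#' Fit a steady-state ATPase rate from a phosphate-release trace
#'
#' Ordinary least-squares slope of absorbance versus time over the
#' steady-state window, converted to turnover with
#' `rate = slope / (calib_slope * hexamer_conc)` after unit reconciliation
#' (calibration in absorbance per uM phosphate, enzyme in nM; one released
#' phosphate equals one hydrolysed ATP). With a `replicate` column the
#' slope is fitted per replicate and the rate reported as the replicate
#' mean with its standard error.
#'
#' @param data data.frame with columns `time_s`, `absorbance_360` (and
#'   optionally `replicate`).
#' @param hexamer_conc hexamer concentration (nM, > 0).
#' @param calib_slope absorbance per uM phosphate.
#' @param window `c(t_min, t_max)` in seconds selecting the linear
#'   steady-state phase (default all points).
#' @return An object of class `atpase_fit`: `rate` (ATP/hexamer/s), `se`,
#'   `ci`, `slope` (absorbance/s), per-replicate rates.
#' @export
fit_atpase_rate <- function(data, hexamer_conc, calib_slope,
                            window = c(0, Inf)) {
  stop_if(!all(c("time_s", "absorbance_360") %in% names(data)),
          "data must have columns 'time_s' and 'absorbance_360'")
  check_scalar(hexamer_conc, "hexamer_conc", positive = TRUE)
  check_scalar(calib_slope, "calib_slope", positive = TRUE)
  d <- data[data$time_s >= window[1] & data$time_s <= window[2], , drop = FALSE]
  reps <- if (is.null(d$replicate)) list(d) else split(d, d$replicate)
  stop_if(any(vapply(reps, nrow, 1L) < 3),
          "need >= 3 time points in the linear window")
  to_rate <- function(slope) slope * 1000 / (calib_slope * hexamer_conc)
  slopes <- vapply(reps, function(dd)
    unname(stats::coef(stats::lm(absorbance_360 ~ time_s, dd))[2]), numeric(1))
  rates <- to_rate(slopes)
  if (length(rates) > 1) {
    rate <- mean(rates); se <- stats::sd(rates) / sqrt(length(rates))
  } else {
    lm1 <- stats::lm(absorbance_360 ~ time_s, reps[[1]])
    rate <- rates[1]
    se <- if (stats::sigma(lm1) < 1e-12) 0 else
      to_rate(summary(lm1)$coefficients["time_s", "Std. Error"])
  }
  structure(list(rate = unname(rate), se = unname(se),
                 ci = unname(rate + c(-1, 1) * stats::qnorm(0.975) * se),
                 slope = unname(mean(slopes)), replicate_rates = unname(rates),
                 calib_slope = calib_slope, hexamer_conc = hexamer_conc,
                 window = window),
            class = "atpase_fit")
}

#' @export
print.atpase_fit <- function(x, ...) {
  cat(sprintf("ATPase rate: %.3f +/- %.3f ATP/hexamer/s (n = %d replicate(s))\n",
              x$rate, x$se, length(x$replicate_rates)))
  invisible(x)
}

#' @export
coef.atpase_fit <- function(object, ...) c(rate = object$rate)

# -- crosslink filtering ----------------------------------------------------

#' Default crosslink filter criteria
#'
#' Boundary semantics follow the printed criteria literally: strict
#' less-than on mass error (absolute value) and on delta score; inclusive
#' greater-or-equal on peptide length, percent TIC, bond cleavages and LD
#' score. The delta-score direction is unusual for some search-engine
#' conventions and can be switched.
#'
#' @param max_mass_error_ppm strict upper bound on |mass error| (ppm).
#' @param min_peptide_length inclusive minimum peptide length (residues).
#' @param delta_score_cut delta-score cutoff.
#' @param delta_direction `"less"` retains records with
#'   `delta_score < delta_score_cut`; `"greater"` inverts the criterion.
#' @param min_tic_percent inclusive minimum percent TIC.
#' @param min_bond_cleavages inclusive minimum bond cleavages per peptide.
#' @param min_ld_score inclusive minimum LD score.
#' @return named list of class `xlink_criteria`.
#' @export
xlink_criteria <- function(max_mass_error_ppm = 4, min_peptide_length = 6,
                           delta_score_cut = 0.9,
                           delta_direction = c("less", "greater"),
                           min_tic_percent = 0.1, min_bond_cleavages = 4,
                           min_ld_score = 20) {
  structure(list(max_mass_error_ppm = max_mass_error_ppm,
                 min_peptide_length = min_peptide_length,
                 delta_score_cut = delta_score_cut,
                 delta_direction = match.arg(delta_direction),
                 min_tic_percent = min_tic_percent,
                 min_bond_cleavages = min_bond_cleavages,
                 min_ld_score = min_ld_score),
            class = "xlink_criteria")
}

#' Filter a crosslink search-result table
#'
#' Retains a record only when every criterion holds, and labels each
#' retained record intermolecular when its two proteins differ. The
#' peptide-length criterion uses the `peptide_min_length` column when
#' present, otherwise the shorter of `peptide1`/`peptide2`.
#'
#' @param records data.frame with columns `protein1`, `protein2`,
#'   `mass_error_ppm`, `delta_score`, `tic_percent`,
#'   `min_bond_cleavages`, `ld_score`, and `peptide_min_length` (or
#'   `peptide1` and `peptide2` sequences).
#' @param criteria an [xlink_criteria()] object.
#' @return An object of class `xlink_filter_result`: `retained`
#'   (data.frame with added `intermolecular`), `n_input`, `n_retained`,
#'   `criteria`.
#' @export
filter_crosslinks <- function(records, criteria = xlink_criteria()) {
  stopifnot(inherits(criteria, "xlink_criteria"))
  need <- c("protein1", "protein2", "mass_error_ppm", "delta_score",
            "tic_percent", "min_bond_cleavages", "ld_score")
  miss <- setdiff(need, names(records))
  stop_if(length(miss) > 0, "missing column(s): %s",
          paste(miss, collapse = ", "))
  if (is.null(records$peptide_min_length)) {
    stop_if(is.null(records$peptide1) || is.null(records$peptide2),
            "missing column(s): peptide_min_length (or peptide1/peptide2)")
    records$peptide_min_length <- pmin(nchar(records$peptide1),
                                       nchar(records$peptide2))
  }
  cr <- criteria
  delta_ok <- if (cr$delta_direction == "less")
    records$delta_score < cr$delta_score_cut
  else records$delta_score > cr$delta_score_cut
  keep <- abs(records$mass_error_ppm) < cr$max_mass_error_ppm &
    records$peptide_min_length >= cr$min_peptide_length &
    delta_ok &
    records$tic_percent >= cr$min_tic_percent &
    records$min_bond_cleavages >= cr$min_bond_cleavages &
    records$ld_score >= cr$min_ld_score
  keep[is.na(keep)] <- FALSE
  retained <- records[keep, , drop = FALSE]
  retained$intermolecular <- retained$protein1 != retained$protein2
  structure(list(retained = retained, n_input = nrow(records),
                 n_retained = nrow(retained), criteria = criteria),
            class = "xlink_filter_result")
}

#' @export
print.xlink_filter_result <- function(x, ...) {
  cat(sprintf("Crosslink filter: %d of %d record(s) retained (%d intermolecular)\n",
              x$n_retained, x$n_input, sum(x$retained$intermolecular)))
  cat(sprintf(paste0("  criteria: |mass error| < %g ppm; peptide length >= %d; ",
                     "delta score %s %g; %%TIC >= %g; cleavages >= %d; ",
                     "LD >= %g\n"),
              x$criteria$max_mass_error_ppm, x$criteria$min_peptide_length,
              if (x$criteria$delta_direction == "less") "<" else ">",
              x$criteria$delta_score_cut, x$criteria$min_tic_percent,
              x$criteria$min_bond_cleavages, x$criteria$min_ld_score))
  invisible(x)
}

#' Generate a toy crosslink result table with known pass/fail ground truth
#'
#' Synthetic records spanning both sides of every filter boundary, for
#' exercising [filter_crosslinks()].
#'
#' @param n number of records.
#' @param pass_fraction fraction of records drawn from the passing regime.
#' @param proteins protein identifiers sampled for the two ends.
#' @param seed integer seed.
#' @return data.frame of crosslink records with a ground-truth
#'   `should_pass` column (ignored by the filter).
#' @export
simulate_crosslink_table <- function(n = 50, pass_fraction = 0.5,
                                     proteins = c("chaperone", "H3", "H4"),
                                     seed = 1L) {
  set.seed(seed)
  pass <- stats::runif(n) < pass_fraction
  # a failing record violates exactly one randomly chosen criterion
  fail_dim <- ifelse(pass, 0L, sample.int(6L, n, replace = TRUE))
  draw <- function(dim, pass_val, fail_val) ifelse(fail_dim == dim, fail_val,
                                                   pass_val)
  pep <- function(len) vapply(len, function(l)
    paste(sample(c("A", "G", "K", "L", "S", "V"), l, TRUE), collapse = ""), "")
  out <- data.frame(
    peptide1 = pep(draw(2L, sample(6:15, n, TRUE), sample(3:5, n, TRUE))),
    peptide2 = pep(sample(6:15, n, TRUE)),
    protein1 = sample(proteins, n, TRUE),
    protein2 = sample(proteins, n, TRUE),
    position1 = sample(1:900, n, TRUE),
    position2 = sample(1:900, n, TRUE),
    mass_error_ppm = draw(1L, stats::runif(n, -3.9, 3.9), stats::runif(n, 4.1, 8)),
    delta_score = draw(3L, stats::runif(n, 0, 0.89), stats::runif(n, 0.91, 1)),
    tic_percent = draw(4L, stats::runif(n, 0.1, 5), stats::runif(n, 0, 0.09)),
    min_bond_cleavages = draw(5L, sample(4:8, n, TRUE), sample(0:3, n, TRUE)),
    ld_score = draw(6L, stats::runif(n, 20, 45), stats::runif(n, 5, 19.9)),
    stringsAsFactors = FALSE)
  out$should_pass <- pass
  out
}
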