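# hexamertools

Quantification and simulation tools for single-molecule and structural
studies of hexameric AAA+ ATPase histone chaperones — ring-shaped motors
that load histone H3–H4 onto DNA in an ATP-hydrolysis-dependent manner.

Experiments of this kind combine several very different measurements, and
this package implements the full computational side of each:

- **Pseudo-AFM simulation** — predicted topographs of an atomic model
  scanned by a sphere-capped conical tip (apex radius *R*, half-cone angle
  *α*), computed as an exact hard-contact dilation with closed-form
  contact heights in both the spherical-cap and conical-flank regimes,
  followed by a Gaussian spatial low-pass filter (half-power at 1/λc).
- **HS-AFM movie analysis** — particle detection, apparent-width (FWHM)
  statistics with a population Gaussian fit, per-frame classification of
  hexamer rings into six angular sectors (open/closed subunits),
  dwell-time estimation of opening/closing rates *k*_open, *k*_close with
  an exact correction for frame-rate sampling
  (λ = 1 − q̂c − q̂o = e^−(k_open+k_close)Δ), and chi-square/exact
  multinomial tests of random subunit activation.
- **DNA-curtain quantification** — kymographs per DNA molecule,
  multi-Gaussian fitting of the intensity profile with BIC model
  selection, flow-off validation (only peaks that vanish when buffer flow
  stops are DNA-bound; surface-stuck spots persist and are rejected),
  fraction of DNA bound, and Kolmogorov–Smirnov uniformity tests of the
  binding-position distribution.
- **Ensemble assays** — fluorescence-anisotropy binding fits under the
  exact single-site ligand-depletion (quadratic) model
  f_b = ((P+L+Kd) − √((P+L+Kd)² − 4PL)) / 2P, steady-state ATPase rates
  from linear phosphate-release traces, and rule-based filtering of
  crosslinking mass-spectrometry result tables.
- **Structure geometry** — PDB/mmCIF models, Kabsch superposition
  (validated against a quaternion oracle), per-subunit domain centroids,
  inter-domain distances and angles, spiral rise along a cylinder-fit ring
  axis, inter-subunit gaps, and pore-diameter profiles.
- **Synthetic data with ground truth** — seeded generators for every
  input above (Gillespie ring dynamics sampled at the frame rate,
  two-channel curtain scenes with Poisson + read noise, titrations,
  ATPase traces, toy hexamer coordinate models), so that each pipeline can
  be validated end-to-end by parameter recovery.

The methods vignette (`vignettes/methods.Rmd`) documents every model,
default, and numerical choice.

## Worked example

Simulate an anisotropy titration at a known affinity and recover it, then
simulate an HS-AFM movie at known opening/closing rates and run the full
classification → dwell-time pipeline:

```r
library(hexamertools)

tp  <- titration_params(kd_true = 23, noise_sd = 0.004, seed = 101)
tt  <- simulate_titration(tp, n_replicates = 3)
fit <- fit_binding(tt, labeled_conc = 20)
fit
#> Binding fit (quadratic ligand model, labelled 20 nM)
#>   Kd = 23.2 nM  [21.4, 25.7] 95% CI
#>   r_free = 0.1500, r_bound = 0.3197, SSE = 0.000323

p  <- ring_dynamics_params(k_open = 1.5, k_close = 0.99, n_frames = 600,
                           n_molecules = 4, seed = 7)
rm <- simulate_ring_movie(p)
estimate_rates(classify_ring_states(rm))
#> Dwell-time rates (ctmc estimator, 221/222 events, 8 censored)
#>   k_open  1.588 /s  [1.412, 1.819] 95% CI
#>   k_close 0.958 /s  [0.858, 1.081] 95% CI
```

The fitted Kd (23.2 nM) recovers the planted 23 nM within its bootstrap
CI, and both kinetic rates recover the planted 1.5 s⁻¹ / 0.99 s⁻¹ from
~220 dwell events after frame-rate-aware correction.

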