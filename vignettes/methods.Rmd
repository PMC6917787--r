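---
title: "Models and methods behind hexamertools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hexamertools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexamertools)
```

`hexamertools` quantifies the single-molecule and structural experiments
used to characterise hexameric AAA+ ATPase histone chaperones: high-speed
AFM (HS-AFM) movies of rings whose subunits stochastically drop out of the
image plane ("ring opening"), DNA-curtain assays of histone deposition onto
barrier-anchored DNA, fluorescence-anisotropy binding titrations,
phosphate-release ATPase assays, crosslinking mass-spectrometry (XL-MS)
result tables, and the geometry of hexamer coordinate models in different
nucleotide states. Every analysis has a matching synthetic-data generator
with known ground truth, so the full pipelines can be validated by
parameter recovery.

This vignette records the statistical models, the tunable parameters and
their defaults, the numerical choices, and the known limitations.

## Synthetic data: what is emulated

**Ring movies.** Each molecule's conformational state evolves as a
continuous-time Markov chain: closed → open at rate $k_\mathrm{open}$
(opened subunit drawn uniformly among the six), open → closed at
$k_\mathrm{close}$, with an optional rare double-open branch (a second
subunit opens at $k_\mathrm{open}$ while one is open; each open subunit
then closes independently). Trajectories are simulated exactly with
Gillespie draws and only then sampled at the frame instants, so the
frame-rate censoring that the dwell-time estimators must handle enters
solely through the observation step. Defaults ($k_\mathrm{open} = 1.5$
s$^{-1}$, $k_\mathrm{close} = 0.99$ s$^{-1}$, 5 Hz) are the conditions of
the study this package models.

A ring is rendered as a Gaussian annulus with a six-fold angular
modulation,
$h(d,\theta) = A\, m(\theta)\, e^{-(d - r_c)^2 / 2\sigma_r^2}$ with
$m(\theta) = 1 - c\,(1 - \cos 6\theta)/2$. Because $m$ has period
$60^\circ$, opposite directions through the centre are identical, so the
distance between the outermost half-maximum crossings equals
$2(r_c + \sigma_r\sqrt{2\ln 2})$ along *every* direction. The generator
inverts this relation, which makes the planted apparent width (default
population 19.8 ± 2.6 nm) exact by construction rather than calibrated.
An open subunit is rendered by scaling its $60^\circ$ sector by
$1 - \texttt{open\_drop\_fraction}$ (default 0.8). Height noise is
additive Gaussian (default 0.2 nm per pixel), the standard detector model
for filtered HS-AFM topographs.

**Curtain movies.** DNA molecules are vertical columns anchored at a
barrier row; buffer flow extends them into the evanescent field. The green
channel carries the DNA stain, the red channel histone spots (Gaussian
point-spread function, default $\sigma$ = 1.2 px) and surface-stuck
distractors. At flow-off, columns and DNA-bound spots vanish while
distractors persist — by construction, since that is the physical basis of
flow-off validation. Counts are Poisson shot noise on signal plus
background with additive Gaussian read noise. The DNA contour length is
configuration (default 48,502 bp, λ-phage DNA) and maps affinely onto the
extended pixel length. The camera scale and exposure of the original
instrument are not published; photon-rate defaults (300 peak counts over a
100-count background) are explicitly arbitrary but give realistic
signal-to-noise. Not emulated: DNA polymer dynamics (recoil is modelled as
signal removal, not worm-like-chain mechanics), photobleaching, drift.

**Titrations.** With labelled histone at $P$ = 20 nM — comparable to the
dissociation constant — ligand depletion is not negligible, so the bound
fraction uses the exact single-site quadratic solution
$$f_b = \frac{(P + L + K_d) - \sqrt{(P + L + K_d)^2 - 4PL}}{2P},$$
and anisotropy is $r_\mathrm{free} + (r_\mathrm{bound} -
r_\mathrm{free})\,f_b$ plus Gaussian noise. Anisotropy endpoints (0.15,
0.32) and noise (0.004) are typical plate-reader values at the
standard-error scale of triplicate measurements.

**ATPase traces.** Phosphate release at steady state is linear:
$A_{360}(t) = A_0 + s_\mathrm{cal} \cdot r\,[\mathrm{hexamer}]\, t$ with
the calibration $s_\mathrm{cal}$ in absorbance per µM phosphate (default
0.011, the scale of coupled colorimetric phosphate assays), sampled at 5 s
then every 10 s, matching the assay protocol.

## Pseudo-AFM simulation

The image of a hard-sphere model scanned by a rigid probe is a
morphological dilation. For a sphere-capped cone (apex radius $R$ = 0.5
nm, half-cone angle $\alpha$ = 10° by default) over a sphere of radius $a$
centred at height $z_0$, the apex height at first contact has two analytic
regimes in the lateral offset $d$:

- spherical cap, $d \le (R+a)\cos\alpha$:
  $h = z_0 + \sqrt{(R+a)^2 - d^2} - R$;
- conical flank, $d > (R+a)\cos\alpha$:
  $h = z_0 + \big(a - (d - R\cos\alpha)\cos\alpha\big)/\sin\alpha - R(1 - \sin\alpha)$,

meeting continuously at the tangency offset. The map of a union of spheres
is the pointwise maximum, clipped at the substrate plane. The default
simulation grid is 0.2 nm/px — finer than experimental sampling — so that
grid bias is negligible in width statistics; tests verify the closed form
against a brute-force oracle that numerically lowers a discretised tip.

The spatial low-pass filter is a Gaussian transfer function with its
half-power point at spatial frequency $1/\lambda_c$ (default cutoff
wavelength $\lambda_c$ = 2.0 nm): amplitude at the cutoff is attenuated by
exactly $1/\sqrt{2}$ and the DC gain is exactly 1. Under this convention a
*larger* cutoff wavelength smooths more strongly; as $\lambda_c$ falls
below the pixel scale the filter approaches the identity (and warns that
it is ineffective below Nyquist). The filter family of the original
instrument software is not published; the convention here is recorded in
the output metadata.

## HS-AFM quantification

**Apparent width (FWHM).** Per particle, the profile through the
intensity-weighted centroid is taken along both image axes (bilinear
interpolation between adjacent rows/columns, so the line truly passes
through the centroid), the four half-profiles are folded about the centroid
and averaged into one radial profile, and the FWHM is twice the outermost
crossing of half the profile maximum. The fold implements the "average of
two orthogonal directions" while halving the noise on the profile maximum,
whose upward fluctuation is the main source of width bias; residual bias
is below 0.1 nm at the default noise level. The per-particle profile is
*never* fitted with a Gaussian — a ring profile is not Gaussian — only the
population of widths is summarised by a normal fit (mean, SD), matching
how AFM width histograms are reported.

**Ring-state classification.** Heights in an annulus around the radial
peak are summarised in six $60^\circ$ sectors (robust peak = 90th
percentile per sector); a sector is open when its height falls below
`open_threshold` (default 0.5) times the median of the six — a relative
criterion, invariant to global height scaling and drift. The sector frame
is registered either once from the mean frame ("static", default: adsorbed
molecules rotate little), per frame by the phase of the six-fold angular
Fourier component constrained to ±30° of the previous frame ("track"), or
supplied externally when ground truth is available. Frames whose maximum
falls below a detection floor are marked missing and excluded; dwells are
never bridged across missing frames.

**Dwell-time rates.** Dwells are run lengths of the frame-sampled state
sequence; the first and last dwell of every contiguous observed segment
are boundary-censored and dropped. Three estimators are exposed:

- `"ctmc"` (default): the frame-sampled process is itself a two-state
  Markov chain whose transition matrix is $e^{Q\Delta}$; with per-frame
  leave probabilities $\hat q_c, \hat q_o$ = 1/mean dwell, its second
  eigenvalue is $\hat\lambda = 1 - \hat q_c - \hat q_o =
  e^{-(k_\mathrm{open}+k_\mathrm{close})\Delta}$, giving
  $k_\mathrm{open} + k_\mathrm{close} = -\ln(\hat\lambda)/\Delta$, split
  by the stationary odds $\hat q_c : \hat q_o$. This inversion accounts
  for transitions that complete within one frame interval and is
  consistent; simulations in the test suite confirm negligible bias at
  2800+ events.
- `"geometric"`: $k = -f \ln(1 - 1/\bar n)$ per state, the memoryless
  discrete correction without the round-trip term. At rates approaching
  the frame rate it is biased low (about −10 to −14% at the default
  study conditions), which is why it is not the default.
- `"naive"`: $k = 1/\bar t$ on dwell durations in seconds; most biased.

Confidence intervals are percentile bootstrap over the dwell lists.

**Randomness of activation.** Opening events pooled over molecules are
tested for uniformity over the six subunits (chi-square), and consecutive
openings within a molecule for uniformity of the step
$\Delta = (s_{t+1} - s_t) \bmod 6$ — a rotary sequential mechanism
concentrates mass on one step. When expected cell counts drop below 6 an
exact multinomial test (full enumeration) is substituted and flagged.

## Curtain quantification

Kymographs stack the per-frame profile along each DNA (default 3-column
average). The analysis profile is the tenth kymograph frame by convention,
configurable. Peak candidates are local maxima more than 3 robust SDs
above the robust baseline; sums of $K$ Gaussians plus a constant baseline
are fitted jointly for $K$ from 0 to one more than the number of
candidates (two spots closer than ~2σ merge into a single maximum, so one
extra component seeded by splitting the strongest candidate is always
tried), and $K$ is selected by BIC. If a joint fit fails, per-peak local
fits are used and flagged.

A fitted peak is validated as DNA-bound when (a) its background-subtracted
mean intensity at the peak position during flow-off frames is below 20% of
its fitted flow-on amplitude (the threshold is configurable; the original
report states the principle but no number), and (b) its fitted width is at
least `min_peak_width` (default 0.9 px): a diffraction-limited spot can
never be narrower than the point-spread function, so sub-PSF components
are single-pixel noise. Fraction bound is the share of DNA with at least
one validated peak. Validated peak centres map affinely to kb (barrier →
0, DNA end → contour length, half-open) and are tested against uniformity
with a one-sample Kolmogorov–Smirnov test. Disassembly-style comparisons
use a Mann–Whitney test on per-DNA total validated intensity with a
rank-biserial effect size.

The extraction window extends a few pixels past the DNA end so end-bound
spots keep their point-spread support. Known limitation: spots within
about half a PSF width of the barrier or DNA end are still occasionally
missed, biasing fraction-bound estimates down by roughly 1–2% at high
occupancy; the validation tests budget for this explicitly. Occupancy is
planted as an exact count (stratified assignment of `round(p * n)`
occupied DNA), so a simulated scene realises the stated occupancy rather
than a binomial draw around it — recovery error then measures the
pipeline, not the draw.

## Ensemble fits and XL-MS filtering

The binding fit is nonlinear least squares of the quadratic
ligand-depletion model above (the hyperbolic model is available for the
dilute regime and agrees within 1% when the labelled concentration is far
below $K_d$); $K_d$ is bounded at zero and its CI comes from case-resampling
bootstrap. The ATPase rate is the OLS slope over a configurable
steady-state window, converted by
$\mathrm{rate} = \mathrm{slope} \cdot 1000 / (s_\mathrm{cal}\,
[\mathrm{hexamer}]_\mathrm{nM})$ (one phosphate per ATP); with replicates,
the reported rate is the replicate mean ± SE.

The crosslink filter retains a record only when all criteria hold:
|mass error| < 4 ppm (strict), peptide length ≥ 6, delta score < 0.9
(strict; this direction is unusual for some search-engine conventions and
can be switched), %TIC ≥ 0.1, bond cleavages ≥ 4, LD score ≥ 20.
Boundary semantics follow the printed criteria literally and are echoed in
the result header. Retained records are labelled intermolecular when the
two proteins differ. FDR estimation is out of scope — it is a property of
the upstream search, not of this filter.

## Structure geometry

Domain centroids are unweighted means of Cα coordinates over
author-numbered residue ranges — Cα only, because side-chain completeness
differs between chains in intermediate-resolution models. The
inter-domain distance is between the two nucleotide-binding-domain (NBD)
centroids; the angle is at the helix-bundle-domain (HBD) centroid between
the vectors to the two NBD centroids (the angle convention is a package
choice, documented and configurable). Deltas are reported against a
reference chain (default A). Domain boundary ranges are configuration:
published figures print only partial ranges, so any shipped ranges are
non-authoritative, and the reported inter-subunit differences shift
slightly under different reasonable boundaries.

Superposition solves orthogonal Procrustes by SVD with the determinant
correction (no reflections), pairing atoms by chain/residue/atom name; the
test suite checks it against an independent quaternion-eigenvalue oracle
to $10^{-6}$ Å.

The ring axis starts from the least-squares plane through chain centroids
and is then refined to the cylinder axis that minimises the spread of
their radial distances. The refinement matters for spirals: a plane fit
absorbs most of a helical rise into tilt, whereas the cylinder axis is
tilt-free for a circular staircase, so per-subunit rises are recovered
exactly on toy spirals. The pore profile is, per axial slab (default 4 Å),
twice the minimum over atoms of (radial distance − van der Waals radius);
the summary pore diameter is the minimum over the central half of the
axial extent, since the slab convention behind published pore numbers is
not stated.

## Problem sizes and reproducibility

All generators are pure functions of their parameter object, including its
seed. The validation suite runs full pipelines at deliberately moderate
sizes chosen to make Monte-Carlo error small relative to the tolerances:
12,000-frame trajectories for stationarity, ~500–750 dwell events for rate
recovery, 120 ring particles for width statistics, 200 DNA molecules per
curtain condition, triplicate titrations and traces. `scripts/acceptance.R`
re-runs the five headline pipelines from scratch at these sizes and writes
the recovered quantities as JSON; see the README for how to run it.
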