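---
title: "Sensor-space group analysis for fNIRS: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensor-space group analysis for fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical decisions that shape results at the
margins.

## 1. The measurement model

Continuous-wave fNIRS measures optical-density changes Δφ at two
wavelengths for each source–detector channel. Under the modified
Beer–Lambert law the change is linear in the chromophore concentration
changes,

Δφ(λ) = (α_H(λ) ΔHbO + α_Q(λ) ΔHbR) · d(λ, a) · l,

with α the molar absorption coefficients (mM⁻¹ cm⁻¹), d the
differential pathlength factor (DPF), and l the source–detector
separation (cm). Two wavelengths give a 2×2 linear system per sample
and channel; `od_to_hb()` solves it in closed form and refuses
wavelength pairs whose determinant
α_H(λ₁)α_Q(λ₂) − α_H(λ₂)α_Q(λ₁) is numerically zero (tolerance
1e-12 relative to the coefficient products), because a near-singular
inversion amplifies noise without bound.

**Assumptions.** Differential measurements only (no absolute
concentrations); exactly two wavelengths; scattering changes and
partial-volume effects are absorbed into the DPF and not modelled.
The shipped absorption table (`extinction_defaults()`) and the
age-dependent DPF equation (`dpf_model_general()`, valid 690–832 nm,
increasing in age) are compiled defaults for convenience: conversion
*correctness* never depends on them (tests use explicit coefficients),
and quantitative applications should supply instrument-specific values.
Units are fixed — mM, cm, nm — and the converters never rescale
silently.

## 2. Temporal preprocessing

The chain runs motion correction → band-stop → DCT high-pass →
downsampling, each channel independently, each stage linear except the
(data-driven) motion step.

* **Motion artifacts** (`correct_motion()`): samples whose moving
  standard deviation (window 1 s) exceeds 3× the channel's median
  moving SD are grouped into segments; each segment is replaced by a
  smoothing-spline fit linearly adjusted to join the neighbouring
  untouched samples, which removes spike-like excursions while leaving
  every sample outside a segment bit-identical. Window and threshold
  are overridable; the defaults suit 10 Hz recordings with second-scale
  artifacts. This moving-SD + spline scheme is one published family of
  motion correction; wavelet and PCA approaches are out of scope.
* **Physiological oscillations** (`bandstop_physio()`): zero-phase
  (forward–backward) 5th-order Butterworth band-stops over
  0.12–0.35 Hz (respiration, Mayer waves) and 0.7–2.0 Hz (cardiac).
  Zero-phase filtering avoids phase-distorting the hemodynamic
  response; the cost is an effective doubling of the order, which is
  documented rather than hidden. Numerically, narrow normalized bands
  make the transfer-function DC gain ill-conditioned to evaluate as
  sum(b)/sum(a), so the implementation pins the analytically unit DC
  gain — constants pass through exactly.
* **Slow drift** (`dct_highpass()`): the orthonormal DCT regressor set
  below 1/64 Hz (including the constant) is projected out; the
  projection is idempotent and the basis is returned for use as
  confounds. The k-th basis function has frequency k/(2·M·dt), so the
  basis holds ⌊2·T·f_c⌋ + 1 columns for a T-second series.
* **Downsampling** (`downsample_hb()`): anti-alias low-pass at 80% of
  the target Nyquist, then decimation. Only integer ratios are allowed
  — fractional resampling would introduce kernel ambiguity the analysis
  does not need, as acquisitions at 10 Hz target 1 Hz.

A caveat recorded here because it is easy to over-read: band-stop and
DCT high-pass commute only up to finite-length edge effects (the DCT
projection is global, the filter's reflection padding is local), so the
package's property tests check commutation away from the series ends at
1e-3 relative, not at machine precision.

**Filtering the model like the data.** `first_level_pipeline()` pushes
the task regressors through the same band-stop, high-pass and
decimation as the data. This follows directly from writing the
filtered GLM as Y* = SY, X* = SX: if the data lose power in the
stopbands but the regressors keep it, effect estimates shrink — about
30% in our end-to-end simulations. Matched filtering restores unbiased
channel-level recovery, which the test suite verifies against generator
ground truth.

## 3. Within-subject GLM

The hemodynamic response is a double-gamma kernel: gamma densities
parameterized by their mode so the response peaks exactly at 6 s and
the undershoot at 16 s, dispersions 1 s, undershoot ratio 1/6, support
32 s, normalized to unit peak. The mode-parameterization is a
deliberate choice: the printed peak delay is then exact by
construction rather than approximate. Dispersions and undershoot ratio
are configurable because published toolboxes differ in them.

Events are delta sticks (boxcars when durations are positive) convolved
with the canonical kernel and, optionally, its temporal derivative to
absorb peak-latency variability. A constant column is always appended
— filtered Δ-series still carry arbitrary offsets. Temporal
autocorrelation is modelled AR(1) with a single global coefficient
pooled across channels (the innovation variance stays channel-specific)
estimated from OLS residuals, followed by one whitened refit — a
Cochrane–Orcutt-style pass rather than full ReML, which matches the
AR(1)+global-correlation structure the model specifies while staying
cheap at 52 channels. The whitening matrix is the exact bidiagonal
square-root inverse of the AR(1) correlation (S V Sᵀ = I), stored
sparse. Degrees of freedom are reported as M − L; no AR-induced
effective-dof correction is applied at the first level because group
inference consumes only the contrast values, not first-level variances.

## 4. Canonical scalp surfaces and interpolation

Channel positions (MNI mm) are projected radially onto a least-squares
head sphere. Two canonical representations are supported:

* **2D disc**: azimuthal-equidistant projection about the vertex
  (planar radius = scalp radius × polar angle), the planar surface of
  the 10–20 convention. The default 64×64 grid spans the disc of
  radius R·π/2 and records its pixel size (≈4.5 mm at R = 90 mm) in
  the NIfTI header. Channel contrasts are interpolated
  piecewise-linearly over the Delaunay triangulation — exact at
  channels, exact for affine fields, bounded by the data range, NA
  outside the channel hull (extrapolation is refused, because group
  overlap is only meaningful where channels support the map) — and
  then smoothed with a mask-renormalized 14 mm FWHM Gaussian so that
  the error field is smooth relative to the pixel size, as topological
  inference assumes. Renormalizing the kernel over defined pixels
  keeps constants exact up to the mask edge instead of biasing edge
  pixels toward zero. The triangulation is computed by `deldir`;
  barycentric evaluation is vectorized in the package. (A sweep-hull
  triangulator was rejected: it jitters co-circular inputs — exactly
  what a regular probe grid is — and loses exactness and determinism.)
* **3D mesh**: an icosphere (icosahedron subdivided s times, midpoints
  merged, vertices on the unit sphere; V = 10·4ˢ + 2), s = 4 by
  default for the 2562-vertex canonical surface. Channel contrasts are
  interpolated with order-4 spherical splines: the Legendre-series
  kernel is summed until the coefficient bound (2n+1)/(n(n+1))ᵐ falls
  below 1e-10 (≈30 terms at m = 4), with polynomials by the stable
  three-term recurrence. The augmented system enforces exact
  reproduction at channels and zero-sum kernel coefficients.

**A conditioning decision.** The order-4 kernel is extremely smooth,
so the interpolation matrix for a densely packed 52-channel array has
condition number ~1e9 and coefficient norms ~1e8. Even a 1e-12 ridge
then perturbs channel reproduction by ~1e-4 — far above the 1e-8 the
exact-reproduction property demands. The default is therefore *no*
ridge plus one step of iterative refinement (reproduction ≈5e-10 on
the standard array); a ridge argument remains for genuinely degenerate
layouts. Relatedly, the zero-sum constraint is satisfied at the
solver's absolute precision (~1e-8 when coefficients are ~1e8), which
is machine precision *relative to the coefficient scale*.

The search region (`make_search_mask()`) is the set of pixels/vertices
within 30 mm (the 3 cm optode separation) of any channel — Euclidean
on the grid, great-circle on the mesh — intersected on the grid with
the dilated channel hull and the disc. The radius is a stated,
overridable default; published mask sizes depend on unstated
construction details and are not treated as ground truth.

## 5. Group model and topological inference

Per-subject contrast images are stacked over the *intersection* of
subject masks (group inference is undefined where any subject lacks
support) and fitted with the summary-statistics random-effects model.
Its residual variance estimates the mixed within+between subject error;
for the default one-sample design the statistic is exactly the
classical one-sample t with N − 1 (= 20 at N = 21) degrees of freedom,
which the tests verify to 1e-10. Locations with zero residual variance
return NA rather than failing.

Two corrections are offered, mirroring standard practice:

* **Bonferroni over channels**: one-sided t quantile at α/52.
* **RFT over the search region**: smoothness is estimated from the
  variance of spatial derivatives of the standardized second-level
  residuals (the only residuals a summary-statistics pipeline has) —
  FWHM = √(4 ln 2 / λ) per dimension, finite differences on the grid,
  per-triangle linear-interpolant gradients on the mesh. Resel counts
  follow the standard construction: R₂ = area/FWHM², R₁ =
  half-boundary-length/FWHM, R₀ = the mask's Euler characteristic
  (quad-counting on the grid, V−E+F on the mesh). Peak inference uses
  the t-field Euler-characteristic densities; the cluster-forming
  threshold solves Σ_d R_d ρ_d(T_c) = α by bisection (the bracket
  expands adaptively; for dof ≤ 2 the 2D density does not decay in t,
  so small α can be genuinely unreachable and the package says so
  rather than returning a number). Cluster p-values use the
  stationary 2D Gaussian-field extent approximation with the
  Gaussianized-threshold convention: cluster count ~ Poisson with mean
  the expected EC, extents exponential with mean the expected
  suprathreshold resel volume per cluster. t-field extent densities
  would be the natural refinement and are noted as an extension.
  Connectivity is 8-neighbour on the grid and shared-edge on the mesh.

Smoothness estimation degrades at very small N (few standardized
residual images); below ~8 subjects treat resel estimates as noisy.
Two-sided inference is deliberately not offered — contrast direction
is explicit in this framework.

## 6. What the generator emulates, and what it does not

`simulate_events()`/`simulate_subject()`/`simulate_group()` mirror the
two-level generative model at the scale of the motivating study: 52
channels in a 3×11 prefrontal band (17 sources, 16 detectors, 3 cm
spacing on a 90 mm sphere), 10 Hz sampling, 80 frequent + 20 rare
events with ISIs uniform on 9–12 s, AR(1) temporal noise, sinusoidal
cardiac (1.1 Hz) and respiratory (0.25 Hz) components with
subject-random phase placed inside the band-stop stopbands so the
filtering stage is exercised verifiably, subject effects
w_n = w_pop + z_n with z_n ~ N(0, σ_b²), and HbR as a scaled inverted
copy of the HbO signal. Defaults σ_w = 0.3, σ_b = 0.5 encode the
reported dominance of between-subject over within-subject variability
in fNIRS. All randomness flows from one master seed through
per-subject substreams; identical seeds give bit-identical datasets.

`simulate_channel_contrasts()` draws per-subject channel contrasts
directly from w̄_n = w_pop + z_n + e_n — the exact distributional
assumption the second level makes about the first. Operating
characteristics of the *spatial* inference (family-wise error, power)
are simulated at this level: the first level is channel-wise and
independent of the property under test, and the contrast-level
shortcut is what makes 200-replicate simulations routine. The time
series path is validated separately by end-to-end recovery tests at
reduced scale.

The optional `spatial_scale` parameter draws z_n from a Gaussian
process over channel positions (squared-exponential, length in mm)
instead of independently per channel. Independent channel noise
produces group maps about as rough as the channel spacing — estimated
resel counts then approach the channel count and RFT has no advantage
over Bonferroni. Spatially coherent between-subject variability
(vascular and anatomical variation is not white across a 3 cm array)
produces the smooth regime in which RFT thresholds drop below the
Bonferroni threshold; with σ_w = 0.15, σ_b = 0.5 and a 60 mm length
the simulated search region is worth ~2.5–4 resels, inside the range
reported for real prefrontal Stroop data, and the threshold ordering
reproduces. Both regimes are first-class study conditions in the test
suite.

Not emulated: scalp-versus-cortex partial volume and short-channel
physiology (no short-separation channels are simulated), photon
transport, motion artifacts with realistic spectra (the motion stage
is tested with injected artifacts instead), subject-specific head
geometry (channel jitter is available but subjects share one canonical
sphere), and condition-dependent HRF shape. Passing tests therefore
demonstrate statistical correctness of the pipeline under its own
model assumptions — not robustness to every violation real data can
produce.

## 7. Numerical choices, degenerate inputs, problem sizes

* Zero-phase filtering uses odd-reflection end padding with
  steady-state initialization, exact for constants; pad lengths scale
  with the lowest band edge.
* AR(1) coefficients are clipped to |ρ| ≤ 0.99; |ρ| ≥ 1 is a
  stationarity error.
* Delaunay triangulation of collinear channels, duplicate channel
  directions, empty masks, rank-deficient designs, zero-variance
  residuals, mixed image spaces, and N = 1 groups all raise named
  errors rather than propagating NaNs; zero group variance at a
  location flags the statistic NA.
* NIfTI images store masked pixels as NaN and the pixel size in the
  header; GIfTI files use ASCII encoding (text, lossless for float32,
  diffable); SNIRF containers hold dual-wavelength optical density
  plus probe geometry.
* Test-suite problem sizes are chosen to exercise the study scale
  while keeping the suite quick: operating-characteristic simulations
  use 200 null and 50 effect replicates of N = 21 × 52 channels on the
  64×64 grid (about 4 minutes total), smoothness recovery uses 100
  fields, and end-to-end time-series recovery uses 6 subjects with 15
  events at reduced sampling. The defaults users see are always the
  full study-scale values.

## 8. Known limitations

Cluster p-values rest on a Gaussian-field approximation applied to a
t-field via Gaussianization; they are approximate at dof ≈ 20 and
small resel counts, and peak-level inference is the safer quantity in
this regime. Smoothness is assumed stationary across the search
region. The NFRI-style registration from 10–20 landmarks to MNI space
is out of scope — channel MNI coordinates are an input. Short-channel
regression, FIR/adaptive response bases, permutation corrections,
false-discovery-rate control and source reconstruction are all
deliberate non-goals of this package.
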