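---
title: "neodot methods: from photons to seizure haemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neodot methods: from photons to seizure haemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the methods implemented in **neodot**: the optical
physics, the numerical forward model, the image reconstruction, and — in most
detail — the event-timing estimators, whose design choices are the least
standard part of the package.

## 1. Spectroscopy: the modified Beer–Lambert law

For a source–detector channel with separation $\rho$ (mm), the change in
optical density at wavelength $\lambda$ relative to the channel's own
temporal mean intensity is

$$\Delta\mathrm{OD}_\lambda(t) = -\ln\frac{I_\lambda(t)}{\bar I_\lambda}
 = \big(\varepsilon_{\mathrm{HbO}}(\lambda)\,\Delta[\mathrm{HbO_2}]
 + \varepsilon_{\mathrm{HbR}}(\lambda)\,\Delta[\mathrm{HbR}]\big)\,
 \rho\,\mathrm{DPF},$$

with molar extinction coefficients $\varepsilon$ (per µM per mm) and a
differential pathlength factor DPF of 4.9, appropriate for the neonatal
head. With two wavelengths (780 and 850 nm) this is a per-channel 2×2 linear
system; `mbll_convert()` solves it directly. The extinction pair is chosen on
opposite sides of the haemoglobin isosbestic point — HbR dominates at 780 nm,
HbO₂ at 850 nm — so the system is well conditioned (condition number < 20)
and the forward/inverse round trip is exact to numerical precision
(`mbll_forward()` then `mbll_convert()` agree to ~1e-14 µM).

Because the OD reference is the channel's own mean, absolute concentrations
are not recoverable; all outputs are changes about an arbitrary per-channel
constant, which downstream baselining removes.

## 2. Preprocessing

`preprocess_bundle()` applies, in order:

1. **Channel QC** — channels with mean intensity below an absolute floor
   (dead/disconnected optodes) or with excessive high-frequency coefficient
   of variation are dropped and reported in a QC tibble.
2. **Step-artifact correction** — abrupt gain steps (optode lift/re-seat)
   are detected as outliers of the differenced log-intensity; each segment
   between detected steps is refit with a near-interpolating smoothing
   spline (`all.knots = TRUE`, penalty ~1e-12 scaled) and segments are
   re-levelled so the piecewise trend is continuous. The near-interpolation
   setting matters: `stats::smooth.spline`'s default reduced knot set cannot
   represent a one-sample jump at *any* penalty, which silently leaves most
   of the step in place.
3. **Zero-phase band filtering** — 5th-order Butterworth applied with
   `signal::filtfilt` after odd-reflection padding of ten characteristic
   periods of the cutoff. `filtfilt` in the signal package has no
   initial-condition handling, so padding is the only transient control;
   three periods measurably leaves an O(1e-3) DC transient at the ends,
   ten periods reduces it below 1e-12.
4. **MBLL conversion** and a **global average** HbT trace over retained
   channels, the input to event analysis.

## 3. The forward model

### Photon diffusion FEM

Continuous-wave light transport in tissue is modelled by the diffusion
approximation

$$-\nabla\!\cdot\!\big(D(\mathbf r)\nabla\phi(\mathbf r)\big)
 + \mu_a(\mathbf r)\,\phi(\mathbf r) = q(\mathbf r),
 \qquad D = \frac{1}{3(\mu_a + \mu_s')},$$

with a Robin boundary condition $\phi + 2AD\,\partial_n\phi = 0$ encoding
the refractive-index mismatch at the skin. `fem_measure()` discretises this
with linear (P1) tetrahedral elements; the absorption term is mass-lumped to
the nodes, so each node $j$ owns a volume $V_j$. Collimated sources are
placed one transport mean free path ($1/\mu_s'$) below the surface.

Meshes are structured Kuhn (6-tetrahedra-per-cube) grids: an axis-aligned
slab with arbitrary grading, or a hemisphere obtained by mapping the cube
grid through an equal-max-norm cube-to-ball map. Layered optical properties
(extracerebral tissue, grey matter, white matter) are assigned by depth.

The solver is validated against the analytic extrapolated-boundary
semi-infinite solution (image-dipole construction): after removing a single
global source-amplitude factor, FEM and analytic boundary measurements agree
within 1.7% across 20–40 mm separations on a graded mesh with ≤ 1 mm edges
near the optode line.

### Adjoint Jacobian

Sensitivity of a channel's OD to nodal absorption follows from the adjoint
theorem. With mass-lumped absorption the discrete form is *exact*:

$$\frac{\partial\,\mathrm{OD}_c}{\partial \mu_{a,j}}
 = \frac{\phi_{s}(\mathbf r_j)\,\phi_{d}(\mathbf r_j)\,V_j}{m_c},$$

where $\phi_s,\phi_d$ are the forward and adjoint (detector-sourced) fields
and $m_c$ the unperturbed measurement. Because this is the exact derivative
of the discrete system, finite-difference perturbation of $\mu_a$ at single
nodes reproduces it to 0.01% — the comparison is direct, with no
volume-weighting correction. `build_jacobian_set()` assembles per-wavelength
Jacobians and a stacked multispectral system mapping nodal
$(\Delta\mathrm{HbO_2}, \Delta\mathrm{HbR})$ to all channel/wavelength ODs
through the extinction coefficients.

## 4. Image reconstruction

The stacked system $y = A x$ is hugely underdetermined (dozens of channels,
~10⁴ node unknowns per chromophore). `reconstruct_frame()` solves
zeroth-order Tikhonov in its dual form,

$$\hat x = A^\top (A A^\top + \lambda^2 I)^{-1} y,$$

via a Cholesky factorisation of the small channel-space matrix, which is
reused across frames by `reconstruct_series()`. The regulariser is
$\lambda = 0.01\,\sigma_{\max}(A)$ (`choose_lambda()`), i.e. singular-value
filtering with factors $d_i/(d_i^2+\lambda^2)$ — the dual solution is
algebraically identical to the dense SVD-filtered solution (verified to
1e-16 in the tests). Frames are baselined against a pre-event window and can
be projected to the grey-matter surface (`project_series_to_surface()`) for
display. Focal localisation uses an upper-quantile-thresholded intensity
centroid (`field_centroid()`); on the default hemisphere mesh a noiseless
focal ΔHbO₂ blob rendered through the same physics localises to ~6.6 mm.

## 5. Event-timing estimators

The scientific target is the triple of phase durations per seizure:
time from electrographic onset to the HbT maximum, maximum-to-minimum time,
and minimum-to-recovery time. The estimator design in `response_metrics()`
was driven by measured failure modes on synthetic truth:

* **Two-scale search.** Extremum location on the raw 10 Hz trace is
  noise-limited; on a heavily smoothed trace it is bias-limited (smoothing
  shifts an asymmetric peak). The estimator first localises each extremum on
  a 0.2 Hz-smoothed trace, then refines on the raw trace within a window
  around the coarse location; the trough is additionally refined by a
  two-branch quadratic fit around the knot, since the programmed waveform is
  piecewise smooth with a derivative break there.
* **Recovery with a hold.** Recovery is the first baseline re-crossing that
  *holds*: the trace must stay at or above $-\epsilon$ for 20 s, tolerating
  dips in at most 5% of samples. $\epsilon = \max(2\sigma_s,\;10^{-6}
  (\mathrm{peak}-\mathrm{trough}))$, where $\sigma_s$ is the noise SD of the
  smoothed trace. The crossing is interpolated between samples and
  bias-corrected by $+\sqrt{\epsilon/k}$ with $k$ the local curvature of the
  approach — a quadratically-closing tail reaches $-\epsilon$ exactly that
  long before it reaches zero.
* **Noise-SD estimation.** $\sigma_s$ is the *median* of
  quadratically-detrended SDs over three 30 s pre-onset sub-windows, with the
  residual variance corrected for the fitted parameters using an effective
  sample count adjusted for lag-1 autocorrelation (a 30 s window of a 0.2 Hz
  trace carries only ~12 independent samples). A minimum over sub-windows,
  tried first, is badly downward-biased at this effective sample size and
  caused multi-second late recovery detections; the median retains
  robustness to contamination by the previous event's tail without the bias.
* **Censoring.** A phase whose search window is cut off by the next event's
  onset is reported `NA` and flagged `censored`; a trace whose peak does not
  rise above the pre-onset noise is flagged `unresponsive`.

Between events, the inter-ictal trend is estimated by a robust linear fit to
samples outside all event response windows (`detrend_interictal()`), which
is unbiased by the responses themselves — unlike a whole-trace fit.

On synthetic scenes the pipeline recovers programmed phase knots to
≤ 0.09 s without noise and ≤ 1.9 s with 0.1% multiplicative intensity noise
over 140 events. The residual noisy error is an identifiability limit of the
waveform, not the estimator: near the flat HbT maximum the trace stays
within ~2σ of its peak for over a second.

## 6. Group inference

`hemispheric_power_test()` compares left- vs right-hemisphere EEG band power
per event with a paired two-sided t-test. Its empirical size is verified on
null data: over 1000 simulated null cohorts the rejection rate at
$\alpha = 0.05$ falls within [0.03, 0.07].

## 7. Synthetic scenes as ground truth

`simulate_recording()` composes (i) a non-overlapping seizure schedule with
jittered onsets and two synthetic annotators whose mean is the consensus,
(ii) a C¹ piecewise-smooth biphasic HbT waveform with programmable rise /
fall / recovery durations, amplitudes and undershoot scale, (iii) a spatial
pattern on the head mesh rendered through the same Jacobian physics used for
reconstruction (or a direct channel-space shortcut), and (iv) a nuisance
model: multiplicative intensity noise, slow drift, a cardiac oscillation,
dead channels, and step artifacts. The bundle carries its full ground truth,
so every claim in the test suite is checked against known values rather than
regression snapshots.
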