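---
title: "Models and estimators for midpiece contraction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators for midpiece contraction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midpiece)
```

This vignette documents the models behind the package: what the synthetic
generator simulates, how each estimator works, which numerical choices were
made where the underlying procedures leave them open, and what the test
suite does and does not establish about real data.

## The midpiece model

`make_geometry()` describes a mouse sperm midpiece as a straight tube of
arclength `length_um` (default 21.2 µm) and baseline radius
`membrane_radius_um` (default 0.731/2 µm, half the intact outer diameter),
wrapped by an `n_strands`-start actin helix with per-strand axial pitch
`helix_pitch_nm` (intact default 244 nm; 87 gyres over the midpiece) and
strand radius `helix_radius_nm` (intact default 300 nm). The
acrosome-reacted state is the same model with pitch 159 nm and radius
252 nm. The membrane-to-actin peak distance is an independent parameter
`gap_membrane_actin_um` (default 0.180 µm); it is deliberately *not*
derived from the difference between tube radius and helix radius, because
the measured gap and the two radii are not mutually consistent — the
generator keeps them as independent knobs rather than silently reconciling
them.

**Contraction program.** Imaging shows contraction starting at one or two
initiation foci and then involving the whole midpiece, but no functional
form is established. We model the normalized diameter at position $s$ as a
falling logistic in time,

$$ d(s, t) = 1 - \frac{a}{1 + e^{-k\,(t - t_{on}(s))}}, \qquad
   t_{on}(s) = t_{focus} + \frac{\mathrm{dist}(s, \text{nearest focus})}{v}, $$

with amplitude $a$ (`contraction_amplitude`), steepness $k$
(`onset_rate_s`, default 0.25 s⁻¹), and propagation speed $v$
(`propagation_um_s`). The default $v = 0.2$ µm/s lets onset propagate
across a 21 µm midpiece in about two minutes, matching the minutes-scale
contraction kymographs the model emulates. These three constants are the
generator's study conditions; recovery tests run against the ground truth
the generator exports, not against these constants directly.

**Event clock.** The calcium transient starts at `ca_onset_s` and the
membrane-dye rise at `fm_onset_s`, with `ca_onset_s < fm_onset_s` enforced
structurally — the generator builds the event ordering that the dynamics
module is later asked to recover.

**Membrane-dye coupling.** The reference linear model between normalized
diameter $x$ and normalized membrane-dye fluorescence $y$ is
$y = m x + b$ with $m = 8.90$, $b = -8.05$, $R^2 = 0.32$, on the axis
convention x = diameter, y = fluorescence. Note a sign tension inherited
from the source material: the observed biology is fluorescence *rising*
while the diameter *falls* (a negative association), yet the published
slope on these axes is positive. `simulate_regression_pairs()` and
`fit_fluorescence_diameter()` follow the printed axes and slope verbatim,
so slope/intercept recovery is exact and self-consistent. For the
time-lapse render, evaluating $y = mx+b$ literally at contracted $x$
would give *negative* fluorescence, contradicting the rise it must show;
`render_timelapse()` therefore couples the membrane trace as
$\Delta F/F_0 = m\,(1 - x(t))$ — the same slope magnitude per unit
contraction, in the direction the movies actually show.

## What the generator does and does not emulate

Renders include Gaussian peak/ridge profiles (the point-spread function is
folded into the peak width analytically), Poisson shot noise, detector
offset, gain, and Gaussian read noise (scalar or per-pixel map), and
i.i.d. Gaussian profile noise. Localizations get isotropic Gaussian
perturbations of magnitude `precision_nm`, with the two strands
phase-offset by π (the natural two-start offset; not explicitly stated in
the source structure work, fixed here once).

Not emulated: realistic 3-D/astigmatic PSFs, fluorophore blinking
kinetics, drift, flagellar curvature and out-of-plane beating, cell-to-cell
heterogeneity, or background autofluorescence structure. Passing recovery
tests therefore demonstrates that the estimators are correct for data with
the assumed statistical structure; they do not certify performance on raw
microscope output, where segmentation and drift correction dominate and
are out of scope here.

Default pixel sizes are 0.1 µm for wide-field emulation and 0.02 µm radial
steps for super-resolved profiles — typical for the respective modalities;
the source imaging calibrations are not stated.

## Diameter from profile autocorrelation

The cross-section profile of a membrane-stained tube has two maxima at
±radius. Their separation appears in the profile autocorrelation as the
largest nonzero-lag maximum; `diameter_from_profile()` returns that lag.
Numerical details that matter:

* **Background removal.** The profile median (the peaks occupy a minority
  of the crossline) is subtracted before correlating, and the
  autocorrelation is computed without further demeaning. Correlating the
  raw background instead produces finite-window cross terms — when a peak
  exits the overlap window at lag ≈ separation, the secondary maximum
  acquires a kink that can shift it by a step or two. Median subtraction
  removes the background exactly for noise-free profiles and without bias
  under noise (where subtracting the minimum would re-introduce a
  noise-floor background).
* **Search band.** Lags are restricted to 0.2–1.5 µm, the physiological
  diameter range, so axoneme/actin secondary structure cannot win.
* **Sub-step refinement.** The winning lag is corrected for the biased
  estimator's $1/n$ taper, locally detrended by the chord through a
  ±3-step window, and refined with a three-point parabola, with one
  recentering iteration. The refined estimate agrees with a direct
  peak-position oracle to within half an offset step on noise-free
  profiles; the test suite asserts agreement within one step across 100
  random profiles.
* **Undetermined diameters.** If no secondary maximum in the band exceeds
  `min_acf = 0.1`, the function returns `NA` ("diameter undetermined") —
  a genuine peak pair correlates far above this; flat profiles, single
  peaks, and pure noise do not. `normalized_diameter_kymograph()` errors
  if more than half of a position's baseline frames are undetermined.

The estimate is invariant to intensity scaling and additive offsets by
construction.

## Onsets and initiation foci

`detect_contraction_onset()` reports the first frame of a sustained drop
below $1 - \text{drop\_threshold}$ (defaults: 10% drop, 5 frames). The
run is evaluated with hysteresis — triggered below the full threshold,
sustained below half of it — because single noisy frames near the
threshold would otherwise fragment a genuine contraction and delay the
reported onset by many frames. The same scheme, with k·σ thresholds from
the baseline window, drives `detect_event_onset()` for fluorescence
traces.

`find_initiation_foci()` takes the per-position onset profile and returns
its local minima: contraction starts at a focus and reaches other
positions later, so foci are onset minima over arclength. Minima closer
than `min_separation_um` (default 2.5 µm, one crossline spacing) merge,
keeping the earliest onset; plateaus of exactly equal onset collapse to
their smallest position, so a simultaneous whole-midpiece onset reports a
single focus at position 0 rather than one focus per crossline. Each focus
is labelled proximal/central/distal with the half-open intervals
[0–7), [7–14), [14–21] µm (upper end closed, positions beyond 21 µm clamp
to distal).

## Peak tracking and velocities

`find_membrane_peaks()` smooths the profile (Gaussian, σ = 1 offset step —
the derivative of an unsmoothed sampled profile is too ragged to give
clean sign changes), finds maxima where the spatial derivative crosses
from positive to negative, keeps peaks above 10% prominence, and selects
the outermost pair around the profile midpoint (so membrane peaks win over
interior actin peaks in a four-peak profile). Sub-step positions come from
a log-domain parabola, which is exact for Gaussian peaks. The cell center
is the mean of the two membrane peaks, normalized to 0; all offsets are
re-expressed relative to it, and velocity analysis uses the right-side
distances, mirroring the symmetric geometry. `fit_velocity()` is plain OLS
of distance against time reported in µm/min; the magnitude is the headline
number ("contracting at a rate of …") with the signed slope retained in
the diagnostics.

## Helix geometry from localization tables

`fit_axis_center()` takes the principal axis of the point cloud as the
flagellar axis and refines the transverse center by Gaussian fits to the
coordinate histograms (5 nm bins, `nls`, falling back to the mean if the
fit diverges). A quadratic-bend check rejects ROIs whose transverse drift
exceeds 150 nm RMS — the analysis assumes a straight segment.
`to_cylindrical()` yields $(r, \theta, s)$; 2-D tables (no z) are
supported with $r$ as the projected transverse distance, flagged
`projected`.

**Radial distribution.** `radial_distribution()` histograms $r$ in 10 nm
bins (centers on multiples of the bin width) and reports the parabolically
refined argmax as $R$. Raw counts are used, matching the published
convention for this quantity; a $1/r$ Jacobian-corrected variant is
available (`jacobian = TRUE`) but is not the default since no such
correction is stated in the source procedure.

**Pitch frequency.** For an $n$-start helix each strand obeys
$\theta = 2\pi f_0 s + \phi_k$ with strand phases spaced $2\pi/n$, so
$n\theta - 2\pi (n f_0) s$ is constant across *all* strands regardless of
strand identity. `pitch_frequency()` therefore maximizes the
phase-coherence periodogram
$\left|\sum_j e^{i n \theta_j - 2\pi i \nu s_j}\right|^2$ over $\nu$ and
reports $f_0 = \hat\nu / n$. This extracts the per-strand fundamental
directly — the total projected density of a two-start helix also has a
component at $2/l$, and a naive spectrum of it would report that second
harmonic. Both chiralities are tested (the PCA transverse basis has an
arbitrary handedness), the grid search (resolution ≈ 0.4/extent over
1–10 µm⁻¹) is followed by golden-section refinement, and a minimum
coherence of 0.05 guards against declaring a pitch in phase-random data.
For projected 2-D tables the azimuth collapses to a sign and the
periodogram instead uses the $n$-th power of the signed transverse
coordinate, which oscillates at $n f_0$. An autocorrelation-period
estimate on binned strand coordinates serves as the independent
cross-check in the tests; a 2-D image FFT would measure the same $1/l$
and is not separately implemented.

**Gyres.** `count_gyres()` is `round(extent × f0)`; `analyze_helix()`
measures the axial extent from the data (range of $s$, optionally
quantile-trimmed) and requires at least 5 pitches of extent before
trusting the frequency estimate.

## Pixel statistics

Manders coefficients: $M_1$ is the fraction of channel-1 intensity on
pixels where channel 2 exceeds its threshold, and symmetrically for
$M_2$. Default thresholds are per-channel Otsu on the analyzed region
(explicit thresholds accepted for reproducibility); the Otsu
implementation returns the *midpoint* of the optimal-threshold plateau,
which is otherwise ambiguous for well-separated modes. Absolute M1/M2
values depend on optics and labeling; the tests assert the identities
(1/1, 0/0, the four-pixel hand computation) and the direction of change —
both coefficients rise when the membrane–actin gap shrinks from 0.180 to
0.074 µm.

Number & brightness: per non-overlapping 100-frame segment and pixel,
$N = \mu'^2/\sigma'^2$ and $B = \sigma'^2/\mu'$ after subtracting the
detector offset from the mean and the read-noise variance from the
variance. $B$ is reported as variance-over-mean *without* the $+1$
shot-noise convention; the convention travels in the output metadata so
downstream comparisons are unambiguous. Pixels with nonpositive corrected
moments are masked to `NA` rather than producing infinities.

## Trace dynamics

`order_events()` normalizes each ROI trace, detects rises and falls, and
issues ordering verdicts: calcium rise before membrane rise (the AE
scenario) and nuclear rise < calcium fall < membrane rise (the fusion
scenario). Verdicts are `NA` — undefined, not false — when a required
channel or onset is missing.

`classify_midpiece_pattern()` distinguishes a sustained decrease (below
−3σ for ≥ 20% of the post-stimulus record), a transient increase (above
+3σ with return to within ±2σ), and no change. The σ floor is 1% of
baseline, a realistic indicator noise floor that also makes noise-free
traces classify sensibly. The classifier labels trace *shapes* only; in
the fusion setting a fluorescence decrease cannot distinguish a true
calcium drop from dye dilution into the oocyte, and the package makes no
claim either way.

`beat_frequency()` mean-subtracts, Hann-windows, and Fourier-transforms an
orientation series; the dominant non-DC peak is accepted only if Fisher's
g statistic (largest periodogram ordinate over the sum) is significant at
α = 0.01, so white noise and constant series report "no dominant beat".
The spectral resolution fps/N is reported alongside. Motility arrest
appears in `beat_frequency_profile()` as windows losing their significant
peak.

## Problem sizes and reproducibility

All generators take explicit seeds and restore the global RNG state; a
pipeline run under `run_pipeline()` is deterministic given its seed, and
the manifest records checksums of every artifact. The test suite and the
acceptance script use 5×10⁴-point localization tables (seconds per
analysis), 2,000 regression pairs, 9-crossline × ~60–120-frame contraction
renders, and 300–1,000-frame fluctuation stacks — sizes chosen so each
recovery experiment is statistically comfortable at desk scale while the
full suite runs in a few minutes.

## Known limitations

* Midlines are inputs (config or ground truth); there is no interactive
  midline drawing or automatic flagellum segmentation.
* The helix estimators assume a straight ROI; curvature beyond the
  tolerance is rejected rather than corrected.
* Localization fitting, drift correction, and super-resolution
  reconstruction (SRRF/MSSR-style) are upstream tools, consumed not
  reimplemented.
* Group-level hypothesis testing across cells is out of scope; reports
  carry counts and per-cell quantities only.
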