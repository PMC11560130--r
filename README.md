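# midpiece

Quantitative image analysis of the mouse sperm flagellar midpiece during
acrosomal exocytosis (AE) and gamete fusion. The midpiece — the proximal
~21 µm of the flagellum — is wrapped by a double-helical F-actin network
(87 gyres at a 244 nm pitch in the intact cell). During AE the midpiece
contracts, the helix remodels (shorter pitch, smaller radius), and sperm
motility arrests; a calcium transient precedes the membrane-dye rise that
reports the contraction. This package implements the full measurement
pipeline for these phenomena as tested, reusable R functions, driven by a
synthetic-data generator with exported ground truth so every stage is
verifiable without raw imaging data.

It is written for microscopists and quantitative biologists who have
kymograph-ready time-lapse stacks, super-resolved cross-section profiles,
or single-molecule localization tables, and want the published estimators
rather than ad-hoc scripts.

## What it computes

* **Kymographs** — longitudinal (time × arclength) fluorescence kymographs
  from a midline band, and cross-section kymographs from crosslines drawn
  every 2.5 µm; traces normalized as (F − F₀)/F₀ with F₀ the pre-stimulus
  baseline mean; midpiece regions proximal [0–7), central [7–14),
  distal [14–21] µm.
* **Diameter dynamics** — midpiece diameter per position and frame as the
  lag of the secondary autocorrelation maximum of the cross-section
  profile; baseline-normalized diameter kymographs; contraction onsets
  (sustained drop below 1 − threshold) and initiation foci (local onset
  minima with region labels and counts).
* **Peak tracking** — membrane/actin fluorescence peaks at derivative sign
  changes, cell center as the mean of the membrane pair (normalized to 0),
  contraction velocities by OLS of right-peak distance against time
  (µm/min), and the membrane–actin gap.
* **Fluorescence ↔ diameter transform** — the linear model
  y = m·x + b between normalized diameter (x) and normalized membrane-dye
  fluorescence (y), with m = 8.90, b = −8.05, R² = 0.32 as the reference
  parameterization, and the inverse prediction x̂ = (f − b)/m.
* **Helix geometry from localization tables** — axis fit (PCA + Gaussian
  histogram centers), cylindrical transform (r, θ, s), radial
  distribution peak R, pitch frequency f₀ (turns/µm, with pitch
  l = 1/f₀) from a phase-coherence periodogram of the two-start strand
  signal, and gyre count round(L·f₀).
* **Pixel statistics** — Manders colocalization coefficients M1/M2 with
  Otsu or explicit thresholds; number & brightness maps
  (N = µ′²/σ′², B = σ′²/µ′ per 100-frame segment) with sCMOS-style
  offset/read-noise correction and 1 µm² ROI summaries.
* **Trace dynamics** — event onsets (k·σ with hysteresis), cross-channel
  ordering verdicts (calcium before membrane-dye in AE; nuclear dye before
  calcium decrease before membrane-dye in fusion), midpiece calcium
  pattern classes (decrease / transient increase / no change), and
  flagellar beat frequency by windowed Fourier analysis with a Fisher
  g-test for peak significance.
* **Synthetic data** — a parametric midpiece model (tube + two-start
  helix + contraction program + event clock) that renders cross-section
  profiles, wide-field time-lapses, localization tables, fluctuation
  stacks, regression pairs, and ROI traces, each with ground truth
  attached and bit-reproducible under a seed.

## Worked example

Estimate the actin helix geometry from synthetic intact-sperm
localizations, then measure the worked-example contraction velocities:

```r
library(midpiece)

locs <- simulate_localizations(make_geometry(), n_points = 5e4,
                               precision_nm = 15, seed = 1)
analyze_helix(locs)
#> <helix_params> pitch 244.0 nm (f0 4.098 /um), R 300.3 nm, 87 gyres over 21.25 um

mem <- render_peak_motion_profiles(14, channel = "membrane", r0_um = 0.9)
act <- render_peak_motion_profiles(3, channel = "actin", r0_um = 0.72)
csk <- cross_section_kymograph(c(mem$channels, act$channels),
                               positions_um = 0, times_s = mem$times_s,
                               offsets_um = mem$offsets_um)
trk <- track_peaks(csk)
fit_velocity(trk$mem_right_um, trk$time_s)$velocity_um_min   # 14
fit_velocity(trk$actin_right_um, trk$time_s)$velocity_um_min # 3
```

The helix output reads: a per-strand axial period of 244 nm (pitch
frequency 4.10 turns/µm), strand radius 300 nm, and 87 helical turns over
the 21.25 µm measured extent — the intact-midpiece geometry the generator
was asked for. The velocity fits recover the 14 µm/min (membrane) and
3 µm/min (actin) contraction rates of the noise-free kymographs exactly.

## Analysis workflow

The `analysis/` scripts run the whole study on synthetic data and write
tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # inputs + ground truth
Rscript analysis/02_contraction.R       # diameters, onsets, foci, velocities, OLS
Rscript analysis/03_helix.R             # intact vs reacted helix geometry
Rscript analysis/04_pixel_statistics.R  # Manders vs gap, number & brightness
Rscript analysis/05_dynamics.R          # event ordering, patterns, beat frequency
```

`run_pipeline()` offers the same stages behind a single YAML config (see
`inst/extdata/demo_config.yaml`) and writes a checksummed run manifest.

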