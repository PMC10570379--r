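---
title: "Methods: quantitative analysis of shadow images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of shadow images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(shadowimg)
```

Shadow imaging labels the interstitial fluid of living brain tissue so
that all cells appear as dark silhouettes against a bright extracellular
background. This vignette is the package's own account of the models and
procedures it implements, the parameters that matter, what the synthetic
phantoms emulate (and what they do not), and the numerical choices made
where the design was genuinely open.

## Data model

All rasters travel as an `image_stack`: a 5-D array with the axis order
fixed to (t, c, z, y, x) — the ImageJ hyperstack convention — with
singleton axes always materialized, plus a `pixel_geometry` (µm per pixel,
optional µm per plane and seconds per frame). Fixing the axis order once
removes every downstream ambiguity. Coordinates are 0-based and
pixel-centred: physical position = index × pixel size; sub-pixel sampling
uses bilinear interpolation, which reproduces affine intensity fields
exactly (a tested invariant). TIFF I/O stores 32-bit floats with a JSON
geometry sidecar; ImageJ-style resolution metadata is honoured on read
when present.

Per-frame normalization maps the 0.1th percentile of a frame to 0 and the
99.9th to 1 (clipped). Robust percentiles rather than min/max are used
because fractional grey-level thresholds ("above 70%", "below 2% of the
range") are meaningless in the presence of a single hot pixel; the
percentile pair is a parameter (`norm_pct`). A frame with equal
percentiles is set to zero and flagged degenerate rather than erroring.

## Volume-fraction estimation

The ECS volume fraction of a neuropil region is estimated as

$$\mathrm{VF} = \frac{\langle I_R\rangle - b}{I_\mathrm{ECS} - b}$$

with $I_\mathrm{ECS}$ the intensity of pure extracellular fluid and $b$ a
detector background. The estimator needs no segmentation and is
*a priori* independent of spatial resolution: blurring by a unit-sum PSF
conserves the mean of any region large compared to the kernel. Two
reference modes exist: a designated ROI (a perivascular space large
enough to contain the excitation spot — the preferred mode) or the mean
of the brightest 0.1% of pixels (`top_fraction()`), which approximates
pure ECS when no such ROI is available. With noise present the
top-fraction mode is biased upward by the noise tail of the brightest
pixels, which is why the ROI mode is preferred and used by the validation
suite. The background $b$ defaults to 0 — the estimator's literal
formula — with an optional dark-ROI or fixed offset for detectors with a
pedestal; reference regions containing saturated pixels are refused, as
the normalization is only meaningful in the detector's linear range.
Estimates pushed outside [0, 1] by noise are clipped and flagged rather
than dropped.

## Vessel and perivascular-space widths

Across a vessel, a shadow image shows a dark lumen flanked by two bright
perivascular stripes. Because the three features overlap at capillary
scale, the cross-section is fitted *simultaneously* with

$$b + A_L G(x;\mu_L,\sigma_L) + A_R G(x;\mu_R,\sigma_R)
  - A_0 G(x;\mu_0,\sigma_0),$$

all amplitudes constrained non-negative, rather than with three
independent window fits. Widths are reported as FWHM
$= 2\sqrt{2\ln 2}\,\sigma \approx 2.3548\,\sigma$. Starting values come
from deterministic moments (trough at the minimum, width from the
half-depth crossing, flank peaks at the side maxima); the optimizer is
Levenberg–Marquardt with box bounds, with a derivative-free Nelder–Mead
pass as fallback (noise-free profiles can leave the Gauss–Newton model
matrix singular), and reduced models (one flank, trough only) competing on
residual RMSE when the full model does not fit. A flank whose fitted
amplitude falls below 3× the residual standard deviation — or below 2% of
the profile range, which stops arbitrarily small peaks from passing on
noiseless data — is reported missing; this prevents fitting noise as
anatomy. A profile without a significant trough is flagged `no_vessel`. Profiles are averaged over 5 parallel
lines by default to suppress noise.

For the width–diameter correlation, each vessel contributes its lumen
FWHM paired with the *mean* of its available PVS sides; treating each
side as its own pair is available as an option (`pairing = "sides"`),
since field data typically report about twice as many PVS measurements as
vessels without stating the pairing.

## Phagocytic triage

The lesion pipeline operates on two aligned channels. The shadow channel
is median-filtered (disk of radius 4 px, the convention of the common GUI
tools), normalized, and inverted; intact (dye-negative) material is then
pixels strictly above 0.70 of the range and lysed (dye-positive) material
strictly below 0.02. The two masks are disjoint by construction.

Phagocytic cups are ring-shaped engulfment structures at microglial
process tips; in the binarized EGFP channel their interiors are *holes*.
The detector binarizes each frame (per-frame Otsu by default; a fixed
threshold is available and used for phantoms), fills holes, subtracts the
original binary image — leaving exactly the enclosed background pixels,
an equivalence tested against an independent flood-fill-from-border
oracle — and groups hole pixels over (x, y, t) with 26-connectivity.
Components are kept when the per-frame equivalent diameter lies in
[3, 12] µm (centred on the typical ~6 µm cup) and the mean circularity
$4\pi A/P^2$ is at least 0.6; retained cups are ranked by circularity.
The source procedure states no numeric gates, so all three are declared
parameters with these defaults. Pixel-count perimeters make the
circularity of a discretized disk slightly exceed 1; values are capped at
1.05.

A cup is positive for a tissue state in a frame when the *median* of the
binary mask over its interior is non-zero — a strict majority rule; over
its lifetime a cup is lysed, intact, both (positive for both states in
the same or different frames) or empty. The cup interior is the hole
region itself, not the surrounding ring. Enrichment statistics compare
the lesion-area fractions of each state ("In ROI") with the fraction of
cups positive for it ("In PC"), averaged over frames.

The automatic lesion ROI (closing of lysed ∪ newly-dark pixels relative
to a baseline-frame union) is a fallback; an expert-drawn ROI overrides
it.

## Motility metrics

For a tracked process tip, cumulative distance sums frame-to-frame
displacements from the first frame up to arrival — the first frame within
2 µm of the lesion point (the lesion spot is of that scale; the radius is
a parameter). Mean velocity averages the frame-to-frame speeds between
listed frames 3–7 (1-based, i.e. the displacements 3→4 … 6→7), the early
linear portion of a trajectory; the window counts from the first tracked
frame and is parameterized. Path class (through neuropil vs around cell
bodies) is decided by whether the straight baseline→lesion segment
intersects any dark connected component of equivalent diameter ≥ 5 µm in
the baseline shadow frame.

## The phantom generators

Every pipeline is validated by parameter recovery on seeded synthetic
data, because the study's raw images are available only on request. The
generators' defaults *are* the study conditions: cortical ECS volume
fraction 0.23; capillary lumen FWHM 3.7 ± 1.0 µm flanked by 0.58 µm
perivascular stripes with width coupling calibrated so the population
Pearson r is 0.838; 130 phagocytic cups of ~6 ± 1 µm diameter with
content classes drawn at 63.1/30.8/6.1% (lysed/intact/both); process
cohorts of 29 neuropil-class tips (0.07 µm/s over 17.1 µm) and 14
cell-body-class tips (0.12 µm/s over 28.1 µm) at one frame per 20 s; a
dye-clearance drop of 47.5% between 1 h and 4 h; 170 nm beads imaged at a
212 nm lateral PSF. Image formation is Gaussian-PSF convolution plus
Poisson shot noise at a configurable photon count and Gaussian read
noise — the minimal realistic model for photon-counting detectors; no
scattering, aberrations or motion artefacts are simulated, so passing
tests demonstrate correctness of the *measurement* procedures, not
robustness to every degradation of real tissue data.

Numerical and design choices worth recording:

- **Circular (wrap-around) convolution boundary.** A unit-sum kernel then
  conserves the image mean *exactly*, which underpins both the
  mean-conservation invariant and the resolution-independence of the VF
  estimator. Mirror-style boundaries do not conserve the mean (a kernel
  mass reflected at an edge double-counts interior pixels), so wrap-around
  is used throughout.
- **Image-domain widths.** Vessel, PVS and bead structures are specified
  by their *apparent* (post-blur) FWHM and rendered directly as Gaussian
  cross-sections, because the corresponding field measurements are
  geometric line-profile widths with no deconvolution; the printed widths
  are then directly recoverable. Physical-width structures blurred by a
  separate PSF are used for the quadrature property
  ($\sqrt{a^2 + b^2}$) tests.
- **One annulus per vessel.** Both PVS sides of a vessel share one
  ground-truth width; with the mean-of-sides pairing rule this keeps the
  closed-form population correlation
  $r = b\sigma_D/\sqrt{b^2\sigma_D^2 + \sigma_\varepsilon^2}$ exact.
  Independent per-side noise would shrink the effective noise variance
  under averaging and decouple the generator calibration from the
  closed form.
- **Field scales per modality.** The neuropil (VF) phantom uses 512² px at
  0.16 µm with a 0.32 µm PSF (in vivo two-photon conditions); the vessel
  phantom renders each capillary in its own 176² px tile at 0.08 µm so
  that sub-micron PVS widths are sampled well above Nyquist (bilinear
  interpolation broadens a 0.58 µm Gaussian by ~3% at 0.16 µm pixels but
  <1% at 0.08 µm); the lesion series uses 768² px at 0.08 µm with a
  0.212 µm PSF (confocal lesion-movie conditions) over 24 frames — at
  coarser sampling the median-filter/PSF rim around a cup's dark ring
  consumes a large fraction of the interior and corrupts the majority
  rule. The lesion channel uses a photon peak of 2000: the dye-positive
  band is only 2% of the grey range, so the post-median-filter shot-noise
  sd must sit well below it, as it does in practice for bright confocal
  movies.
- **Trajectory semantics.** The configured path length is defined as the
  ground-truth cumulative distance at arrival: tips start at distance
  (path length + arrival radius) from the lesion and the final approach
  step is truncated to land exactly on the arrival radius, so the
  noiseless measured cumulative distance equals the configured value and
  jitter only adds the expected small positive bias (~1% at 0.1 µm jitter
  against 1.4 µm steps).
- **Exact-counts switch.** Cup content classes are drawn multinomially by
  default; `exact_counts = TRUE` forces the largest-remainder integer
  split (82/40/8 at n = 130), which deterministic recovery checks use.
- **Neuropil grain and sampling design.** Packed cross-sections are
  0.4–2 µm ellipses (log-uniform): the VF regions are neuropil — fine
  neurites, not somata — and this grain reproduces the ROI-to-ROI
  dispersion reported for 10 µm regions (SEM ≈ 0.7 percentage points over
  36 ROIs); coarser structures would make 10 µm ROIs wildly
  heterogeneous. Ellipse centres are drawn from a domain extended by the
  ellipse radius so coverage is stationary up to the field border
  (confining centres to the field leaves a brighter rim and biases the
  interior dark). The validation protocol pools 9 non-overlapping ROIs
  from each of 4 independently generated fields — 36 ROIs from 4
  "animals", the same design as the field data it emulates — which keeps
  the sampling error of the group mean below one percentage point.
- **Plateau handling.** The neuropil phantom reserves a pure-ECS rectangle
  (side ≥ 3× the PSF FWHM) with a cell-free margin of 2× the PSF FWHM so
  that its interior stays exactly at the pure-ECS level after blurring;
  the achieved ECS fraction is reported over the region outside this
  plateau, which is also where validation ROIs are placed (drawn
  independently, so they may overlap — each is an unbiased sample either
  way).
- **Degenerate inputs.** Constant frames normalize to zero with a flag;
  constant profiles refuse to fit; a blank bead field returns an empty
  table rather than an error; trajectories shorter than 8 frames refuse
  the velocity window.

Problem sizes in the test-suite were chosen to keep the whole validation
run at a few minutes on one CPU: unit tests use reduced fields
(256–320 px, ≤ 10 cups), while the acceptance checks run the full
study-scale conditions (512² VF field with 36 ROIs, 500 vessels, 130-cup
lesion series across five seeds, 43 trajectories, 50 beads).

## Known limitations

- The PSF is Gaussian and lateral-only in the 2D generators; no Airy or
  vectorial models, no axial fitting beyond reusing the 1D profile fit.
- The SNR of a time series is defined here as (profile max − min) /
  sd(background ROI); the field literature often leaves SNR undefined, so
  this is a documented stand-in.
- Blebbing/dysmorphic intact structures have no quantitative morphology
  in the source material; the lesion phantom renders them as dark
  ellipses — a modelling choice.
- Vessel axes are user-supplied polylines (phantoms emit their own); no
  automatic vessel tracing is attempted on real data.
- Tip trajectories are inputs (or phantom outputs); the package does not
  detect or track tips in raw EGFP movies.
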