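# shadowimg

Quantitative image analysis for **shadow imaging** of living brain tissue:
fluorescence microscopy in which the *interstitial fluid* is labelled, so
that every membrane-enclosed cell appears as a dark silhouette against a
bright extracellular background. A single inverted-contrast stack carries
far more anatomical context than sparse positive labelling, and several
quantities of high physiological interest become directly measurable.
`shadowimg` implements those measurements for R users working with
confocal, light-sheet or two-photon shadow stacks:

- **Extracellular-space (ECS) volume fraction.** For a neuropil region R
  with pure-ECS reference intensity `I_ECS`,

  `VF = (mean(I_R) - background) / (I_ECS - background)`

  Because convolution with a unit-sum point-spread function conserves local
  means, this estimator is independent of the microscope's spatial
  resolution; no segmentation is needed.
- **Perivascular-space (PVS) and vessel-lumen widths.** Line profiles laid
  orthogonally across a vessel are fitted with a composite model
  `baseline + A_L G(mu_L, s_L) + A_R G(mu_R, s_R) - A_0 G(mu_0, s_0)`
  (two perivascular peaks flanking one lumen trough, fitted
  simultaneously); widths are reported as FWHM = 2.3548 sigma, and the
  Pearson correlation between lumen diameter and PVS width is computed
  across vessels.
- **Microglial phagocytic triage.** In two-channel lesion time series
  (EGFP microglia + shadow channel), phagocytic cups are detected as
  enclosed holes of the binarized EGFP image (fill-holes minus original),
  gated by size and circularity, and their contents are classified from
  the thresholded shadow channel: pixels of the inverted image above 70%
  of the grey range are intact (dye-negative) material, below 2% lysed
  (dye-positive); a cup is positive for a state when the majority
  (median) of its interior carries it.
- **Process motility.** Cumulative distance to lesion arrival and mean
  velocity over the early (frames 3–7) window for tracked microglial
  process tips.
- **Supporting tools.** Robust per-frame normalization, Gaussian peak and
  trough FWHM fitting, bead-based resolution measurement, SNR time
  courses, dye-clearance drop, and ΔF/F traces.

Because the underlying study's raw images are not publicly deposited, the
package ships a first-class, fully seeded **phantom generator**
(`phantom_config()`, `make_neuropil_phantom()`, `make_vessel_phantom()`,
`make_lesion_series()`, `make_trajectories()`, `make_clearance_series()`,
`make_bead_field()`) whose defaults are calibrated to the study's reported
conditions and which emits complete ground truth for every structure, so
each pipeline stage is validated by parameter recovery.

## Worked example

Estimate the ECS volume fraction on a synthetic cortical shadow volume
whose true ECS fraction is 23%:

```r
library(shadowimg)

cfg <- phantom_config(seed = 1)          # 512x512 @ 0.16 um, PSF 0.32 um
ph  <- make_neuropil_phantom(cfg)        # stack + ground truth

pl <- ph$truth$plateau                   # pure-ECS region (y0, x0, y1, x1)
m  <- matrix(FALSE, cfg$ny, cfg$nx)
m[(pl[1] + 5):(pl[3] - 3), (pl[2] + 5):(pl[4] - 3)] <- TRUE
ref <- estimate_pure_ecs_intensity(ph$stack, roi_mask(m, "plateau"))

rois <- random_neuropil_rois(cfg$ny, cfg$nx, 36, round(10 / cfg$dx),
                             avoid = pl, seed = 2)
est <- estimate_vf(ph$stack, rois, ecs_reference = ref)
summarize_vf(est)
#> $mean_pct
#> [1] 22.85113
#> $sem_pct
#> [1] 0.5800316
#> $n
#> [1] 36
```

The group mean (22.9%) recovers the generator's ground truth (23%); the
SEM reflects the spatial heterogeneity of the packed neuropil across
10 × 10 µm ROIs.

Measuring a vessel cross-section:

```r
cfgv <- phantom_config(seed = 3)
phv  <- make_vessel_phantom(cfgv)        # 500 capillaries, ground truth
m    <- measure_vessels(phv$stack, phv$truth$axes,
                        frames = phv$truth$vessels$frame)
mean(m$lumen_fwhm_um)                    #> 3.761169
pvs_vessel_correlation(m)
#> Pearson r = 0.845, p = 2.91e-137, n = 500
```

A command-line wrapper is available at `exec/shadowimg`
(`shadowimg simulate --preset neuropil --seed 1 --out dir/`, plus `vf`,
`vessels`, `triage`, `track`, `beads`, `profile`, `clearance` commands
operating on TIFF/CSV inputs).

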