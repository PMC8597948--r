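# probeloc

Anatomical localization of every recording site of a linear
electrophysiology probe (Neuropixels-class) in a standardized brain
coordinate system.

Chronic and acute silicon-probe recordings span many brain areas on a
single shank; attributing each site to an anatomical compartment requires
reconstructing the probe track from histology, registering the subject
brain to a reference template, and correcting residual depth uncertainty
with electrophysiological landmarks. `probeloc` implements that workflow
end to end, plus the groundtruth analysis that measures how accurate the
result is.

## What it does

- **Volumes** — `read_volume()` / `write_volume()` for TIFF stacks and
  NRRD with mandatory voxel-spacing metadata; `downsample_volume()`
  (block-mean); annotation volumes with region tables and nearest-voxel
  `lookup_region()`.
- **Warping** — 3D thin-plate-spline fits to manual landmark pairs
  (`fit_tps()`, kernel `U(r) = r`), exact at the landmarks, composable
  across spaces (`transform_chain()`), approximate inversion
  (`invert_transform()`), pull-back volume resampling (`warp_volume()`),
  and worst-first held-out residuals (`landmark_residuals()`) to guide
  iterative landmark placement.
- **Tracks** — arc-length parametrized probe tracks from annotated dye
  centerlines (`build_track()`), projection between spaces
  (`project_track()`), and a tip-depth audit against the micromanipulator
  reading (`tip_vs_manipulator()`).
- **Electrodes** — Neuropixels 1.0 geometry (960 sites, banks of
  384/384/192, 20 µm row pitch), placement from the dye tip
  (`place_from_tip()`), piecewise-linear anchoring to
  electrophysiological landmarks (`anchor_electrodes()`,
  `scaling_factors()`), and atlas region assignment (`assign_regions()`).
  A site at shank depth `d` between anchors `(d_k, s_k)`, `(d_k+1, s_k+1)`
  is placed at `s = s_k + (d − d_k)(s_k+1 − s_k)/(d_k+1 − d_k)`; beyond the
  anchor range the nearest factor extrapolates.
- **Ephys features** — median offset removal, common average referencing,
  zero-phase AP/LFP band split (300–5000 Hz @ native rate; < 300 Hz @
  2.5 kHz), −50 µV multiunit threshold detection with 1 ms dead time,
  spike-rate maps (10 s × 20 µm bins), per-depth rate/amplitude/LFP-power
  profiles, automatic brain-surface detection, and stimulus-evoked
  profiles with PSTHs.
- **Groundtruth** — fluorescence intensity along localized electrodes,
  multi-term Gaussian fits (`fit_multigauss()`), greedy peak matching,
  per-penetration accuracy summaries (mean ± SD of |Δpeak| in mm) and a
  paired t comparison between placement spaces.
- **Synthetic phantom** — `make_phantom()` builds a complete miniature
  experiment (layered toy atlas, smooth invertible deformations into an
  enlarged atlas space and a near-undistorted template space, rendered dye
  tracks, projection blobs, region-dependent spiking with evoked
  responses, jittered landmarks/anchors) with exact ground truth,
  deterministic under a seed. `phantom_preset()` provides `"exact"`,
  `"realistic"` and `"hard"` study conditions.

## Worked example

Localize one phantom penetration and assess accuracy over the bundle:

```r
library(probeloc)

spec <- phantom_spec(dims = c(60, 60, 90), spacing_um = c(40, 40, 40),
                     insertion_depth_um = c(1400, 1800),
                     anchor_depths_um = c(0, 1000),
                     blob_depths_um = c(600, 1200),
                     n_penetrations = 4, n_landmarks = 120, seed = 11)
bundle <- make_phantom(spec)

loc <- localize_penetration(bundle, 1, space = "MRI3D")
loc$localization
#> <electrode_localization> 384 sites on 'pen01' in MRI3D (method: anchored)
loc$localization$region_runs[, c("acronym", "from_depth_um", "to_depth_um")]
#>   acronym from_depth_um to_depth_um
#> 1     HPC             0         220
#> 2      WM           240         420
#> 3     CTX           440        1500
#> 4     out          1520        3820
sprintf("tip depth vs manipulator: %+.3f mm", loc$tip_vs_manipulator_mm)
#> [1] "tip depth vs manipulator: +0.029 mm"

groundtruth_assessment(bundle, space = "MRI3D")$accuracy
#> localization accuracy: 0.029 +/- 0.014 mm (mean +/- SD, n = 4)
```

Reading from the tip upward, the probe passes from the hippocampus-like
block through the white-matter band into cortex and exits the brain at
1.5 mm shank depth — the colored-bar summary a probe figure would show.
The accuracy line compares, per penetration, the Gaussian-fitted peak of
fluorescence sampled along the *localized* electrodes against the peak of
stimulus-evoked multiunit activity: 29 µm mean error on this small
phantom.

A command-line front end over the same functions lives in
`inst/cli/probeloc.R` (`phantom`, `localize`, `groundtruth` subcommands).

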