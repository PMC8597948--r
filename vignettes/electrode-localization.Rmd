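---
title: "Localizing linear-probe electrodes in standardized brain coordinates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing linear-probe electrodes in standardized brain coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Silicon probes of the Neuropixels class record from up to 960 sites spread
over a 9.6 mm shank, so a single penetration crosses many brain areas.
Interpreting those recordings requires knowing, for every site, which
anatomical compartment it sat in — expressed in a standardized coordinate
system so that penetrations can be compared across animals and laboratories.
`probeloc` implements a complete reconstruction workflow:

1. **Track reconstruction.** The probe is painted with a lipophilic dye
   before insertion; after clearing and whole-brain imaging, a user marks
   centerline points (roughly every 0.2 mm) on the fluorescent track.
   `build_track()` linearly interpolates these into an arc-length
   parametrized polyline whose last point is the tip estimate.
2. **Landmark warping.** Point correspondences between the subject volume
   and a reference template drive a 3D thin-plate-spline (TPS) fitted by
   `fit_tps()`; `project_track()` carries the track into the template
   space (`apply_transform()`/`transform_chain()` compose maps, e.g.
   subject → atlas → MRI template).
3. **Electrode placement.** `place_from_tip()` lays sites out from the
   track end using the known interelectrode spacing
   (`neuropixels_1_0()` describes the factory geometry).
4. **Electrophysiological anchoring.** Landmarks with recognizable
   electrical signatures — the brain surface (sharp onset of spiking and
   LFP power, `detect_surface()`), white-matter bands, layer boundaries —
   pin specific electrodes to anatomical positions; `anchor_electrodes()`
   rescales the interelectrode spacing piecewise-linearly between anchors
   so anchored electrodes sit exactly at their landmarks.
5. **Region assignment.** `assign_regions()` labels each site through an
   annotation volume (`lookup_region()`), summarizing contiguous runs.

A groundtruth module quantifies accuracy where an independent physiological
readout exists: fluorescent projections (e.g. ChR2-eYFP) produce both an
imaging peak along the probe (`fluorescence_profile()`) and a
photostimulation-evoked multiunit peak (`evoked_profile()`); the distance
between Gaussian-fitted peak positions (`fit_multigauss()`,
`match_peaks()`, `accuracy_summary()`) measures localization error in mm
along the shank.

## Coordinate and orientation conventions

All coordinates are micrometres in (ML, DV, AP) axis order; voxel indices
refer to voxel centres, and voxel ownership is half-open toward increasing
index, so boundary points deterministically belong to the higher-index
voxel. Track arc length is zero at the brain entry and maximal at the tip.
Anchoring arithmetic runs in a from-tip coordinate (distance along the
track measured from the dye-tip end), which makes shank depth and track
offset share an origin; `tipward()` converts entry-based arc length. A
site at shank depth `d` between anchors `(d_k, s_k)` and
`(d_{k+1}, s_{k+1})` receives
`s = s_k + (d - d_k) (s_{k+1} - s_k) / (d_{k+1} - d_k)`; outside the anchor
range the nearest segment's factor extrapolates, and a single anchor uses a
caller-supplied fallback factor (typically the mean factor of sibling
penetrations in the same brain, `scaling_factors()`).

## Thin-plate-spline choices

The radial kernel is `U(r) = r`, the 3D biharmonic spline — the standard
choice in three dimensions; the kernel is a recorded field and `r^3` can be
selected instead. Regularization defaults to `lambda = 0`, i.e. exact
interpolation, matching a manual-landmark workflow where each landmark is
trusted; a positive `lambda` is available for noisy landmark sets. The
linear system is solved densely in centred, scaled coordinates with one
step of iterative refinement, and the evaluator computes control-point
distances per point rather than via the expanded inner-product formula;
both choices exist to keep the landmark interpolation residual far below
1 µm at brain-scale coordinates (a 1000-landmark fit takes well under a
second). Inversion has no closed form for TPS; `invert_transform()` fits
the swapped pairs and is exact only at the landmarks — adequate for
pulling localized sites back into the subject volume, and used that way in
the groundtruth assessment (pointwise pull-back of the ~400 site
coordinates is numerically the same operation as sampling a warped
volume).

## Electrophysiology preprocessing

Raw traces are handled in microvolts (`uV_per_bit` applied up front), so
the −50 µV multiunit threshold is gain independent. Per-channel median
subtraction removes offsets; common average referencing subtracts the
cross-channel median per sample; both are idempotent. The band split uses
zero-phase (forward–backward) order-3 Butterworth filters — corner
frequencies 300 Hz (LFP low-pass, decimated to 2.5 kHz) and 300–5000 Hz
(AP band at the native rate); zero-phase filtering preserves event timing.
Threshold crossings carry a 1 ms per-channel dead time so a single spike
is never double-counted; the event amplitude is the trough within the
dead-time window. LFP power defaults to the mean squared signal over the
full 0–300 Hz band (the sub-band is configurable). Depth bins are centred
on the channel-depth lattice so a channel sitting exactly on the 20 µm
grid maps to its own bin centre — otherwise every binned profile would be
biased by half a bin against the per-site fluorescence profile.

Surface detection is the only automated landmark detector: the
out-of-brain segment has low spiking and LFP power, so the change point of
the per-channel power (or rate) profile is found by a two-segment
within-variance split (each plateau at least 5 channels), the surface
being the first channel above the midpoint of the plateau medians. The
confidence — plateau separation over pooled spread — must exceed 2, else
"no surface transition" is raised. Other landmark signatures (white
matter, ventricles, CA1, the hippocampus–thalamus border) are exposed as
per-depth feature profiles (`depth_profiles()`) for the analyst to match,
mirroring the manual practice; automatic detectors for them are out of
scope.

## Multi-term Gaussian fits and peak matching

Profiles are normalized to [0, 1] before fitting so fluorescence and
evoked counts share amplitude scales. `fit_multigauss()` runs
Levenberg–Marquardt least squares on `sum_k A_k exp(-(x-mu_k)^2 / 2
sigma_k^2) + c` with box constraints (non-negative amplitudes, widths
between half a sample step and two-thirds of the profile range — wider
components are baselines, not peaks). Initial means are the K tallest
local maxima of a lightly smoothed profile, picked greedily with a minimum
mutual separation so two starts never sit on the same bump; starts begin
narrow (broad starts let the optimizer merge neighbouring peaks) and a few
perturbed restarts guard against bad initializations. `K` is chosen by the
analyst from the profile's appearance. Peak matching is greedy
nearest-mean, each peak used once; unmatched peaks are reported but never
enter the accuracy statistic. Each penetration contributes the mean of its
matched |differences| (one value per penetration) before averaging across
penetrations; the summary SD uses the n−1 denominator.

## The synthetic phantom

`make_phantom()` builds a fully self-contained miniature experiment with
known ground truth, deterministic under its seed. The default grid is
200 × 200 × 300 voxels at 20 µm (4 × 4 × 6 mm) — small enough to build in
about two minutes on one CPU, large enough that a 3.4 mm penetration and
its atlas warp behave like the real geometry. The toy brain is a planar
stack: a cortex-like layer (0–1 mm below the surface), a white-matter band
(1–1.2 mm), hippocampus-like (1.2–2.2 mm) and thalamus-like (2.2–3.4 mm)
blocks, brainstem below. Two target spaces exist: an enlarged atlas-like
"CCF" (global scale 1.15 — cleared/averaged templates are systematically
larger than the in vivo brain — plus a 120 µm low-order sinusoidal
perturbation whose displacement components vary along their own axes, so
the local scale along a penetration is nonuniform) and a near-undistorted
"MRI3D" (10 µm perturbation). Both deformations are analytic and
invertible by construction (amplitude small against scale × period keeps
the Jacobian positive), so annotation volumes in each space are labelled
by exact numeric inversion, and ground-truth electrode positions are exact.

Per penetration the phantom renders a Gaussian dye tube (40 µm radial
sigma) with a brighter, smeared tip ball into the subject volume;
annotated centerline points every 200 µm with configurable jitter; a
dye-tip depth error (sigma `tip_smear_um`) that shortens or extends the
visible track, emulating dim or blooming tips; eYFP-like projection blobs
(sigma 150 µm) centred on the true track at 1.6 and 2.8 mm below the
surface; region-dependent Poisson multiunit trains on 192 channels at
20 µm pitch (amplitudes clipped below −50 µV), with a low-noise
out-of-brain segment; and stimulus-evoked events (300 stimuli at 0.2 s
spacing, 8 ms latency, 0.3 ms jitter, peak response probability 0.6 with
a Gaussian depth profile matched to the blob). A short raw 30 kHz
recording of the first penetration exercises the full preprocessing path.
Electrophysiological anchors are the true landmark positions (surface and
the hippocampus–thalamus boundary at 2.2 mm) displaced by the preset's
anchor jitter — emulating manual landmark identification; the
voxelized-annotation crossings of `boundary_positions()` are tested
separately but are not the anchor source here, because their half-voxel
quantization would dominate the noise-free preset's error budget.

Presets fix the study conditions: `"exact"` (all jitters zero and a
pure-affine deformation, so TPS affine reproduction makes the registration
error vanish and any residual is pipeline arithmetic), `"realistic"`
(50 µm landmark jitter, 30 µm anchor jitter, 20 µm track-point jitter,
100 µm tip smear — values a careful experimenter would recognize), and
`"hard"` (all noise doubled). Seventeen penetrations mirror a typical
multi-animal dataset.

What the phantom does *not* emulate: anatomically curved surfaces and
nuclei, tissue dimpling at insertion, probe bending, spike waveform
diversity and sorting, imaging artefacts, or intensity-based registration
error structure. Passing phantom tests therefore demonstrates the
pipeline's arithmetic, its noise propagation and its space-contrast logic,
not performance on any particular real dataset.

## What the end-to-end assessment shows

`groundtruth_assessment()` localizes every penetration in a chosen space,
samples the projection volume along the localized (not the true) sites,
fits both profiles and matches peaks. Under the exact preset the mean
|peak difference| is pipeline arithmetic only and comes out well below
0.01 mm. Under the realistic preset the mean stays below 0.1 mm — the
phantom analogue of sub-0.1 mm localization accuracy. Anchoring directly
in the enlarged atlas space yields a larger mean error than anchoring in
the near-undistorted template space, and the tip-depth audit
(`tip_vs_manipulator()`) shows the corresponding signature: a large
positive histology-minus-manipulator difference in the enlarged space,
a near-zero one in the undistorted space. These are the quantities
`scripts/acceptance.R` recomputes from scratch.

## Numerical and degenerate-input policy

Fewer than 4 or coplanar landmarks, duplicated moving points (< 1 µm
apart) and reversed anchors raise descriptive errors; flat profiles refuse
both surface detection and Gaussian fitting; queries beyond the track tip
extend the terminal segment linearly and are flagged rather than refused,
because dim dye tips under-estimate depth and anchoring must be able to
push electrodes past the visible dye end. Missing voxel spacing in a
volume file is an error — never a silent 1 µm assumption. TIFF stacks
store integer data losslessly as unsigned 16-bit with an offset recorded
in the JSON sidecar; NRRD carries the native numeric type and is the
format for float volumes.
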