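---
title: "Spatial-temporal speckle-variance OCT angiography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-temporal speckle-variance OCT angiography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the signal model

Optical coherence tomography (OCT) produces depth-resolved reflectance
volumes. In coherent imaging, every voxel carries speckle — a granular
interference pattern. In static tissue, speckle is a fixed property of the
scatterer configuration: re-imaging the same position reproduces the same
grain. Where blood flows, the scatterer configuration changes between
exposures, so the speckle *decorrelates*. OCT angiography (OCTA) turns this
nuisance into contrast: the temporal (and, at high scan density, spatial)
statistics of speckle separate perfused vessels from static tissue without
any injected dye.

The approach implemented here works on intensity data alone, in the
*en-face* (C-scan) view. A raw acquisition is a 4D cube indexed
`[x, y, t, z]`: `x` counts A-scans within a B-scan, `y` is depth, `t`
repeats each B-scan (typically 3 times), `z` steps the slow axis. The
processing chain is:

1. **Rigid registration** against bulk motion (respiration ~1 Hz,
   heartbeat ~2.7 Hz in sedated mice), `register_volume()`.
2. **Frame compositing**, `composite_frames()`: reduce `t` by the mean
   (`mu_t`, structure-selective), the standard deviation (`sigma_t`,
   flow-selective), or keep a single frame (fastest, widest field).
3. **Reslice** to en-face order `[x, z, y]`, `reslice_to_enface()` — a pure
   axis permutation, no resampling.
4. **2.5D enhancement**, `enhance_stack()`: six 2D steps applied per
   en-face slice (below).
5. **Projection / metrics**: 60 µm slab projections, color-coded depth
   maps, SNR/CNR reports.

## The six-step en-face enhancement

Per slice (display orientation: rows = slow axis `z`, columns = `x`):

| step | operation | default | purpose |
|------|-----------|---------|---------|
| 2 | `subtract_offset()` | offset 20 a.u. (8-bit) | remove the non-tissue background RMS as a constant; clamped at 0 |
| 3 | `fft_bandpass()` | scales 40 / 3 voxels, horizontal stripe notch | suppress bulk-motion banding and out-of-band structure |
| 4 | `smooth_image()` | Gaussian sigma 2 (or 3D median 5×5×3) | gradient continuity at the capillary scale |
| 5 | `ridge_enhance()` | 9 orientations | oriented peak detection of tubular structures |
| 6 | `median_suppress()` | radius 1 | remove isolated false ridge responses |
| 7 | `rollingball_subtract()` | radius 25 | adaptive removal of slowly varying background |

Step 1 is the composited, resliced input itself; the seven checkpoints are
exportable (`save_steps = TRUE`) for step-wise CNR analysis.

Parameter meanings and why the defaults:

* **Offset 20 a.u.** is the measured non-tissue RMS of the reference
  8-bit system; it is the one parameter expected to need adjustment on
  other systems (`estimate_background_rms()` measures it from the darkest
  decile, or from a user mask).
* **Bandpass 40/3 voxels**: the filter passes structure between 3 and 40
  voxels with Gaussian roll-off (50% attenuation at the stated sizes,
  `a = ln 2` in `exp(-a (s u)^2)`), spanning the 2–40-voxel vessel
  calibre range while rejecting slice-wide banding and single-voxel
  noise. Stripe suppression is a Gaussian notch (width `stripe_sigma = 2`
  frequency bins) along the frequency line of row-constant structure; the
  slice mean (DC) is restored afterwards.
* **Sigma 2 voxels** is the discrete Nyquist scale for ~5 µm capillaries
  at 1.4 µm lateral sampling.
* **9 orientations** at 20° spacing cover 0–180° densely enough that a
  4-voxel-diameter tube is detected at *every* orientation (this is the
  package's printed acceptance claim; the worst-case between-bin loss is
  bounded in the test suite against a 60-orientation bank).
* **Rolling ball radius 25** exceeds the largest modeled vessel diameter
  (20 voxels) so vessels are not flattened, yet is far below the field
  extent so uneven background is removed. The background is the exact
  Sternberg formulation: grayscale opening with a ball structuring
  element, verified against an independently written opening oracle.

## The ridge kernel

The oriented kernel is the least-specified element of the method it
reimplements, so its construction is a documented design choice. The
published attributes are: built from the third derivative of a Gaussian,
truncated with zero padding, carrying a central notch, applied at 9
orientations, and able to detect 4-voxel tubes at all of them.

A pure third-derivative profile `g'''` is an odd function: its correlation
with any symmetric ridge vanishes exactly on the centerline, which would
contradict the detection claim. We therefore *symmetrize* it: the
cross-vessel profile is

```
p(u) = g'''(u + sigma) - g'''(u - sigma)
```

an even, zero-integral profile with a positive central lobe and negative
side lobes — effectively the derivative structure of the Gaussian family
turned into a peak detector while retaining the third-derivative
construction. Along the vessel axis the kernel is Gaussian-tapered (scale
`2 sigma`); the support is a square of half-width
`ceiling(3 sigma) + ceiling(sigma)` (zero padding outside); a strip of
`notch_width = 1` voxel through the centre, running along the vessel axis,
is zeroed; finally a smooth, localized correction field brings the weight
sum to exactly zero. Orientations are produced analytically by rotating
the coordinate frame, not by resampling a master kernel, so the 0° and 90°
kernels are exact transposes.

Responses are combined by the per-pixel maximum over orientations of the
rectified (negative-clipped) correlation; only bright ridges are kept,
since vasculature is hyperintense in en-face OCT. The slice mean is
subtracted before correlation so that a constant image maps to exactly
zero. Max-combination (vs. sum or RMS) is itself a documented choice: it
preserves orientation selectivity and avoids double-counting at crossings.

## Evaluation metrics

* `snr()`: mean intensity on the vessel mask divided by the standard
  deviation on its strict complement.
* `cnr()`: `(mu_s - mu_n) / sqrt(0.5 (sd_s^2 + sd_n^2))` — exactly
  invariant under common affine intensity rescaling, which makes it
  comparable across pipeline steps and compositing methods.
* `build_groundtruth_mask()`: consensus mask from several algorithm
  outputs — min-max normalize, average with equal weight, Gaussian
  low-pass (sigma 2), global Otsu threshold, local adaptive mean
  threshold (window 25). The low-pass/threshold parameters are fixed,
  recorded defaults; the source method describes the stages but not the
  constants.
* Background masks: for SNR the background is the strict inverse of the
  vessel mask. An optional guard ring (2-voxel dilation) exists but is
  off by default for strict fidelity to the definition. Per-plexus CNR
  noise masks contain all non-vessel tissue of the plexus slab —
  including fiber bundles, deliberately, since they are the contaminant
  whose rejection is being measured.

## The synthetic phantom: what it emulates and what it does not

`generate_phantom()` builds a 4D volume with known ground truth:

* **Static tissue**: layered reflectivity (three plexus layers) times a
  *frozen* multiplicative speckle field — fully developed speckle
  (`intensity = mean × Exp(1)`, the standard coherent-imaging law)
  smoothed to a 2-voxel correlation length and renormalized to mean one.
  Frozen means identical in every repeated frame.
* **Flow**: voxels inside flowing vessels redraw their speckle
  independently per frame (the idealized full-decorrelation limit).
* **Fibers**: static, superficial-only bright tubes (nerve-fiber-bundle
  analogue) — the structure that contaminates the superficial plexus.
* **Shadows**: multiplicative attenuation (0.85) below each vessel.
* **Bulk motion**: sinusoidal axial displacement per frame, breathing
  (6 voxels, 1 Hz) plus heartbeat (1.5 voxels, 2.7 Hz), mapped through
  the scan clock. The desk-scale phantom keeps the full-scale 34 s
  volume time so that motion phase advances realistically between
  repeated frames and along the slow axis; shrinking the acquisition
  time with the grid would have made motion invisible.
* **Noise**: additive half-normal noise with RMS 20 (the 8-bit non-tissue
  background level).

Amplitudes not fixed by the modeled system (motion amplitudes, layer
reflectivities 50–60 a.u., vessel/fiber intensities 120/110 a.u., speckle
correlation length 2) were chosen once as physiologically plausible for a
murine retina at ~1.4 µm sampling and are not tuned.

**What a green test does and does not establish.** The phantom
reproduces the *mechanism* (frozen vs. decorrelating speckle, shadowing,
banding) — so green orderings (e.g. stdev > raw > mean per-plexus CNR;
flow-off invisibility) establish that the implementation exploits the
mechanism correctly. It does not reproduce in vivo nuisance statistics:
real static tissue decorrelates slightly (micro-motion, shot noise,
imperfect registration of non-rigid motion), and real backgrounds carry
large-scale uneven reflectivity. Three documented acceptance directions
fail *because* of this idealization, with the measured numbers recorded
in the test suite:

1. The plain speckle-variance baseline sees an unrealistically clean
   background (its only temporal variance is additive noise), so its SNR
   on the phantom exceeds the single-frame pipeline's — the opposite of
   the in vivo ordering.
2. Step 1→2 of the stdev pipeline cannot raise CNR: frozen-world
   background temporal variation (~0.53 × RMS ≈ 10 a.u.) sits entirely
   below the 20 a.u. offset, so vessels lose more than the background
   can give up. Likewise the final rolling-ball step finds an already
   flat background, so it is not the largest CNR increment (the
   bandpass-induced CNR *decrease*, which is reported for the real data
   too, is reproduced).
3. For the same reason the pipeline's CNR gain over the composited input
   is ~1.2× (strictly monotone, but not the 2× expected of noisy
   in vivo input).

These three assertions are left red in `test-acceptance.R` deliberately,
with this analysis as their documentation; weakening the phantom's stated
frozen-speckle world to pass them would have tested a different (and less
falsifiable) claim.

## Numerical choices

* All processing is double precision; quantization only on export.
* Convolution boundary handling: reflect padding everywhere (compiled
  kernels); Fourier steps are cyclic by nature.
* Standard deviation compositing uses the sample convention (divisor
  `t - 1`); the speckle-variance baseline is pinned to the population
  convention; both are switchable.
* Registration: translation via the Fourier cross-correlation peak with
  3-point parabolic sub-voxel refinement; sub-voxel application by
  bilinear interpolation with zero fill; optional small-angle rotation
  grid search (off by default). Constant frames yield an identity
  transform with a warning.
* Rolling-ball border handling: structuring-element support clipped to
  the image for both erosion and dilation, which keeps the background
  below the image everywhere.
* Phase variance measures the second moment (about zero) of
  bulk-corrected, wrapped inter-frame phase differences: after median
  bulk correction the expected static difference is zero, and the second
  moment stays informative for `t = 2`.
* `build_groundtruth_mask()` is only *approximately* idempotent on its own
  binary output: the Gaussian low-pass erodes up to one boundary voxel of
  thin structures per pass (Dice ~0.9 against itself on the phantom).
  Exact idempotence is unattainable for any builder that includes a
  low-pass stage; the test suite asserts the approximate version.
* TIFF interchange is a deliberately minimal baseline dialect
  (uncompressed, 8/16-bit unsigned or 32-bit float, 1–2 samples/pixel,
  both byte orders read) because no TIFF reader exists in the supported
  dependency set; it round-trips bit-exactly for integer data and is
  readable by standard tools.

## Known limitations

* No elastic/affine registration, no saccade excision; only rigid
  in-plane motion is modeled and corrected.
* No automatic retinal layer segmentation: slab starts are manual (CLI
  `--slab-start`), plexus regions on real data are user-supplied.
* Phase-based baselines require complex-valued input; intensity-only
  input is rejected rather than approximated.
* The phantom is not an optics simulation: no PSF, no sensitivity
  roll-off, no polarization, and the frozen/full-redraw speckle dichotomy
  is the idealized limit discussed above.
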