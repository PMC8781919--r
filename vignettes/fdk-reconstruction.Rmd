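---
title: "Cone-beam CT reconstruction with fdkrecon: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cone-beam CT reconstruction with fdkrecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the acquisition model, the reconstruction algorithm and its numerical
conventions, the correction methods and their assumptions, what the
synthetic data generator does and does not emulate, and the design choices
made where more than one reasonable realization existed.

## The acquisition model

A laboratory cone-beam CT scanner holds an X-ray point source and a flat
detector fixed while the sample rotates about a vertical axis.  `fdkrecon`
describes this with a `scan_geometry`: source-to-rotation-center distance
SCD, source-to-detector distance SDD (both mm), detector pitch, detector
size `n_v × n_u`, and the ordered list of rotation angles.  Magnification
at the rotation center is SDD/SCD.

Conventions (all self-consistent between the simulator, the filter bank,
the backprojector and the calibration routines — this self-consistency is
what the tests assert):

* Right-handed world frame, rotation axis = +z; angles are object rotation,
  counter-clockwise viewed from +z.
* Detector pixel indices are 0-based with pixel centers at integer
  positions; the central ray nominally pierces column `(n_u−1)/2`, row
  `(n_v−1)/2`.  A miscalibrated rotation axis appears as a horizontal shift
  of the axis image by `axis_offset_px` pixels; a tilted axis as a
  per-slice offset `a + m·k` for tomogram slice index `k`.
* For a world point with beam-frame coordinates `x⊥` (parallel to detector
  rows) and `d` (distance from the rotation-center plane, positive toward
  the source), the detector intersection is `Xp = x⊥·SDD/(SCD−d)`,
  `Yp = z·SDD/(SCD−d)`, and the FDK distance weight is `SCD²/(SCD−d)²`.

Raw detector frames are modeled as
`raw = transmission × flat_field × gain × fluence + dark`, which is what
the normalization stage inverts.

## Pre-processing

**Normalization.** `normalize_projections()` computes
`(raw − dark)/(flat − dark) · C_fl` and then applies one of three fluence
options: *none* (data already fluence-corrected), *roi_fluence* (divide
each projection by the mean of an object-free background ROI — the most
accurate option when free background exists, and the one that exactly
cancels per-projection source jitter), or *flat_mean* (divide by
`mean(flat − dark)`, for projections fully covered by the object).
`C_fl` is `mean(flat − dark)` or, when an external fluence monitor is
available, its per-projection reading minus the mean dark level.  Pixels
with `flat ≤ dark` cannot be normalized; their denominator is floored and
they are expected to be repaired by the defect-pixel stage.  Output is
floored at 1e-6 so the subsequent logarithm `p = −ln I` is always defined;
the floor corresponds to ~14 attenuation lengths, far beyond any real
signal.

**Beam hardening.** A polychromatic beam hardens along the path: the
measured attenuation grows sub-linearly with material thickness, and
homogeneous objects reconstruct darker in the middle (cupping).
`bhc_correct()` applies the standard polynomial linearization
`f(x) = a·x + b·x^c` to the attenuation values.  The coefficients are
empirical; `calibrate_bhc()` fits (a, b) by least squares against known
(measured attenuation, true thickness·μ) pairs over a grid of exponents
`c ∈ [2, 3]`, as one would obtain from a step wedge or a known beam model.

**Defect pixels (MF).** Stuck or dead pixels sit at fixed detector
coordinates while object structure moves between projections.
`find_outlier_mask()` averages the stack pixelwise, median-blurs the
average (default 5×5), and thresholds the z-score of the absolute residual
(default 3σ).  `repair_defects()` replaces masked pixels with the median of
valid neighbors, growing the window when a neighborhood is fully masked.
Defaults (5×5 window, 3σ) are conventional robust-statistics choices; a
perfectly uniform stack yields an empty mask by construction.  Note that a
strong single-column gain error is itself detected as a defect line — which
is desirable in production, but means gain *measurement* experiments must
be run without the repair stage in front.

**Detector gain rings (DLR).** Smooth per-pixel gain drift after flat
acquisition produces concentric rings.  The sensitivity correction matrix
is estimated from detector line ratios: for each horizontally adjacent
pixel pair, the gain ratio is the median over all projections of their
value ratio (the moving object structure averages out; the fixed gain does
not).  Per row, gains are the cumulative product of these ratios.  The
cumulative product also tracks genuine smooth flat-field structure, so it
is high-pass detrended by dividing out a wide **running median** (width
`n_u/8`, odd).  A running median was chosen over a moving average because
it passes narrow gain spikes into the SCM essentially unattenuated (a
moving average clips a single-column spike by ≈ 1/width) while removing the
same smooth trends.  The matrix is normalized to mean 1 and divided out of
every projection.  Limitations: pixel pairs that see the object in most
projections inherit a small bias from the object's median intensity
gradient, so gains under the object shadow are recovered slightly low
(≈ 1.094 for a true 1.10 single-column gain in the validation study); and
the method assumes structure *moves*, so a perfectly centered, azimuthally
symmetric object is the worst case.  The recommended order, enforced by the
pipeline, is MF first, then DLR — stuck pixels would otherwise corrupt the
ratio statistics.

## Weighting, filtering, backprojection

The FDK algorithm weights each projection by the cosine factor
`W(Xp, Yp) = SDD/√(Xp²+Yp²+SDD²)` (with the `Xp` origin shifted by the axis
offset), ramp-filters every detector row, and backprojects with the
distance weight.

**Discrete kernels.**  The ramp filter is built in the spatial domain from
its exact discrete forms (Ram-Lak; Shepp-Logan with its built-in smoothing)
rather than by sampling `|ω|` in the frequency domain: the discrete forms
have the correct band-limited DC behaviour (tap sums telescope to 0 as the
support grows — the package asserts |Σtaps| < 1e-4 at N = 2048).  The
default half-length N equals the row length so the kernel support covers
the whole row.

**Convolution.**  Rows are convolved acyclically: both operands are
zero-padded to at least `N_f + N_p − 1` samples (rounded up to a fast FFT
size), multiplied in the frequency domain, and the result is cropped
centered on tap n = 0.  This is exactly equal (to ~1e-15) to direct
spatial convolution, which the tests verify against an independent O(N²)
loop.

**Sampling interval Δs.**  The kernels accept any Δs.  The pipeline
default samples the ramp filter at the *demagnified* detector pitch
`pixel_size·SCD/SDD`, i.e. in rotation-center-plane coordinates.  With
this choice, together with the angular normalization below, reconstructed
voxel values land on the absolute scale of attenuation per mm (a filter
sampled at the raw detector pitch differs only by the global factor
SCD/SDD).

**Backprojection.**  Voxel-driven: for every voxel, the filtered
projection is sampled by full-precision bilinear interpolation at the
voxel's detector intersection (coordinates outside the detector contribute
zero), scaled by `SCD²/(SCD−d)²`, and summed over all angles.  The bare
angular sum is normalized by `π/n_proj`: a full turn measures every ray
direction twice, so the effective angular step of the underlying
filtered-backprojection integral over `[0, π)` is `π/n_proj`.  The
validation study recovers the interior of a homogeneous ellipsoid within
0.2% of its true μ at 180 views.

**Chunking.**  The volume is partitioned into z-slabs and the projections
into angle batches, each sized to a memory budget (8 bytes per element);
every voxel's angular sum is accumulated across batches.  Because voxels
are mutually independent and addition is associative, the result is
bitwise independent of the partition — this invariance, asserted at 1e-6
relative tolerance but observed exact, is the correctness contract of the
chunked dataflow, and it is what allows arbitrarily large scans on fixed
memory.  A `(1 slab, 1 batch)` plan is the degenerate in-core case.

## Geometry auto-calibration

**Axis offset (autofocus).**  A wrong rotation-axis offset blurs or
doubles every edge.  `find_axis_offset()` reconstructs one slice (default
central) for each candidate offset on a coarse grid, scores each with
`sharpness_score()` — crop the centered `L×L` window with `L = m·w/2`
(default margin factor m = 0.8), bilateral-filter it (spatial σ 3 px, range
σ 10% of the dynamic range), Sobel, sum of squared gradients — and refines
the argmax by parabolic interpolation through the best triplet, breaking
grid ties toward the smaller |offset|.  An argmax on the range boundary
returns the boundary with a warning.

Two caveats, both inherent to autofocus: the evaluated window must contain
object structure (a featureless slice gives a flat score curve), and
because the window is at most the central half of the slice, objects whose
edges all lie outside it can mislead the score — far-misaligned
reconstructions concentrate artifact gradients near the axis.  The
package's synthetic default phantom is therefore sized to ~55% of the
field of view, which is also the realistic regime (real samples are framed
to fill the detector without clipping, and their structure projects into
the window).  Under these conditions the score curve is sharply peaked at
the true offset and recovery over a ±20 px search is accurate to well
under half a pixel.

**Axis tilt.**  Offsets measured at ≥ 2 slice heights are fitted with
ordinary linear least squares `offset(k) = a + m·k` (`fit_axis_tilt()`,
verified in tests against the explicit 2×2 normal-equation solution);
backprojection then applies the fitted per-slice offset during sampling.
Slope recovery in the end-to-end study (a = 2 px, m = 0.01 px/slice,
five probe slices) is within ~15%, limited by the sub-pixel spacing of the
per-slice offsets relative to the autofocus refinement accuracy.

## The synthetic data generator

`forward_project()` computes exact cone-beam line integrals through
ellipsoid phantoms (closed-form quadratic ray intersection; overlapping
ellipsoids add their μ deltas, so inclusions and voids use negative
deltas).  `inject_artifacts()` then applies, in order: per-pixel gain,
stuck-pixel overwrite, per-projection fluence factors, dark offset.  A
two-energy beam model `T = w₁e^{−k₁p} + w₂e^{−k₂p}` produces genuine
cupping through the full normalization path.  Axis offset and tilt are
injected inside the projector by shifting the detector coordinate frame,
exactly as a misaligned scanner would.  `simulate_scan()` wraps this into
the triple a scanner delivers (projections, flat, dark); the gain table
deliberately corrupts the projections but *not* the flat, emulating
sensitivity drift after flat acquisition — the situation ring corrections
exist for.

What the generator does **not** emulate: photon (Poisson) noise, detector
blur/PSF, scatter, focal-spot size, mechanical wobble.  Passing tests
therefore demonstrate algorithmic correctness — geometry, scaling,
invariances, artifact removal under the stated corruption models — not
robustness to counting noise; tolerances on real data will be wider.

## Numerical choices and degenerate inputs

* Transmission floor 1e-6 before the logarithm; negative attenuation is
  clamped to 0 (with a warning) before fractional-power beam-hardening.
* Ratio denominators below 1e-4 × the stack median are excluded from DLR;
  pixel pairs with < 10% usable projections fall back to ratio 1.
* A constant image scores 0 sharpness; a constant stack yields an empty
  defect mask (the z-score denominator is zero).
* `sd(DI) = 0`, rank-deficient tilt fits, out-of-detector defect
  coordinates, `scd ≥ sdd`, empty angle lists, and too-small memory
  budgets all raise immediate, named errors.
* Reconstruction sizes used in the shipped validation study: 64³ voxels
  from 180 views of 128², with single-slice reconstructions for the
  calibration and ring studies; chosen as the smallest sizes at which all
  geometric effects under test are comfortably resolved.

## Known limitations

* Full-scan (2π) circular trajectory only: no short-scan (Parker)
  weighting, no helical or laminography orbits, no offset-detector mode.
* FDK is exact only in the central plane; cone artifacts grow with cone
  angle, as in any FDK implementation.
* The DLR gain estimate is biased low under the object shadow (see above).
* CPU implementation, vectorized per slab and batch; the chunked dataflow
  is designed so a parallel realization could drop in per-chunk, but none
  is included.
* TIFF is the only projection input format (16-bit unsigned or 32-bit
  float); volumes are written as raw float32 + text sidecar or slice-wise
  float TIFF.
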