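# fdkrecon

Cone-beam computed tomography reconstruction in R: a complete, tested
processing chain from raw detector frames to a calibrated 3-D attenuation
volume, for laboratory micro-CT scanners with a circular source trajectory
and a flat detector.

The package is aimed at people who work with lab-CT or synchrotron
projection data and want a transparent, scriptable reconstruction they can
validate end to end: every stage is an exported function operating on plain
R arrays, and a built-in analytic phantom simulator provides exact ground
truth for all of them.

## What it implements

**Pre-processing.** Flat-field/dark-field normalization

```
I = (I_raw − I_dark) / (I_flat − I_dark) · C_fl
```

with three fluence options (none / background-ROI division / division by
`mean(flat − dark)`), logarithm to attenuation `p = −ln I`, and polynomial
beam-hardening linearization `f(x) = a·x + b·x^c` (c typically in [2, 3])
with a least-squares calibration helper.

**Ring-artifact reduction.** Two complementary methods: defect pixels are
detected by a z-score threshold on the median-blur residual of the
stack-averaged image and repaired by windowed medians (MF), and smooth
per-pixel gain errors are estimated from the median ratio of horizontally
adjacent detector pixels across all projections, accumulated into a
sensitivity correction matrix (SCM) and divided out (DLR).

**FDK filtered backprojection.** Cosine weighting
`W = SDD/√(Xp² + Yp² + SDD²)`, row-wise ramp filtering with discrete
spatial-domain Ram-Lak or Shepp-Logan kernels

```
H_RL(n) = 1/(4Δs²)          n = 0
        = 0                  n even
        = −1/(nπΔs)²         n odd
H_SL(n) = −2 / (π²Δs² (4n² − 1))
```

convolved via FFT with proper acyclic zero-padding, and voxel-driven
backprojection with bilinear detector sampling and the distance weight
`SCD²/(SCD − d)²`.  The volume is processed in z-slabs and projection
batches under a memory budget, so input and output of any size can be
reconstructed; the result is independent of the partition.

**Geometry auto-calibration.** The horizontal rotation-axis offset is found
by an autofocus search (reconstruct one slice over a grid of candidate
offsets, score each with a bilateral-filtered Sobel sharpness measure, take
the argmax with parabolic refinement), and axis tilt by a linear
least-squares fit of per-slice offsets `f(k) = a + m·k`.

**Synthetic ground truth.** An analytic cone-beam projector over ellipsoid
phantoms (exact chord lengths), with injectors for per-pixel gain, stuck
pixels, per-projection fluence jitter, a two-energy beam (cupping), and
axis offset/tilt.

## Worked example

```r
library(fdkrecon)

# a small scanner: magnification 2, 128x128 detector, 180 views
g  <- scan_geometry(scd = 100, sdd = 200, pixel_size = 0.5,
                    n_u = 128, n_v = 128, angles = full_scan_angles(180))
ph <- phantom_spec(list(ellipsoid(c(0, 0, 0), c(5, 5, 5), mu = 0.05)))

att <- forward_project(ph, g)              # exact line integrals
vol <- reconstruct(att, g, volume_shape = c(64, 64, 64))
print(vol)
#> CT volume 64 x 64 x 64, voxel 0.25 mm, range [-0.002125, 0.05564]

vs <- attr(vol, "voxel_size")
xg <- ((0:63) - 31.5) * vs
r2 <- array(outer(outer(xg^2, xg^2, "+"), xg^2, "+"), c(64, 64, 64))
mean(vol[r2 < 4^2])                        # interior of the r = 5 mm sphere
#> [1] 0.04994809
```

The interior mean `0.0499` recovers the true attenuation coefficient
0.05 mm⁻¹ to 0.1%: the chain reconstructs on the absolute scale of
attenuation per mm (ramp filter sampled at the demagnified pitch, angular
normalization π/n_proj).

Reconstruction from files is driven by a flat key-value config
(`run_pipeline("scan.ini")`) or the CLI wrapper
(`inst/cli/ctrecon simulate|preprocess|findcor|findtilt|reconstruct`).

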