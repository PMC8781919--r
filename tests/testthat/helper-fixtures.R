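# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# benchmark-like small geometry: magnification 2, voxel 0.25 mm, 16 mm FOV
geom128 <- function(n_proj = 180L)
  scan_geometry(100, 200, 0.5, 128, 128, full_scan_angles(n_proj))

geom64 <- function(n_proj = 90L)
  scan_geometry(100, 200, 1, 64, 64, full_scan_angles(n_proj))

# centered homogeneous sphere, radius 5 mm, mu 0.05/mm
sphere_phantom <- function(r = 5, mu = 0.05)
  phantom_spec(list(ellipsoid(c(0, 0, 0), c(r, r, r), mu)))

# azimuthally symmetric cylinder for ring/cupping studies
cylinder_phantom <- function(r = 5.5, mu = 0.05, half_height = 14)
  list(ellipsoid(c(0, 0, 0), c(r, r, half_height), mu))

# tall asymmetric phantom with structure at many heights (tilt studies);
# fov_mm is the reconstructed field-of-view edge length
tall_phantom <- function(fov_mm, mu = 0.05) {
  r <- fov_mm / 2
  list(
    ellipsoid(c(0, 0, 0), c(0.34, 0.28, 0.80) * r, mu),
    ellipsoid(c(0.12, 0.055, -0.62) * r, c(0.077, 0.06, 0.12) * r, mu),
    ellipsoid(c(-0.1, -0.066, -0.31) * r, c(0.055, 0.072, 0.12) * r, -0.6 * mu),
    ellipsoid(c(0.08, -0.09, 0) * r, c(0.06, 0.05, 0.12) * r, mu),
    ellipsoid(c(-0.05, 0.1, 0.31) * r, c(0.07, 0.055, 0.12) * r, -0.6 * mu),
    ellipsoid(c(0.1, 0.08, 0.62) * r, c(0.065, 0.06, 0.12) * r, mu))
}

# attenuation stack of the asymmetric default phantom (structure moves with
# angle; used by ring/outlier and axis-offset studies)
fx_asym_att <- function() fx("asym_att", function() {
  g <- geom128()
  forward_project(phantom_spec(default_test_phantom(128 * voxel_size(g))), g)
})

# interior / exterior logical masks for a centered sphere in an n^3 volume
sphere_masks <- function(n, vs, r, inner = 0.8, outer = 1.2) {
  xg <- ((0:(n - 1)) - (n - 1) / 2) * vs
  r2 <- array(outer(outer(xg^2, xg^2, "+"), xg^2, "+"), c(n, n, n))
  list(interior = r2 < (inner * r)^2, exterior = r2 > (outer * r)^2)
}

# independent dense O(N^2) linear convolution (test oracle for filter_rows)
brute_convolve <- function(row, taps) {
  N <- (length(taps) - 1L) %/% 2L
  n <- length(row)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in -N:N) {
      j <- i - k
      if (j >= 1L && j <= n) acc <- acc + taps[k + N + 1L] * row[j]
    }
    out[i] <- acc
  }
  out
}
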