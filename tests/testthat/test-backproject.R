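test_that("bilinear sampling interpolates and zeroes out-of-bounds", {
  img <- matrix(c(1, 3, 2, 4), 2, 2)   # rows y, cols x
  expect_equal(bilinear_sample(img, 0, 0), 1)
  expect_equal(bilinear_sample(img, 1, 1), 4)
  expect_equal(bilinear_sample(img, 0.5, 0.5), 2.5)     # midpoint of 4 pixels
  expect_equal(bilinear_sample(img, -0.5, 0), 0)
  expect_equal(bilinear_sample(img, 0, 1.25), 0)
  # boundary coordinates are inside
  expect_equal(bilinear_sample(img, 1, 0), 2)
  # shape preserved and vectorized
  out <- bilinear_sample(img, matrix(c(0, 1, 0.5, 5), 2, 2),
                         matrix(c(0, 1, 0.5, 0), 2, 2))
  expect_equal(out, matrix(c(1, 4, 2.5, 0), 2, 2))
})

test_that("chunk plans tile their index ranges under the budget", {
  # everything fits: one slab, one batch
  p <- plan_chunks(c(8, 8, 8), 10, c(8, 8), budget_bytes = 1e9)
  expect_length(p$slabs, 1)
  expect_length(p$batches, 1)
  # budget of half the volume while all projections fit: two slabs, one batch
  p2 <- plan_chunks(c(8, 8, 8), 10, c(4, 4), budget_bytes = 8 * 8 * 4 * 8)
  expect_length(p2$slabs, 2)
  expect_length(p2$batches, 1)
  # covering invariants: disjoint, ordered, exact tiling
  p3 <- plan_chunks(c(5, 5, 7), 11, c(6, 6), budget_bytes = 5 * 5 * 3 * 8)
  covered <- unlist(lapply(p3$slabs, function(s) seq.int(s[1], s[2] - 1L)))
  expect_identical(covered, 0:6)
  coveredb <- unlist(lapply(p3$batches, function(b) seq.int(b[1], b[2] - 1L)))
  expect_identical(coveredb, 0:10)
  # too small: need at least one slice and one projection
  expect_error(plan_chunks(c(8, 8, 8), 10, c(8, 8), budget_bytes = 10),
               "budget too small")
})

test_that("a single constant projection contributes its weighted value at the center", {
  g <- geom64(1)
  st <- projection_stack(array(1, c(64, 64, 1)), 0, "filtered")
  vol <- backproject(st, g, chunk_plan(c(3, 3, 1), 1))
  # center voxel: d = 0, weight 1, sample = 1; times pi/n_proj
  expect_equal(vol[2, 2, 1], pi, tolerance = 1e-12)
})

test_that("backprojection is linear in the projections", {
  g <- geom64(8)
  set.seed(9)
  st <- projection_stack(array(rnorm(64 * 64 * 8), c(64, 64, 8)),
                         full_scan_angles(8), "filtered")
  st2 <- projection_stack(unclass(st) * 2.5, proj_angles(st), "filtered")
  v1 <- backproject(st, g, chunk_plan(c(16, 16, 4), 8))
  v2 <- backproject(st2, g, chunk_plan(c(16, 16, 4), 8))
  expect_equal(unclass(v2), 2.5 * unclass(v1), tolerance = 1e-12)
})

test_that("reconstruction is invariant to the chunk partition", {
  g <- geom64(45)
  att <- forward_project(sphere_phantom(r = 4), g)
  w <- apply_cosine_weights(att, g)
  f <- filter_rows(w, make_kernel("ram-lak", 64, delta_s = voxel_size(g)))
  v1 <- backproject(f, g, chunk_plan(c(32, 32, 32), 45, 1, 1))
  v2 <- backproject(f, g, chunk_plan(c(32, 32, 32), 45, 4, 3))
  expect_lt(max(abs(v1 - v2)), 1e-6 * max(abs(v1)))
  # and to the memory-budget planner's partition
  p <- plan_chunks(c(32, 32, 32), 45, c(64, 64), budget_bytes = 32 * 32 * 5 * 8)
  expect_gt(length(p$slabs), 1)
  v3 <- backproject(f, g, p)
  expect_lt(max(abs(v1 - v3)), 1e-6 * max(abs(v1)))
})

test_that("backproject requires filtered input", {
  g <- geom64(4)
  att <- projection_stack(array(1, c(64, 64, 4)), full_scan_angles(4),
                          "attenuation")
  expect_error(backproject(att, g), "expected stage")
})

test_that("a centered sphere round-trips through the full FDK chain", {
  g <- geom64(90)
  mu <- 0.05
  att <- forward_project(sphere_phantom(r = 4, mu = mu), g)
  vol <- reconstruct(att, g, volume_shape = c(48, 48, 48))
  m <- sphere_masks(48, attr(vol, "voxel_size"), 4)
  expect_lt(abs(mean(vol[m$interior]) - mu) / mu, 0.05)
  expect_lt(abs(mean(vol[m$exterior])), 0.05 * mu)
})

test_that("round-trip error decreases with the number of projections", {
  mu <- 0.05
  err <- vapply(c(24, 48, 96), function(np) {
    g <- geom64(np)
    att <- forward_project(sphere_phantom(r = 4, mu = mu), g)
    sl <- reconstruct_slice(att, g, 31, n_xy = 48)
    vs <- voxel_size(g)
    xg <- ((0:47) - 23.5) * vs
    r2 <- outer(xg^2, xg^2, "+")
    truth <- ifelse(r2 < 16, mu, 0)       # streak artifacts count too
    sqrt(mean((sl - truth)^2))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("simulating and correcting the same axis offset matches the aligned scan", {
  g <- geom64(90)
  fov <- 64 * voxel_size(g)
  att0 <- forward_project(phantom_spec(default_test_phantom(fov)), g)
  att3 <- forward_project(phantom_spec(default_test_phantom(fov),
                                       axis_offset_px = 3), g)
  s0 <- reconstruct_slice(att0, g, 31, n_xy = 48)
  g3 <- g; g3$axis_offset_px <- 3
  s3 <- reconstruct_slice(att3, g3, 31, n_xy = 48)
  expect_lt(max(abs(s3 - s0)) / max(abs(s0)), 0.02)
})

test_that("volume container prints and plots without error", {
  v <- ct_volume(array(rnorm(27), c(3, 3, 3)), voxel_size = 0.1)
  expect_output(print(v), "CT volume 3 x 3 x 3")
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp)
  expect_silent(plot(v))
  grDevices::dev.off()
  unlink(tmp)
})
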