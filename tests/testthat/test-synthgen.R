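test_that("the central ray through a centered sphere integrates to 2 r mu", {
  g <- scan_geometry(100, 200, 0.5, 65, 65, 0)    # odd: exact central pixel
  mu <- 0.05; r <- 4
  att <- forward_project(phantom_spec(list(ellipsoid(c(0, 0, 0), c(r, r, r),
                                                     mu))), g)
  expect_equal(att[33, 33, 1], 2 * r * mu, tolerance = 1e-12)
  # corner rays miss the phantom entirely
  expect_equal(att[1, 1, 1], 0)
  expect_equal(att[65, 65, 1], 0)
})

test_that("forward projection is additive over ellipsoid lists", {
  g <- geom64(5)
  e1 <- ellipsoid(c(1, 0, 0), c(3, 2, 2), 0.04)
  e2 <- ellipsoid(c(-2, 1, -1), c(2, 2, 3), 0.03, phi_z = 0.5)
  a1 <- forward_project(phantom_spec(list(e1)), g)
  a2 <- forward_project(phantom_spec(list(e2)), g)
  a12 <- forward_project(phantom_spec(list(e1, e2)), g)
  expect_equal(unclass(a12), unclass(a1) + unclass(a2), tolerance = 1e-12)
})

test_that("the silhouette of a small centered sphere magnifies by SDD/SCD", {
  g <- scan_geometry(100, 200, 0.25, 128, 128, 0)
  r <- 3
  att <- forward_project(phantom_spec(list(ellipsoid(c(0, 0, 0), c(r, r, r),
                                                     0.05))), g)
  sil <- att[, , 1] > 0
  # width in pixels across the central row
  width_px <- sum(sil[64, ])
  expected_px <- 2 * r * (g$sdd / g$scd) / g$pixel_size
  expect_lt(abs(width_px - expected_px) / expected_px, 0.05)
})

test_that("rotated ellipsoids project consistently with their rotation", {
  g <- geom64(1)
  # a prolate ellipsoid rotated by phi projects at angle 0 like the unrotated
  # one viewed at angle -phi
  e <- ellipsoid(c(0, 0, 0), c(5, 2, 2), 0.05, phi_z = 0.6)
  g2 <- geom64(1); g2$angles <- -0.6
  a1 <- forward_project(phantom_spec(list(e)), g)
  a0 <- forward_project(phantom_spec(list(ellipsoid(c(0, 0, 0), c(5, 2, 2),
                                                    0.05))), g2)
  expect_equal(unclass(a1)[, , 1], unclass(a0)[, , 1], tolerance = 1e-10)
})

test_that("artifact injection applies gain, defects, fluence and dark in order", {
  g <- geom64(3)
  ph0 <- phantom_spec(list(ellipsoid(c(0, 0, 0), c(4, 4, 4), 0.05)))
  raw <- forward_project(ph0, g, flat = 1000, emit = "raw")
  # no artifacts: identity
  expect_equal(unclass(inject_artifacts(raw, ph0)), unclass(raw))
  gain <- matrix(1, 64, 64); gain[10, 20] <- 1.3
  ph <- phantom_spec(ph0$ellipsoids, gain = gain,
                     defects = data.frame(v = 5, u = 7, value = 42),
                     fluence = c(1, 1.1, 0.9))
  out <- inject_artifacts(raw, ph, dark_level = 50)
  expect_equal(out[10, 20, 1], raw[10, 20, 1] * 1.3 + 50)
  expect_equal(out[6, 8, 2], 42 * 1.1 + 50)      # stuck, then fluence + dark
  expect_equal(out[30, 30, 3], raw[30, 30, 3] * 0.9 + 50)
  # defects outside the detector are rejected
  bad <- phantom_spec(ph0$ellipsoids, defects = data.frame(v = 64, u = 0,
                                                           value = 1))
  expect_error(inject_artifacts(raw, bad), "outside the detector")
})

test_that("simulated scans normalize back to the analytic attenuation", {
  g <- geom64(6)
  ph <- phantom_spec(list(ellipsoid(c(0, 0, 0), c(4, 4, 4), 0.05)))
  sim <- simulate_scan(ph, g, flat_level = 30000, dark_level = 200,
                       flat_falloff = 0.1)
  att <- to_attenuation(normalize_projections(
    sim$projections,
    normalization_config("flat_mean", dark = sim$dark, flat = sim$flat)))
  truth <- forward_project(ph, g)
  expect_equal(as.numeric(att), as.numeric(truth), tolerance = 1e-6)
})

test_that("a two-energy beam produces sub-linear (cupped) attenuation", {
  g <- geom64(1)
  beam <- list(weights = c(0.5, 0.5), k = c(1, 2))
  ph <- phantom_spec(list(ellipsoid(c(0, 0, 0), c(4, 4, 4), 0.05)),
                     beam = beam)
  raw <- forward_project(ph, g, flat = 1)
  truth <- forward_project(phantom_spec(ph$ellipsoids), g)
  att <- -log(unclass(raw)[, , 1])
  p <- unclass(truth)[, , 1]
  inside <- p > 0.1
  # the effective attenuation coefficient falls with path length: att/p is
  # strictly smaller for the longest paths than for the shortest (cupping)
  ratio <- att[inside] / p[inside]
  expect_lt(cor(ratio, p[inside]), -0.9)
  expect_lt(mean(ratio[p[inside] > quantile(p[inside], 0.9)]),
            mean(ratio[p[inside] < quantile(p[inside], 0.1)]))
  # weights must sum to one
  expect_error(phantom_spec(ph$ellipsoids,
                            beam = list(weights = c(0.6, 0.5), k = c(1, 2))),
               "w1 \\+ w2")
})
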