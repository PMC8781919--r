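mkstack <- function(data, stage = "raw") {
  projection_stack(data, full_scan_angles(dim(data)[3]), stage)
}

test_that("normalization follows the flat/dark correction arithmetic", {
  raw <- mkstack(array(150, c(4, 4, 2)))
  dark <- matrix(50, 4, 4)
  flat <- matrix(250, 4, 4)
  out <- normalize_projections(raw, normalization_config("flat_mean", dark, flat))
  expect_equal(as.numeric(out), rep(0.5, 32))       # (100/200)*200/200
  expect_equal(proj_stage(out), "normalized")

  # full transmission: raw = flat, dark = 0 -> 1 everywhere
  raw2 <- mkstack(array(250, c(4, 4, 2)))
  out2 <- normalize_projections(raw2, normalization_config("flat_mean",
                                                           matrix(0, 4, 4), flat))
  expect_equal(as.numeric(out2), rep(1, 32))
})

test_that("ROI fluence mode maps the background to 1", {
  d <- array(400, c(8, 8, 3))
  d[3:6, 3:6, ] <- 100                       # object in the middle
  raw <- mkstack(d)
  cfg <- normalization_config("roi_fluence", dark = matrix(0, 8, 8),
                              flat = matrix(200, 8, 8), roi = c(0, 0, 2, 2))
  out <- normalize_projections(raw, cfg)
  expect_equal(out[1, 1, 1], 1.0)            # background self-normalizes
  expect_equal(out[4, 4, 1], 0.25)
})

test_that("ROI fluence cancels per-projection fluence jitter end to end", {
  g <- geom64(12)
  ph <- phantom_spec(list(ellipsoid(c(0, 0, 0), c(4, 4, 4), 0.05)),
                     fluence = seq(0.9, 1.1, length.out = 12))
  sim <- simulate_scan(ph, g)
  cfg <- normalization_config("roi_fluence", dark = sim$dark, flat = sim$flat,
                              roi = c(0, 0, 6, 6))
  att <- to_attenuation(normalize_projections(sim$projections, cfg))
  # same scan without jitter
  ph0 <- phantom_spec(list(ellipsoid(c(0, 0, 0), c(4, 4, 4), 0.05)))
  sim0 <- simulate_scan(ph0, g)
  att0 <- to_attenuation(normalize_projections(
    sim0$projections,
    normalization_config("roi_fluence", dark = sim0$dark, flat = sim0$flat,
                         roi = c(0, 0, 6, 6))))
  expect_equal(as.numeric(att), as.numeric(att0), tolerance = 1e-6)
})

test_that("per-projection fluence measurements enter the up-scaling constant", {
  raw <- mkstack(array(150, c(4, 4, 2)))
  dark <- matrix(50, 4, 4); flat <- matrix(250, 4, 4)
  cfg <- normalization_config("none", dark, flat,
                              per_projection_fluence = c(250, 450))
  out <- normalize_projections(raw, cfg)
  # (150-50)/200 * (fluence - mean(dark)) = 0.5 * c(200, 400)
  expect_equal(out[1, 1, 1], 100)
  expect_equal(out[1, 1, 2], 200)
})

test_that("normalization is invariant to joint rescaling of raw-dark and flat-dark", {
  set.seed(4)
  base <- array(runif(4 * 4 * 3, 100, 200), c(4, 4, 3))
  dark <- matrix(10, 4, 4); flat <- matrix(300, 4, 4)
  k <- 3.7
  out1 <- normalize_projections(mkstack(base),
                                normalization_config("flat_mean", dark, flat))
  out2 <- normalize_projections(
    mkstack(array(dark, c(4, 4, 3)) + k * (base - as.vector(dark))),
    normalization_config("flat_mean", dark, dark + k * (flat - dark)))
  expect_equal(as.numeric(out1), as.numeric(out2), tolerance = 1e-12)
})

test_that("unusable references and bad ROIs are rejected", {
  expect_error(normalization_config("flat_mean", dark = matrix(5, 4, 4),
                                    flat = matrix(5, 4, 4)), "unusable")
  expect_error(normalization_config("roi_fluence", roi = c(0, 0, 0, 2)), "roi")
  raw <- mkstack(array(1, c(4, 4, 2)))
  cfg <- normalization_config("roi_fluence", roi = c(3, 3, 4, 4))
  expect_error(normalize_projections(raw, cfg), "ROI")
})

test_that("attenuation conversion is -log with a 1e-6 clamp", {
  st <- mkstack(array(c(1, exp(-2), 1e-6, 0.5), c(2, 2, 1)), "normalized")
  att <- to_attenuation(st)
  expect_equal(att[1, 1, 1], 0)
  expect_equal(att[2, 1, 1], 2)
  expect_equal(att[1, 2, 1], -log(1e-6), tolerance = 1e-9)
  expect_equal(proj_stage(att), "attenuation")
  # a no-object scan maps to attenuation 0 everywhere
  raw <- mkstack(array(250, c(4, 4, 2)))
  flat <- matrix(250, 4, 4)
  att0 <- to_attenuation(normalize_projections(
    raw, normalization_config("flat_mean", matrix(0, 4, 4), flat)))
  expect_equal(as.numeric(att0), rep(0, 32))
})

test_that("beam-hardening polynomial is applied elementwise", {
  st <- mkstack(array(c(0, 1, 2, 0.5), c(2, 2, 1)), "attenuation")
  id <- bhc_correct(st, bhc_params(1, 0, 3))
  expect_equal(as.numeric(id), as.numeric(st))
  out <- bhc_correct(st, bhc_params(1, 1, 3))
  expect_equal(out[1, 2, 1], 2 + 8)               # f(2) = 2 + 2^3
  expect_equal(out[2, 2, 1], 0.5 + 0.125)
  expect_equal(out[1, 1, 1], 0)                   # f(0) = 0 always
  expect_warning(bhc_correct(mkstack(array(-0.1, c(2, 2, 1)), "attenuation"),
                             bhc_params(1, 1, 2.5)), "clamped")
  expect_error(bhc_params(1, 1, 0), "c must be")
})

test_that("bhc calibration linearizes a two-energy transmission curve", {
  p <- seq(0.01, 0.6, length.out = 100)
  x <- -log(0.6 * exp(-p) + 0.4 * exp(-2.5 * p))
  bp <- calibrate_bhc(x, p)
  expect_true(bp$c >= 2 && bp$c <= 3)
  corr <- bp$a * x + bp$b * x^bp$c
  expect_lt(max(abs(corr - p)) / max(p), 0.02)
})

# independent direct implementation of the outlier detection recipe
oracle_outlier_mask <- function(stack, n_sigma = 3, w = 5, h = 5) {
  d <- dim(stack)
  pbar <- apply(stack, c(1, 2), mean)
  mi <- matrix(0, d[1], d[2])
  rw <- (w - 1) / 2; rh <- (h - 1) / 2
  for (v in 1:d[1]) for (u in 1:d[2]) {
    vs <- pmin(pmax((v - rh):(v + rh), 1), d[1])
    us <- pmin(pmax((u - rw):(u + rw), 1), d[2])
    mi[v, u] <- median(pbar[vs, us])
  }
  di <- abs(pbar - mi)
  if (sd(di) == 0) return(matrix(FALSE, d[1], d[2]))
  (di - mean(di)) / sd(di) > n_sigma
}

test_that("outlier mask matches a brute-force implementation on a toy stack", {
  set.seed(11)
  base <- array(100, c(16, 16, 3))
  base[5, 9, ] <- 1100                         # stuck pixel
  st <- mkstack(base)
  mask <- find_outlier_mask(st, outlier_config(3, c(5, 5)))
  expect_identical(mask, oracle_outlier_mask(unclass(st)))
  expect_identical(which(mask), which(unclass(base[, , 1]) > 100))

  # a full defect detector row is flagged too
  base2 <- array(rep(100 + 10 * sin(outer(1:16, 1:16) / 8), 3), c(16, 16, 3))
  base2[7, , ] <- 900
  st2 <- mkstack(base2)
  mask2 <- find_outlier_mask(st2, outlier_config(3, c(5, 5)))
  expect_identical(mask2, oracle_outlier_mask(unclass(st2)))
  expect_true(all(mask2[7, ]))

  # perfectly constant stack -> empty mask (degenerate sd rule)
  expect_false(any(find_outlier_mask(mkstack(array(7, c(16, 16, 2))))))
})

test_that("defect repair replaces masked pixels by valid-neighbor medians", {
  img <- array(5, c(9, 9, 2))
  img[4, 4, ] <- 999
  mask <- matrix(FALSE, 9, 9); mask[4, 4] <- TRUE
  st <- mkstack(img)
  out <- repair_defects(st, mask)
  expect_equal(as.numeric(out), rep(5, length(out)))

  # empty mask is the identity, bit for bit
  out2 <- repair_defects(st, matrix(FALSE, 9, 9))
  expect_identical(unclass(out2), unclass(st))

  # masked vertical line in a horizontal gradient: repaired from row medians
  grad <- array(rep(seq(0, 8), each = 9), c(9, 9, 1))
  maskl <- matrix(FALSE, 9, 9); maskl[, 5] <- TRUE
  stl <- mkstack(grad)
  outl <- repair_defects(stl, maskl, window = 5)
  oracle <- vapply(1:9, function(v) {
    vs <- pmin(pmax((v - 2):(v + 2), 1), 9)
    median(grad[vs, c(3, 4, 6, 7), 1])
  }, numeric(1))
  expect_equal(outl[, 5, 1], oracle)

  # idempotent for a fixed mask
  expect_equal(unclass(repair_defects(outl, maskl, window = 5)),
               unclass(outl))
})

test_that("repair grows the window when a neighborhood is fully masked", {
  img <- array(rep(1:9, each = 9), c(9, 9, 1))
  mask <- matrix(FALSE, 9, 9); mask[4:6, 4:6] <- TRUE
  expect_message(out <- repair_defects(mkstack(img), mask, window = 3), "grown")
  expect_true(all(is.finite(out)))
})

test_that("SCM is all ones for a structureless uniform stack and mean-1 always", {
  st <- mkstack(array(2, c(32, 32, 60)), "normalized")
  scm <- build_scm_dlr(st)
  expect_equal(as.numeric(scm), rep(1, 32 * 32), tolerance = 1e-6)

  set.seed(3)
  g <- matrix(exp(rnorm(32 * 32, 0, 0.02)), 32, 32)
  st2 <- mkstack(unclass(st) * as.vector(g), "normalized")
  scm2 <- build_scm_dlr(st2)
  expect_equal(mean(scm2), 1, tolerance = 1e-6)
})

test_that("dividing by the SCM inverts an injected gain", {
  st <- mkstack(array(runif(16 * 16 * 50, 1, 2), c(16, 16, 50)), "normalized")
  g <- matrix(exp(rnorm(256, 0, 0.05)), 16, 16)
  corrupted <- mkstack(unclass(st) * as.vector(g), "normalized")
  scm <- structure(g / mean(g), class = "sensitivity_matrix")
  out <- apply_scm(corrupted, scm)
  expect_equal(as.numeric(out), as.numeric(st) * mean(g), tolerance = 1e-10)
  # identity for an all-ones SCM
  ones <- structure(matrix(1, 16, 16), class = "sensitivity_matrix")
  expect_equal(unclass(apply_scm(st, ones)), unclass(st))
})

test_that("stage tags are enforced along the pipeline", {
  raw <- mkstack(array(1, c(4, 4, 2)))
  expect_error(to_attenuation(raw), "expected stage")
  expect_error(bhc_correct(raw, bhc_params()), "expected stage")
  expect_error(build_scm_dlr(raw, 5), "expected stage")
})
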