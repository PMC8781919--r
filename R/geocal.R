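#' Edge-preserving bilateral filter
#'
#' Smooths noise while keeping edges: each output pixel is a weighted mean of
#' its neighbors with Gaussian weights in both spatial distance and gray
#' value difference.  Used to denoise a tomogram slice before the sharpness
#' score so the score responds to object edges, not to reconstruction noise.
#'
#' @param image Numeric matrix.
#' @param sigma_spatial Spatial Gaussian sigma in pixels; default 3.
#' @param sigma_range Gray-value Gaussian sigma; default 10\% of the image
#'   dynamic range.  A constant image is returned unchanged.
#' @return Filtered matrix, same size.
#' @export
bilateral_filter <- function(image, sigma_spatial = 3, sigma_range = NULL) {
  rng <- diff(range(image))
  if (rng == 0) return(image)
  if (is.null(sigma_range)) sigma_range <- 0.1 * rng
  r <- max(1L, ceiling(2 * sigma_spatial))
  nv <- nrow(image); nu <- ncol(image)
  num <- matrix(0, nv, nu); den <- matrix(0, nv, nu)
  vi <- seq_len(nv); ui <- seq_len(nu)
  for (dv in -r:r) for (du in -r:r) {
    ws <- exp(-(dv^2 + du^2) / (2 * sigma_spatial^2))
    if (ws < 1e-4) next
    v2 <- pmin(pmax(vi + dv, 1L), nv)
    u2 <- pmin(pmax(ui + du, 1L), nu)
    nb <- image[v2, u2]
    w <- ws * exp(-(nb - image)^2 / (2 * sigma_range^2))
    num <- num + w * nb
    den <- den + w
  }
  num / den
}

sobel_gradients <- function(image) {
  nv <- nrow(image); nu <- ncol(image)
  # valid interior region only, 3x3 Sobel
  i <- 2:(nv - 1L); j <- 2:(nu - 1L)
  gx <- (image[i - 1, j + 1] + 2 * image[i, j + 1] + image[i + 1, j + 1]) -
        (image[i - 1, j - 1] + 2 * image[i, j - 1] + image[i + 1, j - 1])
  gy <- (image[i + 1, j - 1] + 2 * image[i + 1, j] + image[i + 1, j + 1]) -
        (image[i - 1, j - 1] + 2 * image[i - 1, j] + image[i - 1, j + 1])
  list(gx = gx, gy = gy)
}

#' Autofocus sharpness score of a tomogram slice
#'
#' Crops a centered L x L processing window with \eqn{L = m w / 2} (w = slice
#' width, m the margin factor), applies edge-preserving bilateral smoothing,
#' takes the 3x3 Sobel derivative, and returns the sum of squared gradient
#' values.  Correctly centered reconstructions have sharp edges and score
#' high; a wrong rotation-axis offset blurs or doubles edges and scores low.
#' The score is invariant to a constant intensity offset.
#'
#' @param slice Square tomogram slice (matrix).
#' @param margin_factor m in (0, 1); fraction of the half-width kept.
#'   Default 0.8.
#' @param sigma_spatial,sigma_range Bilateral filter parameters (see
#'   [bilateral_filter()]).
#' @return Non-negative scalar score.
#' @export
sharpness_score <- function(slice, margin_factor = 0.8, sigma_spatial = 3,
                            sigma_range = NULL) {
  stopifnot(is.matrix(slice))
  if (margin_factor <= 0 || margin_factor >= 1)
    stop("margin_factor must be in (0, 1)")
  w <- min(dim(slice))
  L <- floor(margin_factor * w / 2)
  if (L < 8) stop("processing window too small (L = ", L, " px, need >= 8)")
  cv <- floor(nrow(slice) / 2); cu <- floor(ncol(slice) / 2)
  half <- L %/% 2L
  sub <- slice[(cv - half):(cv - half + L - 1L),
               (cu - half):(cu - half + L - 1L)]
  sm <- bilateral_filter(sub, sigma_spatial, sigma_range)
  g <- sobel_gradients(sm)
  sum(g$gx^2 + g$gy^2)
}

parabolic_vertex <- function(x, y) {
  # vertex of the parabola through 3 points; x equally spaced
  denom <- y[1] - 2 * y[2] + y[3]
  if (denom >= 0) return(x[2])  # not a maximum; keep grid argmax
  x[2] + 0.5 * (x[3] - x[2]) * (y[1] - y[3]) / denom
}

#' Find the rotation-axis offset by autofocus search
#'
#' Reconstructs one tomogram slice (near-central recommended) for each
#' candidate axis offset on a coarse grid, scores each reconstruction with
#' [sharpness_score()], takes the argmax, and refines it by parabolic
#' interpolation through the best score triplet.  Ties on the grid are
#' broken toward the smaller absolute offset.  If the argmax falls on a
#' range boundary a warning is issued and the boundary value returned (the
#' search range was too narrow).
#'
#' The slice must contain object structure: like a camera autofocus, the
#' method fails on featureless images.
#'
#' @param stack A [projection_stack()] at stage \code{attenuation}.
#' @param geometry A [scan_geometry()] (its \code{axis_offset_px} is ignored
#'   and replaced by each candidate).
#' @param lo,hi Search range in pixels.
#' @param step Coarse grid step in pixels; default 1.
#' @param slice_index 0-based tomogram slice; default central.
#' @param refine Parabolic sub-grid refinement; default TRUE.
#' @param margin_factor,sigma_spatial Passed to [sharpness_score()].
#' @return Estimated offset in pixels, with the score table in attribute
#'   \code{"scores"} (data frame with columns \code{offset}, \code{score}).
#' @export
find_axis_offset <- function(stack, geometry, lo = -20, hi = 20, step = 1,
                             slice_index = NULL, refine = TRUE,
                             margin_factor = 0.8, sigma_spatial = 3) {
  check_stage(stack, "attenuation", "find_axis_offset")
  if (lo >= hi) stop("need lo < hi")
  if (step <= 0) stop("need step > 0")
  cands <- seq(lo, hi, by = step)
  scores <- vapply(cands, function(off) {
    g <- geometry
    g$axis_offset_px <- off
    sl <- reconstruct_slice(stack, g, slice_index = slice_index)
    sharpness_score(sl, margin_factor = margin_factor,
                    sigma_spatial = sigma_spatial)
  }, numeric(1))
  best_score <- max(scores)
  ties <- which(scores == best_score)
  best <- ties[which.min(abs(cands[ties]))]
  est <- cands[best]
  if (best == 1L || best == length(cands)) {
    warning("sharpness argmax at search boundary (", est,
            " px); widen the range")
  } else if (refine) {
    est <- parabolic_vertex(cands[(best - 1L):(best + 1L)],
                            scores[(best - 1L):(best + 1L)])
  }
  structure(est, scores = data.frame(offset = cands, score = scores))
}

#' Fit the rotation-axis tilt line by linear least squares
#'
#' Models the per-slice axis offset as \eqn{f(k) = a + m k} over tomogram
#' slice indices k and solves \eqn{\min_C \|f - XC\|^2} with design matrix
#' \eqn{X = [1, k]}.
#'
#' @param positions Slice indices (>= 2 distinct values).
#' @param offsets Measured offsets in pixels, e.g. from [find_axis_offset()]
#'   at several slice heights.
#' @return List with \code{a} (intercept, px), \code{m} (slope, px/slice),
#'   \code{residual_norm}, and \code{fitted}.
#' @export
fit_axis_tilt <- function(positions, offsets) {
  stopifnot(length(positions) == length(offsets), length(positions) >= 2L)
  if (length(unique(positions)) < 2L)
    stop("rank-deficient fit: need at least 2 distinct slice positions")
  X <- cbind(1, as.numeric(positions))
  fit <- stats::lm.fit(X, as.numeric(offsets))
  list(a = unname(fit$coefficients[1L]), m = unname(fit$coefficients[2L]),
       residual_norm = sqrt(sum(fit$residuals^2)),
       fitted = unname(fit$fitted.values))
}

#' Estimate axis tilt from offsets measured at several slice heights
#'
#' Runs [find_axis_offset()] at each requested slice index and fits the
#' offset-vs-slice line with [fit_axis_tilt()].  Install the result into a
#' geometry as \code{axis_tilt = c(a, m)} (with \code{axis_offset_px = 0}) to
#' have backprojection compensate the tilt per slice.
#'
#' @param stack A [projection_stack()] at stage \code{attenuation}.
#' @param geometry A [scan_geometry()].
#' @param slice_indices 0-based tomogram slice indices to measure at.
#' @param ... Passed to [find_axis_offset()] (search range, step, ...).
#' @return The [fit_axis_tilt()] result, plus elements \code{positions} and
#'   \code{offsets} with the raw measurements.
#' @export
estimate_axis_tilt <- function(stack, geometry, slice_indices, ...) {
  stopifnot(length(slice_indices) >= 2L)
  offsets <- vapply(slice_indices, function(k) {
    as.numeric(find_axis_offset(stack, geometry, slice_index = k, ...))
  }, numeric(1))
  fit <- fit_axis_tilt(slice_indices, offsets)
  fit$positions <- slice_indices
  fit$offsets <- offsets
  fit
}
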