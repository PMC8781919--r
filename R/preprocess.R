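#' Normalization configuration
#'
#' Bundles the reference images and the fluence-correction mode for
#' [normalize_projections()].  The raw correction is
#' \deqn{I = \frac{I_{raw} - I_{dark}}{I_{flat} - I_{dark}} \, C_{fl},}
#' where the up-scaling constant \eqn{C_{fl}} is either the mean of
#' \code{flat - dark} or, when a per-projection fluence measurement is
#' available, \eqn{I_{fl,\varphi_i} - \mathrm{mean}(I_{dark})} for each
#' projection.  The mode then selects the final fluence handling:
#' \describe{
#'   \item{\code{none}}{projections are assumed already fluence corrected; no
#'     further division.}
#'   \item{\code{roi_fluence}}{every projection is divided by the mean of an
#'     object-free background ROI, cancelling per-projection source
#'     fluctuations.}
#'   \item{\code{flat_mean}}{every projection is divided by
#'     \code{mean(flat - dark)} (used when no free background is visible).}
#' }
#'
#' @param mode One of \code{"none"}, \code{"roi_fluence"}, \code{"flat_mean"}.
#' @param dark,flat Optional \code{n_v x n_u} reference images.  When both
#'   are omitted the raw stack is taken as already flat-corrected.
#' @param roi Background rectangle \code{c(u0, v0, width, height)} in 0-based
#'   pixels (required for \code{mode = "roi_fluence"}).
#' @param per_projection_fluence Optional numeric vector of per-projection
#'   fluence readings \eqn{I_{fl,\varphi_i}} from an external monitor.
#' @return An object of class \code{"normalization_config"}.
#' @export
normalization_config <- function(mode = c("flat_mean", "roi_fluence", "none"),
                                 dark = NULL, flat = NULL, roi = NULL,
                                 per_projection_fluence = NULL) {
  mode <- match.arg(mode)
  if (xor(is.null(dark), is.null(flat)))
    stop("supply both dark and flat, or neither")
  if (!is.null(flat)) {
    stopifnot(is.matrix(flat), is.matrix(dark),
              all(dim(flat) == dim(dark)))
    dd <- flat - dark
    if (!any(dd > 0)) stop("unusable flat field: flat <= dark everywhere")
  }
  if (mode == "roi_fluence") {
    if (is.null(roi) || length(roi) != 4L || roi[3] < 1 || roi[4] < 1)
      stop("mode 'roi_fluence' needs roi = c(u0, v0, width, height) with positive size")
  }
  structure(list(mode = mode, dark = dark, flat = flat, roi = roi,
                 per_projection_fluence = per_projection_fluence),
            class = "normalization_config")
}

roi_indices <- function(roi, n_v, n_u) {
  u <- seq.int(roi[1] + 1, roi[1] + roi[3])
  v <- seq.int(roi[2] + 1, roi[2] + roi[4])
  if (min(u) < 1 || max(u) > n_u || min(v) < 1 || max(v) > n_v)
    stop("ROI extends outside the detector")
  list(u = u, v = v)
}

#' Flat-field / dark-field normalization with fluence correction
#'
#' Applies dark- and flat-field correction followed by one of three fluence
#' correction options (see [normalization_config()]).  The output is a
#' transmission-like image stack, strictly positive (values are floored at
#' 1e-6), tagged stage \code{normalized}.
#'
#' Detector pixels where \code{flat <= dark} cannot be normalized; their
#' denominator is floored at a small positive fraction of the valid
#' denominators and a warning reports the count (such pixels are expected to
#' be caught by [find_outlier_mask()] and repaired downstream).
#'
#' @param raw A [projection_stack()] at stage \code{raw}.
#' @param cfg A [normalization_config()].
#' @return A [projection_stack()] at stage \code{normalized}.
#' @export
normalize_projections <- function(raw, cfg) {
  check_stage(raw, "raw", "normalize_projections")
  stopifnot(inherits(cfg, "normalization_config"))
  d <- dim(raw)
  n_proj <- d[3L]
  out <- array(as.numeric(raw), d)

  if (!is.null(cfg$flat)) {
    if (!all(dim(cfg$flat) == d[1:2]))
      stop("flat/dark dimensions do not match the projections")
    denom <- cfg$flat - cfg$dark
    bad <- denom <= 0
    if (any(bad)) {
      denom[bad] <- 1e-3 * mean(denom[!bad])
      warning(sum(bad), " pixel(s) with flat <= dark; denominator floored")
    }
    if (!is.null(cfg$per_projection_fluence)) {
      if (length(cfg$per_projection_fluence) != n_proj)
        stop("per_projection_fluence must have one value per projection")
      cfl <- cfg$per_projection_fluence - mean(cfg$dark)
    } else {
      cfl <- rep(mean(cfg$flat - cfg$dark), n_proj)
    }
    for (i in seq_len(n_proj))
      out[, , i] <- (out[, , i] - cfg$dark) / denom * cfl[i]
  }

  if (cfg$mode == "roi_fluence") {
    idx <- roi_indices(cfg$roi, d[1L], d[2L])
    for (i in seq_len(n_proj)) {
      m <- mean(out[idx$v, idx$u, i])
      if (m <= 0) stop("ROI mean not positive in projection ", i,
                       "; ROI must cover open beam")
      out[, , i] <- out[, , i] / m
    }
  } else if (cfg$mode == "flat_mean") {
    if (is.null(cfg$flat))
      stop("mode 'flat_mean' requires flat and dark images")
    out <- out / mean(cfg$flat - cfg$dark)
  }

  out[out < 1e-6] <- 1e-6
  restage(raw, out, "normalized")
}

#' Convert normalized transmission to attenuation line integrals
#'
#' \eqn{p = -\ln(\max(I, \epsilon))} elementwise with \eqn{\epsilon = 10^{-6}};
#' the clamp guards against zero or negative transmission from noise.
#'
#' @param stack A [projection_stack()] at stage \code{normalized}.
#' @return A [projection_stack()] at stage \code{attenuation}.
#' @export
to_attenuation <- function(stack) {
  check_stage(stack, "normalized", "to_attenuation")
  restage(stack, -log(pmax(stack, 1e-6)), "attenuation")
}

#' Beam-hardening correction parameters
#'
#' Coefficients of the polynomial linearization \eqn{f(x) = a x + b x^c}
#' applied to attenuation values: the polychromatic attenuation grows
#' sub-linearly with material thickness, and the \eqn{x^c} term (with
#' \eqn{c} typically in \[2, 3\]) restores linearity, removing cupping.
#'
#' @param a,b,c Empirical coefficients; \code{c} must be positive.
#' @return An object of class \code{"bhc_params"}.
#' @export
bhc_params <- function(a = 1, b = 0, c = 3) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c))
  if (c <= 0) stop("bhc exponent c must be > 0")
  structure(list(a = a, b = b, c = c), class = "bhc_params")
}

#' Polynomial beam-hardening correction
#'
#' Applies \eqn{f(x) = a x + b x^c} elementwise to an attenuation stack.
#' Negative attenuation values (possible from noise) are clamped to 0 first
#' so fractional exponents stay defined; a warning reports the count.
#'
#' @param stack A [projection_stack()] at stage \code{attenuation}.
#' @param params A [bhc_params()].
#' @return The corrected stack, still stage \code{attenuation}.
#' @export
bhc_correct <- function(stack, params) {
  check_stage(stack, "attenuation", "bhc_correct")
  stopifnot(inherits(params, "bhc_params"))
  x <- as.numeric(stack)
  neg <- x < 0
  if (any(neg)) {
    warning(sum(neg), " negative attenuation value(s) clamped to 0 before bhc")
    x[neg] <- 0
  }
  restage(stack, params$a * x + params$b * x^params$c, "attenuation")
}

#' Calibrate beam-hardening coefficients from a transmission model
#'
#' Fits \eqn{f(x) = a x + b x^c} so that the measured polychromatic
#' attenuation \code{x} maps back to the true monochromatic line integral
#' \code{p}: for each candidate exponent \code{c}, coefficients (a, b) are
#' obtained by linear least squares of \code{p} on \code{(x, x^c)}, and the
#' exponent with the smallest residual sum of squares is kept.  The (x, p)
#' pairs typically come from a known beam model or a calibration wedge of the
#' sample material.
#'
#' @param x Measured polychromatic attenuation values.
#' @param p True monochromatic line integrals (same length).
#' @param c_grid Candidate exponents; default a grid over \[2, 3\].
#' @return A [bhc_params()] with the fitted coefficients.
#' @export
calibrate_bhc <- function(x, p, c_grid = seq(2, 3, by = 0.25)) {
  stopifnot(length(x) == length(p), length(x) >= 3L)
  best <- NULL; best_rss <- Inf
  for (cc in c_grid) {
    X <- cbind(x, x^cc)
    fit <- stats::lm.fit(X, p)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- bhc_params(a = fit$coefficients[[1]],
                         b = fit$coefficients[[2]], c = cc)
    }
  }
  best
}

#' Outlier detection configuration
#'
#' @param sigma_multiplier Threshold multiplier n: pixels whose z-score of
#'   the median-residual image exceeds n are flagged.  Default 3.
#' @param window Median-blur window \code{c(w, h)}; odd, >= 3.  Default 5x5.
#' @return An object of class \code{"outlier_config"}.
#' @export
outlier_config <- function(sigma_multiplier = 3, window = c(5L, 5L)) {
  if (length(window) == 1L) window <- rep(window, 2L)
  window <- as.integer(window)
  if (any(window < 3L) || any(window %% 2L == 0L))
    stop("median window dimensions must be odd and >= 3")
  if (sigma_multiplier <= 0) stop("sigma_multiplier must be > 0")
  structure(list(sigma_multiplier = sigma_multiplier, window = window),
            class = "outlier_config")
}

# 2-D median filter with replicated borders.  Window w x h (odd).
median_filter_2d <- function(img, w, h) {
  nv <- nrow(img); nu <- ncol(img)
  rw <- (w - 1L) %/% 2L; rh <- (h - 1L) %/% 2L
  # gather shifted copies (clamped indices) into columns, rowwise median
  shifts <- expand.grid(du = -rw:rw, dv = -rh:rh)
  acc <- matrix(0, nv * nu, nrow(shifts))
  ui <- seq_len(nu); vi <- seq_len(nv)
  for (s in seq_len(nrow(shifts))) {
    u2 <- pmin(pmax(ui + shifts$du[s], 1L), nu)
    v2 <- pmin(pmax(vi + shifts$dv[s], 1L), nv)
    acc[, s] <- as.vector(img[v2, u2])
  }
  matrix(apply(acc, 1L, stats::median), nv, nu)
}

#' Detect defect detector pixels across a projection stack
#'
#' Defect (stuck/dead) pixels sit at fixed detector coordinates while real
#' object structure moves from projection to projection.  The stack is
#' averaged pixelwise, the average is median-blurred, and pixels whose
#' absolute residual has a z-score above the configured threshold are
#' flagged:
#' \preformatted{
#'   P~  = mean over projections
#'   MI  = median_blur(P~, win(w, h))
#'   DI  = |P~ - MI|
#'   z   = (DI - mean(DI)) / sd(DI)
#'   mask = z > sigma_multiplier
#' }
#' A perfectly uniform stack (sd(DI) = 0) yields an empty mask.
#'
#' @param stack A [projection_stack()] (any stage; normally raw), >= 2
#'   projections.
#' @param cfg An [outlier_config()].
#' @return Logical \code{n_v x n_u} matrix; \code{TRUE} marks defect pixels.
#' @export
find_outlier_mask <- function(stack, cfg = outlier_config()) {
  stopifnot(inherits(stack, "projection_stack"), inherits(cfg, "outlier_config"))
  d <- dim(stack)
  if (d[3L] < 2L) stop("need at least 2 projections to detect outliers")
  pbar <- apply(unclass(stack), c(1L, 2L), mean)
  mi <- median_filter_2d(pbar, cfg$window[1L], cfg$window[2L])
  di <- abs(pbar - mi)
  s <- stats::sd(di)
  if (s == 0) return(matrix(FALSE, d[1L], d[2L]))
  z <- (di - mean(di)) / s
  z > cfg$sigma_multiplier
}

#' Repair masked defect pixels by windowed median of valid neighbors
#'
#' For each projection independently, every masked pixel is replaced by the
#' median of the non-masked pixels inside a window centered on it; unmasked
#' pixels are untouched.  If a window contains no valid pixel it is grown by
#' 2 until at least one is found.
#'
#' @param stack A [projection_stack()].
#' @param mask Logical defect mask from [find_outlier_mask()].
#' @param window Odd window size (scalar), default 5.
#' @return The repaired stack, same stage.
#' @export
repair_defects <- function(stack, mask, window = 5L) {
  stopifnot(inherits(stack, "projection_stack"), is.logical(mask))
  d <- dim(stack)
  if (!all(dim(mask) == d[1:2]))
    stop("mask dimensions do not match the detector")
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (!any(mask)) return(stack)
  idx <- which(mask, arr.ind = TRUE)
  out <- unclass(stack)
  nv <- d[1L]; nu <- d[2L]
  grew <- FALSE
  for (k in seq_len(d[3L])) {
    img <- out[, , k]
    rep_vals <- numeric(nrow(idx))
    for (j in seq_len(nrow(idx))) {
      v <- idx[j, 1L]; u <- idx[j, 2L]
      r <- (window - 1L) %/% 2L
      repeat {
        vs <- max(1L, v - r):min(nv, v + r)
        us <- max(1L, u - r):min(nu, u + r)
        valid <- !mask[vs, us]
        if (any(valid)) break
        r <- r + 1L
        grew <- TRUE
      }
      rep_vals[j] <- stats::median(img[vs, us][valid])
    }
    img[idx] <- rep_vals
    out[, , k] <- img
  }
  if (grew) message("repair_defects: window grown around fully masked neighborhoods")
  restage(stack, out)
}

#' Build a detector sensitivity correction matrix from line ratios
#'
#' Ring artifacts come from fixed per-pixel gain errors.  Because object
#' structure moves across projections while detector gain does not, the gain
#' ratio of horizontally adjacent pixels can be estimated as the median over
#' all projections of their value ratio.  Per detector row the pixel gains
#' are then the cumulative product of these ratios, high-pass detrended by
#' dividing out a wide running median (which passes narrow gain spikes into
#' the SCM unattenuated while genuine smooth flat-field trends are preserved
#' rather than "corrected" away), and finally the whole matrix is normalized
#' to mean 1.
#'
#' Ratios whose denominator is below \code{1e-4} times the stack median are
#' excluded; if fewer than 10\% of projections remain usable for a pixel
#' pair, its ratio falls back to 1 and a message is emitted.
#'
#' @param stack A [projection_stack()] at stage \code{normalized}; at least
#'   ~50 projections are recommended for statistical stability.
#' @param detrend_width Running-median width in pixels for the row-wise
#'   detrend; default \code{n_u / 8} rounded up to odd.
#' @return A \code{n_v x n_u} matrix of class \code{"sensitivity_matrix"}:
#'   strictly positive multiplicative gains with mean 1.
#' @export
build_scm_dlr <- function(stack, detrend_width = NULL) {
  check_stage(stack, "normalized", "build_scm_dlr")
  d <- dim(stack)
  nv <- d[1L]; nu <- d[2L]; np <- d[3L]
  if (np < 2L) stop("need a projection stack to estimate gains")
  if (is.null(detrend_width)) {
    detrend_width <- max(3L, as.integer(round(nu / 8)))
    if (detrend_width %% 2L == 0L) detrend_width <- detrend_width + 1L
  }
  x <- unclass(stack)
  floor_val <- 1e-4 * stats::median(x)
  # ratio of column u+1 to column u, per row, median over projections
  ratio <- matrix(1, nv, nu - 1L)
  nlow <- 0L
  for (u in seq_len(nu - 1L)) {
    den <- x[, u, , drop = TRUE]
    num <- x[, u + 1L, , drop = TRUE]
    r <- num / den
    r[den <= floor_val] <- NA_real_
    usable <- rowSums(!is.na(r))
    med <- apply(r, 1L, stats::median, na.rm = TRUE)
    bad <- usable < 0.1 * np
    if (any(bad)) { med[bad] <- 1; nlow <- nlow + sum(bad) }
    ratio[, u] <- med
  }
  if (nlow > 0L)
    message("build_scm_dlr: ", nlow,
            " pixel pair(s) had <10% usable projections; ratio set to 1")
  gains <- t(apply(cbind(1, ratio), 1L, cumprod))
  # high-pass: divide out the smooth row trend
  trend <- t(apply(gains, 1L, function(v)
    stats::runmed(v, detrend_width, endrule = "median")))
  scm <- gains / trend
  scm <- scm / mean(scm)
  structure(scm, class = "sensitivity_matrix")
}

#' Apply a sensitivity correction matrix
#'
#' Divides every projection elementwise by the SCM gains.
#'
#' @param stack A [projection_stack()] at stage \code{normalized}.
#' @param scm A \code{sensitivity_matrix} from [build_scm_dlr()].
#' @return The corrected stack, stage \code{normalized}.
#' @export
apply_scm <- function(stack, scm) {
  check_stage(stack, "normalized", "apply_scm")
  d <- dim(stack)
  if (!all(dim(scm) == d[1:2])) stop("SCM dimensions do not match the detector")
  restage(stack, unclass(stack) / as.vector(unclass(scm)), "normalized")
}

#' Ring-artifact severity of a tomogram slice
#'
#' Mean over radii of the standard deviation of slice values sampled along
#' circles centered on the rotation axis.  Ring artifacts are constant along
#' such circles' complement structure: gain errors show up as large
#' circumferential standard deviation at their radius, so the metric drops
#' when rings are suppressed.
#'
#' @param slice Square tomogram slice (matrix).
#' @param radii Radii in pixels to sample; default 2 to 45\% of the width.
#' @param n_samples Sample points per circle; default 360.
#' @return Non-negative scalar.
#' @export
ring_metric <- function(slice, radii = NULL, n_samples = 360L) {
  n <- nrow(slice)
  stopifnot(ncol(slice) == n)
  cx <- (n - 1) / 2
  if (is.null(radii)) radii <- seq(2, 0.45 * n, by = 1)
  th <- seq(0, 2 * pi, length.out = n_samples + 1L)[seq_len(n_samples)]
  sds <- vapply(radii, function(r) {
    stats::sd(bilinear_sample(slice, cx + r * cos(th), cx + r * sin(th)))
  }, numeric(1))
  mean(sds)
}
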