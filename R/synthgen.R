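#' Attenuating ellipsoid
#'
#' One building block of an analytic phantom: an ellipsoid with center and
#' semi-axes in mm, an additive attenuation delta \eqn{\mu} (mm\eqn{^{-1}}),
#' and an optional rotation about the z axis.  Overlapping ellipsoids add
#' their \eqn{\mu} deltas (the Shepp-Logan composition convention), so holes
#' and inclusions are modeled with negative deltas.
#'
#' @param center Numeric triple, mm.
#' @param semiaxes Numeric triple, mm, all > 0.
#' @param mu Attenuation delta in mm^-1.
#' @param phi_z Rotation about z in radians; default 0.
#' @return A list describing the ellipsoid.
#' @export
ellipsoid <- function(center, semiaxes, mu, phi_z = 0) {
  stopifnot(length(center) == 3L, length(semiaxes) == 3L, all(semiaxes > 0),
            is.finite(mu), is.finite(phi_z))
  list(center = as.numeric(center), semiaxes = as.numeric(semiaxes),
       mu = mu, phi_z = phi_z)
}

#' Phantom specification: ellipsoids plus artifact injection
#'
#' Bundles the analytic ground truth (a list of [ellipsoid()]s) with the
#' artifact model used to emulate real acquisitions: per-pixel detector
#' gain, stuck defect pixels, per-projection fluence jitter, a two-energy
#' polychromatic beam (which produces cupping), and an injected rotation-axis
#' offset/tilt.
#'
#' @param ellipsoids List of [ellipsoid()]s.
#' @param gain Optional \code{n_v x n_u} multiplicative per-pixel gain image
#'   applied to the raw projections (drift relative to the flat field).
#' @param defects Optional data frame with columns \code{v}, \code{u}
#'   (0-based pixel coordinates) and \code{value}: pixels stuck at a constant
#'   raw value in every projection.
#' @param fluence Optional per-projection multiplicative fluence factors.
#' @param beam Optional two-energy beam: list with \code{weights}
#'   \eqn{(w_1, w_2)} summing to 1 and \code{k} \eqn{(k_1, k_2)}, per-energy
#'   multipliers of the monochromatic line integral; transmission is
#'   \eqn{w_1 e^{-k_1 p} + w_2 e^{-k_2 p}}.
#' @param axis_offset_px Injected horizontal rotation-axis offset in pixels.
#' @param axis_tilt Injected tilt \code{c(a, m)}: extra offset a + m*row
#'   (pixels) at detector row index row.
#' @return An object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(ellipsoids, gain = NULL, defects = NULL,
                         fluence = NULL, beam = NULL,
                         axis_offset_px = 0, axis_tilt = c(0, 0)) {
  stopifnot(is.list(ellipsoids), length(ellipsoids) >= 0L)
  if (!is.null(beam)) {
    stopifnot(length(beam$weights) == 2L, length(beam$k) == 2L,
              all(beam$weights >= 0))
    if (abs(sum(beam$weights) - 1) > 1e-9)
      stop("beam weights w1 + w2 must equal 1")
  }
  if (!is.null(defects))
    stopifnot(all(c("v", "u", "value") %in% names(defects)))
  structure(list(ellipsoids = ellipsoids, gain = gain, defects = defects,
                 fluence = fluence, beam = beam,
                 axis_offset_px = as.numeric(axis_offset_px),
                 axis_tilt = as.numeric(axis_tilt)),
            class = "phantom_spec")
}

# Chord lengths of rays S + t*(P - S) through one ellipsoid, vectorized over
# rays.  sx.. are matrices/vectors of identical shape.
ellipsoid_chords <- function(e, sx, sy, sz, dx, dy, dz) {
  cphi <- cos(e$phi_z); sphi <- sin(e$phi_z)
  # translate then rotate by -phi_z, then scale by semi-axes
  ox <- (sx - e$center[1]) * cphi + (sy - e$center[2]) * sphi
  oy <- -(sx - e$center[1]) * sphi + (sy - e$center[2]) * cphi
  oz <- sz - e$center[3]
  ex <- dx * cphi + dy * sphi
  ey <- -dx * sphi + dy * cphi
  ez <- dz
  ox <- ox / e$semiaxes[1]; oy <- oy / e$semiaxes[2]; oz <- oz / e$semiaxes[3]
  ex <- ex / e$semiaxes[1]; ey <- ey / e$semiaxes[2]; ez <- ez / e$semiaxes[3]
  A <- ex^2 + ey^2 + ez^2
  B <- 2 * (ox * ex + oy * ey + oz * ez)
  C <- ox^2 + oy^2 + oz^2 - 1
  disc <- B^2 - 4 * A * C
  hit <- disc > 0
  chord_t <- numeric(length(A))
  chord_t[hit] <- sqrt(disc[hit]) / A[hit]
  chord_t * sqrt(dx^2 + dy^2 + dz^2)   # parameter span -> world length
}

#' Analytic cone-beam forward projection of an ellipsoid phantom
#'
#' For every detector pixel and projection angle, accumulates the exact line
#' integral \eqn{\sum_i \mu_i \cdot} (chord length of the source--pixel ray
#' through ellipsoid i), from the closed-form quadratic ray/ellipsoid
#' intersection.  The injected axis offset and tilt of the phantom spec are
#' realized by shifting the detector coordinate frame, exactly as a
#' misaligned scanner would.
#'
#' With a monochromatic beam (no \code{beam} element) the output is the
#' attenuation stack itself.  With a two-energy beam the polychromatic
#' transmission \eqn{w_1 e^{-k_1 p} + w_2 e^{-k_2 p}} is multiplied by the
#' flat-field image (plus nothing else; gain, defects, fluence and dark are
#' applied by [inject_artifacts()]) and emitted as a raw-intensity stack, so
#' the full normalization/linearization path is exercised.
#'
#' @param phantom A [phantom_spec()].
#' @param geometry A [scan_geometry()].
#' @param flat Flat-field image (matrix) or scalar open-beam level; only used
#'   with a polychromatic beam or when \code{emit = "raw"}.  Default 1.
#' @param emit \code{"auto"} (attenuation if monochromatic, raw if a beam is
#'   present), \code{"attenuation"}, or \code{"raw"}.
#' @return A [projection_stack()] at stage \code{attenuation} or \code{raw}.
#' @export
forward_project <- function(phantom, geometry, flat = 1,
                            emit = c("auto", "attenuation", "raw")) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(geometry, "scan_geometry"))
  emit <- match.arg(emit)
  if (emit == "auto") emit <- if (is.null(phantom$beam)) "attenuation" else "raw"
  if (emit == "attenuation" && !is.null(phantom$beam))
    stop("a polychromatic phantom emits raw intensity, not attenuation")
  n_u <- geometry$n_u; n_v <- geometry$n_v
  angles <- geometry$angles
  ctr <- detector_center(geometry)
  px <- geometry$pixel_size
  # detector-frame pixel coordinates with injected offset/tilt shifts
  urow <- 0:(n_u - 1L)
  vcol <- 0:(n_v - 1L)
  shift_v <- phantom$axis_offset_px + phantom$axis_tilt[1] +
    phantom$axis_tilt[2] * vcol                     # per-row shift in px
  U <- (matrix(urow, n_v, n_u, byrow = TRUE) - ctr["u"] - shift_v) * px
  V <- matrix((vcol - ctr["v"]) * px, n_v, n_u)
  sdd <- geometry$sdd; scd <- geometry$scd
  stack <- array(0, c(n_v, n_u, length(angles)))
  for (a in seq_along(angles)) {
    phi <- angles[a]
    # source and pixel positions in the (rotated) sample frame
    sx <- -scd * sin(phi); sy <- scd * cos(phi); sz <- 0
    pxw <- U * cos(phi) + (sdd - scd) * sin(phi)
    pyw <- U * sin(phi) - (sdd - scd) * cos(phi)
    pzw <- V
    dx <- pxw - sx; dy <- pyw - sy; dz <- pzw - sz
    if (any(dx^2 + dy^2 + dz^2 == 0)) stop("degenerate zero-length ray")
    p <- matrix(0, n_v, n_u)
    for (e in phantom$ellipsoids)
      p <- p + e$mu * ellipsoid_chords(e, sx, sy, sz, dx, dy, dz)
    stack[, , a] <- p
  }
  if (emit == "attenuation")
    return(projection_stack(stack, angles, "attenuation"))
  if (is.null(phantom$beam)) {
    trans <- exp(-stack)
  } else {
    w <- phantom$beam$weights; k <- phantom$beam$k
    trans <- w[1] * exp(-stack * k[1]) + w[2] * exp(-stack * k[2])
  }
  if (is.matrix(flat)) {
    stopifnot(all(dim(flat) == c(n_v, n_u)))
    raw <- trans * as.vector(flat)
  } else raw <- trans * flat
  projection_stack(raw, angles, "raw")
}

#' Inject detector artifacts into a raw projection stack
#'
#' Applies, in order: per-pixel gain multiplication, defect-pixel overwrite
#' (stuck raw values, constant across projections), per-projection fluence
#' scaling, and dark-offset addition.  With no artifact parameters set this
#' is the identity.
#'
#' @param stack A [projection_stack()] at stage \code{raw}.
#' @param phantom A [phantom_spec()] carrying the artifact block.
#' @param dark_level Scalar dark offset added last; default 0.
#' @return The corrupted raw stack.
#' @export
inject_artifacts <- function(stack, phantom, dark_level = 0) {
  check_stage(stack, "raw", "inject_artifacts")
  stopifnot(inherits(phantom, "phantom_spec"))
  d <- dim(stack)
  out <- unclass(stack)
  if (!is.null(phantom$gain)) {
    stopifnot(all(dim(phantom$gain) == d[1:2]))
    out <- out * as.vector(phantom$gain)
  }
  if (!is.null(phantom$defects)) {
    df <- phantom$defects
    if (any(df$v < 0 | df$v >= d[1L] | df$u < 0 | df$u >= d[2L]))
      stop("defect coordinates outside the detector")
    for (k in seq_len(d[3L]))
      out[cbind(df$v + 1L, df$u + 1L, k)] <- df$value
  }
  if (!is.null(phantom$fluence)) {
    stopifnot(length(phantom$fluence) == d[3L])
    for (k in seq_len(d[3L])) out[, , k] <- out[, , k] * phantom$fluence[k]
  }
  out <- out + dark_level
  restage(stack, out, "raw")
}

#' Simulate a complete scan: projections, flat field and dark field
#'
#' Convenience wrapper around [forward_project()] and [inject_artifacts()]
#' producing the files a real scanner would deliver.  The flat field is the
#' open-beam level (optionally with a smooth radial falloff); the per-pixel
#' gain models sensitivity drift *after* flat acquisition, so it corrupts the
#' projections but not the flat (this is what creates ring artifacts that
#' flat-fielding cannot remove).  The dark field is a constant offset.
#'
#' @param phantom A [phantom_spec()].
#' @param geometry A [scan_geometry()].
#' @param flat_level Open-beam detector counts; default 20000.
#' @param dark_level Dark counts; default 100.
#' @param flat_falloff Relative drop of the flat field at the detector corner
#'   (smooth quadratic vignette); default 0 (uniform).
#' @return List with elements \code{projections} (raw
#'   [projection_stack()]), \code{flat}, \code{dark} (matrices).
#' @export
simulate_scan <- function(phantom, geometry, flat_level = 20000,
                          dark_level = 100, flat_falloff = 0) {
  n_u <- geometry$n_u; n_v <- geometry$n_v
  ctr <- detector_center(geometry)
  U <- matrix(0:(n_u - 1L), n_v, n_u, byrow = TRUE) - ctr["u"]
  V <- matrix(0:(n_v - 1L), n_v, n_u) - ctr["v"]
  r2 <- (U^2 + V^2) / max(U^2 + V^2)
  flat_img <- flat_level * (1 - flat_falloff * r2)
  raw <- forward_project(phantom, geometry, flat = flat_img, emit = "raw")
  raw <- inject_artifacts(raw, phantom, dark_level = dark_level)
  dark <- matrix(dark_level, n_v, n_u)
  list(projections = raw, flat = flat_img + dark, dark = dark)
}
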