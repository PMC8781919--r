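#' Cone-beam scan geometry
#'
#' Describes a circular cone-beam acquisition: an X-ray point source at
#' distance \code{scd} (source--center distance, mm) from the rotation axis, a
#' flat detector at distance \code{sdd} (source--detector distance, mm) from
#' the source, and a list of projection angles.  The object rotates about the
#' vertical z axis; the detector is sampled on a regular grid of
#' \code{n_v} rows by \code{n_u} columns with pitch \code{pixel_size} (mm).
#'
#' Conventions used throughout the package:
#' \itemize{
#'   \item Right-handed world frame, rotation axis along +z.  Angles are the
#'     object rotation, counter-clockwise viewed from +z.
#'   \item Detector coordinates \eqn{(X_p, Y_p)} in mm with origin on the
#'     central ray; pixel indices are 0-based with pixel centers at integer
#'     indices, the central ray nominally at column \eqn{(n_u-1)/2} and row
#'     \eqn{(n_v-1)/2}.
#'   \item \code{axis_offset_px} shifts the image of the rotation axis
#'     horizontally on the detector (in pixels, signed): the projection of the
#'     axis falls at column \eqn{(n_u-1)/2 + } \code{axis_offset_px}.
#'   \item \code{axis_tilt = c(a, m)} describes a rotation axis whose apparent
#'     horizontal offset varies linearly with the tomogram slice index k:
#'     offset(k) = a + m*k pixels (on top of \code{axis_offset_px}).
#' }
#'
#' The magnification at the rotation center is \code{sdd/scd}; the natural
#' (Nyquist-matched) reconstruction voxel size is
#' \code{pixel_size * scd / sdd}, i.e. the detector pitch demagnified to the
#' rotation-center plane.
#'
#' @param scd Source-to-rotation-center distance in mm (> 0).
#' @param sdd Source-to-detector distance in mm (> scd).
#' @param pixel_size Detector pixel pitch in mm (> 0).
#' @param n_u,n_v Detector columns and rows (integers >= 2).
#' @param angles Numeric vector of projection angles in radians, ordered as
#'   acquired.  Full-scan reconstruction assumes coverage of \eqn{[0, 2\pi)}.
#' @param axis_offset_px Horizontal rotation-axis offset in detector pixels
#'   (signed); default 0.
#' @param axis_tilt Numeric pair \code{c(a, m)}: axis offset in pixels at
#'   slice 0 and slope in pixels per slice; default \code{c(0, 0)}.
#' @return An object of class \code{"scan_geometry"}.
#' @seealso [full_scan_angles()], [voxel_to_detector()], [magnification()]
#' @examples
#' g <- scan_geometry(scd = 188, sdd = 1017.34, pixel_size = 0.2,
#'                    n_u = 512, n_v = 512, angles = full_scan_angles(400))
#' magnification(g)   # ~5.41
#' voxel_size(g)      # ~0.037 mm
#' @export
scan_geometry <- function(scd, sdd, pixel_size, n_u, n_v, angles,
                          axis_offset_px = 0, axis_tilt = c(0, 0)) {
  stopifnot(is.numeric(scd), length(scd) == 1L,
            is.numeric(sdd), length(sdd) == 1L,
            is.numeric(pixel_size), length(pixel_size) == 1L)
  if (!(scd > 0 && scd < sdd))
    stop("invalid geometry: need 0 < scd < sdd (got scd = ", scd,
         ", sdd = ", sdd, ")")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  n_u <- as.integer(n_u); n_v <- as.integer(n_v)
  if (n_u < 2L || n_v < 2L) stop("n_u and n_v must be >= 2")
  if (length(angles) < 1L) stop("angle list must not be empty")
  if (!all(is.finite(angles))) stop("angles must be finite")
  if (length(axis_tilt) != 2L || !all(is.finite(axis_tilt)))
    stop("axis_tilt must be a finite pair c(a, m)")
  if (!is.finite(axis_offset_px)) stop("axis_offset_px must be finite")
  structure(list(scd = scd, sdd = sdd, pixel_size = pixel_size,
                 n_u = n_u, n_v = n_v, angles = as.numeric(angles),
                 axis_offset_px = as.numeric(axis_offset_px),
                 axis_tilt = as.numeric(axis_tilt)),
            class = "scan_geometry")
}

#' Equally spaced full-scan angles
#'
#' @param n_proj Number of projections over a full turn.
#' @return Angles in radians covering \eqn{[0, 2\pi)} end-exclusive.
#' @export
full_scan_angles <- function(n_proj) {
  n_proj <- as.integer(n_proj)
  stopifnot(n_proj >= 1L)
  seq(0, 2 * pi, length.out = n_proj + 1L)[seq_len(n_proj)]
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("Cone-beam scan geometry\n")
  cat(sprintf("  SCD %.4g mm, SDD %.4g mm (magnification %.4f)\n",
              x$scd, x$sdd, magnification(x)))
  cat(sprintf("  detector %d x %d px, pitch %.4g mm\n", x$n_v, x$n_u,
              x$pixel_size))
  cat(sprintf("  %d projection angles [%.4g, %.4g] rad\n", length(x$angles),
              min(x$angles), max(x$angles)))
  cat(sprintf("  axis offset %.3f px, tilt (a = %.3f px, m = %.5f px/slice)\n",
              x$axis_offset_px, x$axis_tilt[1], x$axis_tilt[2]))
  cat(sprintf("  reconstruction voxel size %.4g mm\n", voxel_size(x)))
  invisible(x)
}

#' Magnification at the rotation center
#' @param geometry A [scan_geometry()].
#' @return \code{sdd/scd}.
#' @export
magnification <- function(geometry) geometry$sdd / geometry$scd

#' Reconstruction voxel size
#'
#' The detector pitch demagnified to the rotation-center plane,
#' \code{pixel_size * scd / sdd} (mm).  Volumes are isotropic at this size.
#' @param geometry A [scan_geometry()].
#' @return Voxel edge length in mm.
#' @export
voxel_size <- function(geometry) geometry$pixel_size * geometry$scd / geometry$sdd

#' Map voxel centers to detector coordinates
#'
#' For a projection at rotation angle \code{angle}, computes where the ray
#' from the source through each voxel center intersects the detector, and the
#' FDK distance weight.  With the object rotated by \eqn{\varphi}, a world
#' point (x, y, z) has beam-frame coordinates
#' \eqn{x_\perp = x\cos\varphi + y\sin\varphi} (parallel to the detector
#' rows) and \eqn{d = -x\sin\varphi + y\cos\varphi} (signed distance from the
#' rotation-center plane, positive toward the source).  Then
#' \deqn{X_p = x_\perp \frac{SDD}{SCD - d}, \quad
#'       Y_p = z \frac{SDD}{SCD - d},}
#' and the backprojection distance weight is \eqn{SCD^2/(SCD - d)^2}, equal
#' to 1 on the rotation-center plane and > 1 for voxels nearer the source.
#'
#' @param points Numeric matrix with 3 columns (x, y, z) in mm, or a length-3
#'   vector for a single point.
#' @param angle Projection angle in radians (scalar).
#' @param geometry A [scan_geometry()].
#' @return List with numeric vectors \code{Xp}, \code{Yp} (mm on the
#'   detector), \code{d} (mm, positive toward the source) and \code{weight}.
#' @export
voxel_to_detector <- function(points, angle, geometry) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  stopifnot(ncol(points) == 3L, length(angle) == 1L)
  cphi <- cos(angle); sphi <- sin(angle)
  xp <- points[, 1L] * cphi + points[, 2L] * sphi
  d <- -points[, 1L] * sphi + points[, 2L] * cphi
  if (any(abs(d) >= geometry$scd))
    stop("voxel outside the valid field of view: |d| >= scd")
  m <- geometry$sdd / (geometry$scd - d)
  list(Xp = xp * m, Yp = points[, 3L] * m, d = d,
       weight = (geometry$scd / (geometry$scd - d))^2)
}

# Detector center column/row in 0-based pixel indices (before axis offset).
detector_center <- function(geometry) {
  c(u = (geometry$n_u - 1) / 2, v = (geometry$n_v - 1) / 2)
}
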