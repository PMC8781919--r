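#' Bilinear interpolation on an image grid
#'
#' Full-precision bilinear interpolation of the four pixel neighbors of each
#' fractional coordinate.  Coordinates are 0-based with pixel centers at
#' integer positions; any coordinate outside \eqn{[0, n-1]} in either axis
#' contributes 0 (rays leaving the detector add nothing to a voxel).
#'
#' @param image Numeric matrix (rows = y, columns = x).
#' @param x Fractional column coordinates (any shape).
#' @param y Fractional row coordinates (same shape as \code{x}).
#' @return Interpolated values, same shape as \code{x}.
#' @export
bilinear_sample <- function(image, x, y) {
  nv <- nrow(image); nu <- ncol(image)
  inside <- x >= 0 & x <= nu - 1 & y >= 0 & y <= nv - 1
  xc <- pmin(pmax(x, 0), nu - 1)
  yc <- pmin(pmax(y, 0), nv - 1)
  x0 <- pmin(floor(xc), nu - 2)
  y0 <- pmin(floor(yc), nv - 2)
  fx <- xc - x0; fy <- yc - y0
  # flatten: a matrix-shaped index would trigger R's coordinate-pair indexing
  i00 <- as.vector(y0 + 1 + x0 * nv)
  v <- as.vector((1 - fx) * (1 - fy)) * image[i00] +
       as.vector(fx * (1 - fy)) * image[i00 + nv] +
       as.vector((1 - fx) * fy) * image[i00 + 1] +
       as.vector(fx * fy) * image[i00 + nv + 1]
  v[!inside] <- 0
  if (!is.null(dim(x))) dim(v) <- dim(x)
  v
}

split_range <- function(n, chunk) {
  starts <- seq.int(0L, n - 1L, by = chunk)
  lapply(starts, function(s) c(s, min(s + chunk, n)))
}

#' Plan volume slabs and projection batches under a memory budget
#'
#' Backprojection of arbitrarily large data proceeds chunk-wise: the volume
#' is split into z-slabs and the projection stack into batches of angles, so
#' that each slab and each batch individually fits the memory budget.  Every
#' voxel's angular sum is accumulated across batches, which is exact because
#' voxels are mutually independent and the backprojection sum is associative.
#' Slabs and batches are chosen greedily maximal (8 bytes per element).
#'
#' @param volume_shape Integer triple \code{c(n_x, n_y, n_z)}.
#' @param n_proj Number of projections.
#' @param detector_shape Integer pair \code{c(n_v, n_u)}.
#' @param budget_bytes Memory budget in bytes that a slab, and separately a
#'   projection batch, must fit into.
#' @return An object of class \code{"chunk_plan"}: half-open 0-based slab
#'   ranges over \eqn{[0, n_z)} and batch ranges over \eqn{[0, n_{proj})}.
#' @export
plan_chunks <- function(volume_shape, n_proj, detector_shape, budget_bytes) {
  volume_shape <- as.integer(volume_shape)
  detector_shape <- as.integer(detector_shape)
  stopifnot(length(volume_shape) == 3L, length(detector_shape) == 2L,
            all(volume_shape >= 1L), n_proj >= 1L)
  bytes_slice <- prod(volume_shape[1:2]) * 8
  bytes_proj <- prod(detector_shape) * 8
  max_slab <- floor(budget_bytes / bytes_slice)
  max_batch <- floor(budget_bytes / bytes_proj)
  if (max_slab < 1L || max_batch < 1L)
    stop("memory budget too small: need at least ",
         max(bytes_slice, bytes_proj), " bytes (one volume slice / one projection)")
  structure(list(volume_shape = volume_shape,
                 slabs = split_range(volume_shape[3L], min(max_slab, volume_shape[3L])),
                 batches = split_range(as.integer(n_proj), min(max_batch, n_proj)),
                 budget_bytes = budget_bytes),
            class = "chunk_plan")
}

#' Explicit chunk plan with a requested number of slabs and batches
#'
#' Mainly for testing the chunking contract: the reconstruction must be
#' invariant to how the volume and projections are partitioned.
#'
#' @param volume_shape Integer triple \code{c(n_x, n_y, n_z)}.
#' @param n_proj Number of projections.
#' @param n_slabs,n_batches Number of (nearly equal) parts.
#' @return A \code{chunk_plan}.
#' @export
chunk_plan <- function(volume_shape, n_proj, n_slabs = 1L, n_batches = 1L) {
  volume_shape <- as.integer(volume_shape)
  stopifnot(n_slabs >= 1L, n_batches >= 1L, n_slabs <= volume_shape[3L],
            n_batches <= n_proj)
  structure(list(volume_shape = volume_shape,
                 slabs = split_range(volume_shape[3L],
                                     ceiling(volume_shape[3L] / n_slabs)),
                 batches = split_range(as.integer(n_proj),
                                       ceiling(n_proj / n_batches)),
                 budget_bytes = NA_real_),
            class = "chunk_plan")
}

#' @export
print.chunk_plan <- function(x, ...) {
  cat(sprintf("Chunk plan: volume %s in %d z-slab(s), %d projection batch(es)\n",
              paste(x$volume_shape, collapse = "x"),
              length(x$slabs), length(x$batches)))
  invisible(x)
}

# Core accumulation: adds the contribution of projections `proj_idx` to a
# z-slab.  fstack rows may be a detector row band starting at row `row0`
# (0-based).  zg_mm are the slab's voxel-center heights, z_idx their global
# tomogram slice indices (for the tilt term).
bp_accumulate <- function(slab, fstack, proj_idx, geometry, xg, yg, zg_mm,
                          z_idx, row0 = 0L) {
  ctr <- detector_center(geometry)
  px <- geometry$pixel_size
  nxy <- length(xg) * length(yg)
  nz <- length(zg_mm)
  gx <- rep(xg, times = length(yg))
  gy <- rep(yg, each = length(xg))
  angles <- attr(fstack, "angles")
  tilt <- geometry$axis_tilt
  off_z <- geometry$axis_offset_px + tilt[1] + tilt[2] * z_idx  # per-slice px
  for (j in proj_idx) {
    phi <- angles[j]
    xp <- gx * cos(phi) + gy * sin(phi)
    d <- -gx * sin(phi) + gy * cos(phi)
    m <- geometry$sdd / (geometry$scd - d)
    w2 <- (geometry$scd / (geometry$scd - d))^2
    ubase <- xp * m / px + ctr["u"]
    img <- fstack[, , j]
    U <- matrix(ubase, nxy, nz) +
      matrix(off_z, nxy, nz, byrow = TRUE)
    V <- outer(m / px, zg_mm) + (ctr["v"] - row0)
    val <- bilinear_sample(img, U, V) * w2
    slab <- slab + val
  }
  slab
}

#' Voxel-driven FDK backprojection
#'
#' Accumulates, for every voxel, the distance-weighted bilinear sample of
#' each filtered projection at the voxel's detector intersection:
#' \deqn{V(x, y, z) = \frac{\pi}{n_{proj}} \sum_{\varphi}
#'   \frac{SCD^2}{(SCD - d(\varphi))^2} \, I'_\varphi(X_p, Y_p),}
#' with \eqn{(X_p, Y_p, d)} from [voxel_to_detector()].  The
#' \eqn{\pi/n_{proj}} factor is the angular-step normalization of a full-scan
#' FBP (each ray direction is measured twice over \eqn{2\pi}), which puts the
#' reconstruction on the absolute scale of attenuation per mm when the ramp
#' filter is sampled at the demagnified pitch (see [reconstruct()]).
#'
#' Detector sampling includes \code{axis_offset_px} and, when
#' \code{axis_tilt} is set, the per-slice offset \eqn{a + m k} for global
#' tomogram slice index k.  Rays leaving the detector contribute 0.
#' Work proceeds slab-by-slab and batch-by-batch per the chunk plan; the
#' result is independent of the partition.
#'
#' @param stack A [projection_stack()] at stage \code{filtered}.
#' @param geometry A [scan_geometry()].
#' @param plan A [chunk_plan()] / [plan_chunks()] result; default one chunk
#'   of shape \code{c(n_u, n_u, n_v)}.
#' @param origin mm offset \code{c(x, y, z)} of the volume center from the
#'   rotation center; default centered.
#' @param z_index0 Global tomogram slice index of the volume's first z slice
#'   (only relevant when reconstructing a sub-stack with axis tilt).
#' @return A \code{ct_volume}: numeric \code{n_x x n_y x n_z} array with
#'   attributes \code{voxel_size} (mm) and \code{origin}.
#' @export
backproject <- function(stack, geometry, plan = NULL, origin = c(0, 0, 0),
                        z_index0 = 0L) {
  check_stage(stack, "filtered", "backproject")
  stopifnot(inherits(geometry, "scan_geometry"))
  d <- dim(stack)
  n_proj <- d[3L]
  if (is.null(plan))
    plan <- chunk_plan(c(geometry$n_u, geometry$n_u, geometry$n_v), n_proj)
  stopifnot(inherits(plan, "chunk_plan"))
  vs <- voxel_size(geometry)
  shape <- plan$volume_shape
  xg <- ((0:(shape[1L] - 1L)) - (shape[1L] - 1) / 2) * vs + origin[1L]
  yg <- ((0:(shape[2L] - 1L)) - (shape[2L] - 1) / 2) * vs + origin[2L]
  zg_all <- ((0:(shape[3L] - 1L)) - (shape[3L] - 1) / 2) * vs + origin[3L]
  vol <- array(0, shape)
  nxy <- shape[1L] * shape[2L]
  for (slab in plan$slabs) {
    ks <- (slab[1L] + 1L):slab[2L]             # 1-based local z indices
    acc <- matrix(0, nxy, length(ks))
    for (batch in plan$batches) {
      js <- (batch[1L] + 1L):batch[2L]
      acc <- bp_accumulate(acc, stack, js, geometry, xg, yg,
                           zg_all[ks], z_index0 + ks - 1L)
    }
    vol[, , ks] <- acc
  }
  vol <- vol * pi / n_proj
  ct_volume(vol, voxel_size = vs, origin = origin)
}

#' Reconstructed volume container
#'
#' @param data Numeric 3-D array (x, y, z).
#' @param voxel_size Isotropic voxel edge length in mm.
#' @param origin mm offset of the volume center from the rotation center.
#' @return An object of class \code{"ct_volume"}.
#' @export
ct_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L, voxel_size > 0)
  structure(data, voxel_size = voxel_size, origin = origin,
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("CT volume %d x %d x %d, voxel %.4g mm, range [%.4g, %.4g]\n",
              d[1L], d[2L], d[3L], attr(x, "voxel_size"), min(x), max(x)))
  invisible(x)
}

#' Display an axial slice of a reconstructed volume
#'
#' @param x A \code{ct_volume}.
#' @param slice z index (1-based); default central.
#' @param ... Passed to [graphics::image()].
#' @export
plot.ct_volume <- function(x, slice = NULL, ...) {
  d <- dim(x)
  if (is.null(slice)) slice <- (d[3L] + 1L) %/% 2L
  graphics::image(x[, , slice], col = grDevices::gray.colors(256),
                  asp = 1, axes = FALSE,
                  main = sprintf("axial slice %d / %d", slice, d[3L]), ...)
  invisible(x)
}

#' Reconstruct a single tomogram slice from attenuation projections
#'
#' Weights, ramp-filters and backprojects one z slice of the notional
#' \code{n_u x n_u x n_v} tomogram stack.  Only the detector row band that
#' the slice's rays can intersect is filtered, which makes repeated calls
#' (e.g. the rotation-axis autofocus search) cheap.
#'
#' @param stack A [projection_stack()] at stage \code{attenuation}
#'   (unweighted).
#' @param geometry A [scan_geometry()]; its \code{axis_offset_px} /
#'   \code{axis_tilt} are honored.
#' @param slice_index 0-based tomogram slice index in \eqn{[0, n_v)};
#'   default the central slice.
#' @param filter_family Ramp filter family for [make_kernel()].
#' @param n_xy Slice edge length in voxels; default \code{n_u}.
#' @return Numeric \code{n_xy x n_xy} slice matrix.
#' @export
reconstruct_slice <- function(stack, geometry, slice_index = NULL,
                              filter_family = "ram-lak", n_xy = NULL) {
  check_stage(stack, "attenuation", "reconstruct_slice")
  d <- dim(stack)
  n_v <- d[1L]; n_u <- d[2L]
  if (is.null(slice_index)) slice_index <- (n_v - 1L) %/% 2L
  if (is.null(n_xy)) n_xy <- n_u
  vs <- voxel_size(geometry)
  z_mm <- (slice_index - (n_v - 1) / 2) * vs
  # detector rows that rays through this slice can hit, worst-case over the
  # in-slice field of view (radius of the xy grid) plus tilt and margin
  ctr <- detector_center(geometry)
  rmax <- sqrt(2) * (n_xy / 2) * vs
  mags <- geometry$sdd / (geometry$scd + c(-rmax, rmax))
  vpix <- z_mm * mags / geometry$pixel_size + ctr["v"]
  rows <- max(0L, floor(min(vpix)) - 2L):min(n_v - 1L, ceiling(max(vpix)) + 2L)
  sub <- projection_stack(unclass(stack)[rows + 1L, , , drop = FALSE],
                          proj_angles(stack), "attenuation")
  w <- cosine_weights(geometry)[rows + 1L, , drop = FALSE]
  sub <- restage(sub, unclass(sub) * as.vector(w))
  kern <- make_kernel(filter_family, n_u, delta_s = vs)
  fsub <- filter_rows(sub, kern)
  xg <- ((0:(n_xy - 1L)) - (n_xy - 1) / 2) * vs
  acc <- matrix(0, n_xy * n_xy, 1L)
  acc <- bp_accumulate(acc, fsub, seq_along(proj_angles(stack)), geometry,
                       xg, xg, z_mm, slice_index, row0 = rows[1L])
  matrix(acc * pi / d[3L], n_xy, n_xy)
}
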