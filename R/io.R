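# --- TIFF ------------------------------------------------------------------
# Reading goes through tiff::readTIFF (libtiff), which handles 16-bit
# unsigned and 32-bit float grayscale.  tiff::writeTIFF only stores
# [0,1]-scaled integer samples, so float output (attenuation stacks, SCM,
# volume slices) is written by a minimal uncompressed grayscale float-TIFF
# writer below; its output round-trips bit-exactly through libtiff.

write_float_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL); w2(42L)
  np <- length(pages)
  ifd_size <- 2L + 10L * 12L + 4L
  off <- 8L
  data_off <- ifd_off <- integer(np)
  for (i in seq_len(np)) {
    nb <- length(pages[[i]]) * 4L
    data_off[i] <- off
    ifd_off[i] <- off + nb
    off <- off + nb + ifd_size
  }
  w4(ifd_off[1L])
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count); w4(value)
  }
  for (i in seq_len(np)) {
    img <- pages[[i]]
    h <- nrow(img); w <- ncol(img)
    writeBin(as.numeric(t(img)), con, size = 4, endian = "little")
    w2(10L)
    entry(256L, 4L, 1L, w)              # ImageWidth
    entry(257L, 4L, 1L, h)              # ImageLength
    entry(258L, 3L, 1L, 32L)            # BitsPerSample
    entry(259L, 3L, 1L, 1L)             # Compression: none
    entry(262L, 3L, 1L, 1L)             # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off[i])    # StripOffsets
    entry(277L, 3L, 1L, 1L)             # SamplesPerPixel
    entry(278L, 4L, 1L, h)              # RowsPerStrip
    entry(279L, 4L, 1L, h * w * 4L)     # StripByteCounts
    entry(339L, 3L, 1L, 3L)             # SampleFormat: IEEE float
    w4(if (i < np) ifd_off[i + 1L] else 0L)
  }
  invisible(path)
}

# integer samples unscaled (as.is), float samples natively; as.is is only
# valid for integer TIFFs, so fall back when libtiff refuses it
read_tiff_pages <- function(f, all = TRUE) {
  tryCatch(tiff::readTIFF(f, all = all, as.is = TRUE),
           error = function(e) {
             if (grepl("as.is", conditionMessage(e), fixed = TRUE))
               tiff::readTIFF(f, all = all)
             else stop(e)
           })
}

# order file names treating embedded digit runs numerically
natural_order <- function(x) {
  keys <- lapply(x, function(s) {
    nums <- regmatches(s, gregexpr("[0-9]+", s))[[1]]
    if (length(nums) == 0) return(NA_real_)
    as.numeric(nums)
  })
  maxlen <- max(lengths(keys))
  mat <- do.call(rbind, lapply(keys, function(k)
    c(k, rep(-Inf, maxlen - length(k)))))
  do.call(order, c(lapply(seq_len(maxlen), function(j) mat[, j]), list(x)))
}

#' Read a projection stack from TIFF files
#'
#' Accepts a multi-page TIFF file, a directory of single-page TIFFs, or an
#' explicit character vector of files.  Multiple files are ordered by
#' natural sort of their names (embedded numbers compared numerically);
#' pages of a multi-page file keep their page order.  16-bit unsigned
#' samples are promoted to float without rescaling (65535 reads as 65535.0);
#' 32-bit float samples are read natively.
#'
#' @param path File, directory, or character vector of files.
#' @param angles Optional projection angles; default equally spaced over a
#'   full scan.
#' @param stage Stage tag for the resulting stack; default \code{"raw"}.
#' @return A [projection_stack()].
#' @export
read_projection_stack <- function(path, angles = NULL, stage = "raw") {
  if (length(path) == 1L && dir.exists(path)) {
    path <- list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                       ignore.case = TRUE)
    if (length(path) == 0L) stop("no TIFF files found in directory")
  }
  path <- path[natural_order(basename(path))]
  pages <- list()
  for (f in path) {
    p <- tryCatch(read_tiff_pages(f),
                  error = function(e) stop("unreadable TIFF '", f, "': ",
                                           conditionMessage(e)))
    if (!is.list(p)) p <- list(p)
    for (im in p) {
      if (length(dim(im)) == 3L) im <- im[, , 1L]  # drop extra channels
      if (length(pages) > 0L && !all(dim(im) == dim(pages[[1L]])))
        stop("mixed image dimensions in '", f, "'")
      pages[[length(pages) + 1L]] <- im * 1.0
    }
  }
  data <- array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
  if (is.null(angles)) angles <- full_scan_angles(length(pages))
  projection_stack(data, angles, stage)
}

#' Read a single grayscale TIFF image (flat/dark field)
#'
#' @param path TIFF file.
#' @return Numeric matrix (16-bit values unscaled).
#' @export
read_image_tiff <- function(path) {
  im <- read_tiff_pages(path, all = FALSE)
  if (length(dim(im)) == 3L) im <- im[, , 1L]
  im * 1.0
}

#' Write a projection stack (or images) as 32-bit float TIFF
#'
#' @param stack A [projection_stack()] or a matrix.
#' @param path Output file (multi-page when several projections).
#' @return The path, invisibly.
#' @export
write_projection_stack <- function(stack, path) {
  if (is.matrix(stack)) return(invisible(write_float_tiff(stack, path)))
  d <- dim(stack)
  pages <- lapply(seq_len(d[3L]), function(k) unclass(stack)[, , k])
  invisible(write_float_tiff(pages, path))
}

#' Write a defect mask as 8-bit TIFF (0 / 255)
#'
#' @param mask Logical matrix.
#' @param path Output file.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a defect mask written by [write_mask_tiff()]
#' @param path TIFF file.
#' @return Logical matrix.
#' @export
read_mask_tiff <- function(path) read_image_tiff(path) > 0

# --- volumes ---------------------------------------------------------------

#' Write a reconstructed volume
#'
#' \code{format = "raw"}: little-endian 32-bit float, x fastest, plus a text
#' sidecar \code{<path>.meta} recording nx, ny, nz, voxel size and byte
#' order.  \code{format = "tiff"}: one float-TIFF file per z slice
#' (\code{<path>_zNNNN.tif}) plus the same sidecar.
#'
#' @param volume A \code{ct_volume}.
#' @param path Output path (raw file, or slice-file prefix).
#' @param format \code{"raw"} or \code{"tiff"}.
#' @return The sidecar path, invisibly.
#' @export
write_volume <- function(volume, path, format = c("raw", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(volume, "ct_volume"), all(is.finite(volume)))
  d <- dim(volume)
  meta <- c(sprintf("nx = %d", d[1L]), sprintf("ny = %d", d[2L]),
            sprintf("nz = %d", d[3L]),
            sprintf("voxel_size_mm = %.10g", attr(volume, "voxel_size")),
            "dtype = float32", "byte_order = little", "order = x_fastest",
            sprintf("format = %s", format))
  if (format == "raw") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(volume), con, size = 4L, endian = "little")
  } else {
    for (k in seq_len(d[3L]))
      write_float_tiff(volume[, , k], sprintf("%s_z%04d.tif", path, k - 1L))
  }
  writeLines(meta, paste0(path, ".meta"))
  invisible(paste0(path, ".meta"))
}

#' Read a volume written by [write_volume()]
#'
#' @param path The path given to [write_volume()].
#' @return A \code{ct_volume}.
#' @export
read_volume <- function(path) {
  meta <- read_kv_lines(readLines(paste0(path, ".meta")))
  d <- c(as.integer(meta$nx), as.integer(meta$ny), as.integer(meta$nz))
  vs <- as.numeric(meta$voxel_size_mm)
  if (identical(meta$format, "tiff")) {
    data <- array(0, d)
    for (k in seq_len(d[3L]))
      data[, , k] <- tiff::readTIFF(sprintf("%s_z%04d.tif", path, k - 1L))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    data <- array(readBin(con, numeric(), n = prod(d), size = 4L,
                          endian = "little"), d)
  }
  ct_volume(data, voxel_size = vs)
}

# --- configuration ---------------------------------------------------------

read_kv_lines <- function(lines) {
  lines <- sub("[#;].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  out <- list()
  for (l in lines) {
    kv <- regmatches(l, regexpr("=", l), invert = TRUE)[[1]]
    if (length(kv) != 2L) next
    out[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  out
}

#' Read a pipeline configuration file
#'
#' Flat, human-readable key-value format: one \code{key = value} per line,
#' optional \code{[section]} headers (cosmetic; keys must be globally
#' unique), \code{#} or \code{;} comments.  Numeric-looking values are
#' converted; comma-separated values become vectors;
#' \code{true}/\code{false} become logicals.
#'
#' @param path Config file.
#' @return Named list of class \code{"ct_config"}.
#' @export
read_ct_config <- function(path) {
  kv <- read_kv_lines(readLines(path))
  parse1 <- function(v) {
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    parts <- trimws(strsplit(v, ",")[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    if (!anyNA(nums)) return(nums)
    if (length(parts) > 1L) parts else v
  }
  structure(lapply(kv, parse1), class = "ct_config")
}

#' Write a pipeline configuration file
#'
#' @param cfg Named list (values may be vectors; written comma-separated).
#' @param path Output file.
#' @export
write_ct_config <- function(cfg, path) {
  fmt1 <- function(v) {
    if (is.logical(v)) return(tolower(as.character(v)))
    paste(format(v, digits = 12, trim = TRUE, scientific = FALSE),
          collapse = ", ")
  }
  writeLines(sprintf("%s = %s", names(cfg), vapply(cfg, fmt1, character(1))),
             path)
  invisible(path)
}
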