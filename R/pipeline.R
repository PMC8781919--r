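#' Weight, filter and backproject an attenuation stack
#'
#' The FDK core in one call: cosine weighting, row-wise ramp filtering with
#' the kernel sampled at the demagnified detector pitch (the reconstruction
#' voxel size, which puts voxel values on the absolute scale of attenuation
#' per mm), and chunked voxel-driven backprojection.
#'
#' @param stack A [projection_stack()] at stage \code{attenuation}.
#' @param geometry A [scan_geometry()].
#' @param filter_family \code{"ram-lak"} (default) or \code{"shepp-logan"}.
#' @param volume_shape Integer triple; default \code{c(n_u, n_u, n_v)}.
#' @param budget_bytes Memory budget for [plan_chunks()]; default 512 MiB.
#' @param plan Optional explicit [chunk_plan()] (overrides the two above).
#' @return A \code{ct_volume}.
#' @export
reconstruct <- function(stack, geometry, filter_family = "ram-lak",
                        volume_shape = NULL, budget_bytes = 512 * 1024^2,
                        plan = NULL) {
  check_stage(stack, "attenuation", "reconstruct")
  d <- dim(stack)
  if (is.null(volume_shape)) volume_shape <- c(geometry$n_u, geometry$n_u,
                                               geometry$n_v)
  if (is.null(plan))
    plan <- plan_chunks(volume_shape, d[3L], d[1:2], budget_bytes)
  w <- apply_cosine_weights(stack, geometry)
  kern <- make_kernel(filter_family, d[2L], delta_s = voxel_size(geometry))
  f <- filter_rows(w, kern)
  backproject(f, geometry, plan)
}

log_line <- function(log, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  c(log, line)
}

cfg_get <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

#' Run the complete reconstruction pipeline from a configuration
#'
#' Executes the stages in acquisition-processing order: read projections
#' (and flat/dark) -> normalization with the configured fluence option ->
#' defect-pixel median filtering (MF) -> detector-line-ratio sensitivity
#' correction (DLR) -> logarithm to attenuation -> polynomial beam-hardening
#' correction -> cosine weighting -> ramp filtering -> optional rotation-axis
#' offset / tilt estimation -> chunked backprojection -> volume output.
#' MF is applied before DLR because the line-ratio statistics are themselves
#' corrupted by stuck pixels.  The run is headless and deterministic; every
#' stage's parameters are echoed into the run log.
#'
#' Recognized config keys (flat key-value file, see [read_ct_config()]):
#' \preformatted{
#' projections, flat, dark, output      # paths (flat/dark optional)
#' output_format                        # raw | tiff (default raw)
#' scd, sdd, pixel_size, n_proj         # geometry; or angles = a1, a2, ...
#' axis_offset_px, axis_tilt            # optional prior calibration
#' normalize_mode                       # none | roi_fluence | flat_mean
#' roi                                  # u0, v0, w, h  (roi_fluence)
#' mf_enabled, mf_sigma, mf_window      # outlier correction (default off)
#' dlr_enabled                          # ring correction (default off)
#' bhc_enabled, bhc_a, bhc_b, bhc_c     # beam hardening (default off)
#' filter                              # ram-lak | shepp-logan
#' find_cor, cor_range, cor_step        # autofocus axis search (default off)
#' find_tilt, tilt_slices               # tilt estimation (default off)
#' volume_shape                         # nx, ny, nz (default n_u, n_u, n_v)
#' budget_mb                            # chunking budget (default 512)
#' }
#'
#' @param config A \code{ct_config} list from [read_ct_config()], a path to
#'   a config file, or a plain named list.
#' @param stack Optional in-memory raw [projection_stack()] (bypasses the
#'   \code{projections} path).
#' @param flat,dark Optional in-memory reference images.
#' @param quiet Suppress progress messages; default TRUE.
#' @return List with elements \code{volume} (a \code{ct_volume}),
#'   \code{geometry} (as used, including any estimated offset/tilt) and
#'   \code{log} (character vector).
#' @export
run_pipeline <- function(config, stack = NULL, flat = NULL, dark = NULL,
                         quiet = TRUE) {
  if (is.character(config)) config <- read_ct_config(config)
  cfg <- config
  log <- character()
  say <- function(l, fmt, ...) {
    l <- log_line(l, fmt, ...)
    if (!quiet) message(utils::tail(l, 1L))
    l
  }
  stage_fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  # --- input ---
  if (is.null(stack)) {
    if (is.null(cfg$projections)) stop("config lacks 'projections' path")
    stack <- tryCatch(read_projection_stack(cfg$projections),
                      error = function(e) stage_fail("read", e))
  }
  if (is.null(flat) && !is.null(cfg$flat)) flat <- read_image_tiff(cfg$flat)
  if (is.null(dark) && !is.null(cfg$dark)) dark <- read_image_tiff(cfg$dark)
  d <- dim(stack)
  log <- say(log, "input: %d projections of %d x %d px", d[3L], d[1L], d[2L])

  # --- geometry ---
  angles <- if (!is.null(cfg$angles)) cfg$angles else
    full_scan_angles(cfg_get(cfg, "n_proj", d[3L]))
  geom <- tryCatch(
    scan_geometry(cfg$scd, cfg$sdd, cfg$pixel_size, d[2L], d[1L], angles,
                  axis_offset_px = cfg_get(cfg, "axis_offset_px", 0),
                  axis_tilt = cfg_get(cfg, "axis_tilt", c(0, 0))),
    error = function(e) stage_fail("geometry", e))
  log <- say(log, "geometry: scd %.4g sdd %.4g pitch %.4g (voxel %.4g mm)",
             geom$scd, geom$sdd, geom$pixel_size, voxel_size(geom))

  # --- normalization ---
  mode <- cfg_get(cfg, "normalize_mode", if (is.null(flat)) "none" else "flat_mean")
  ncfg <- tryCatch(
    normalization_config(mode = mode, dark = dark, flat = flat,
                         roi = cfg_get(cfg, "roi")),
    error = function(e) stage_fail("normalize", e))
  norm <- tryCatch(normalize_projections(stack, ncfg),
                   error = function(e) stage_fail("normalize", e))
  log <- say(log, "normalized (mode %s)", mode)

  # --- ring corrections on normalized data ---
  if (isTRUE(cfg_get(cfg, "mf_enabled", FALSE))) {
    ocfg <- outlier_config(cfg_get(cfg, "mf_sigma", 3),
                           rep(cfg_get(cfg, "mf_window", 5L), 2L))
    mask <- find_outlier_mask(norm, ocfg)
    norm <- repair_defects(norm, mask, window = cfg_get(cfg, "mf_window", 5L))
    log <- say(log, "MF: %d defect pixel(s) repaired (sigma %.3g, win %d)",
               sum(mask), ocfg$sigma_multiplier, ocfg$window[1L])
  }
  if (isTRUE(cfg_get(cfg, "dlr_enabled", FALSE))) {
    scm <- build_scm_dlr(norm)
    norm <- apply_scm(norm, scm)
    log <- say(log, "DLR: SCM gain range [%.4f, %.4f]", min(scm), max(scm))
  }

  # --- attenuation + beam hardening ---
  att <- to_attenuation(norm)
  if (isTRUE(cfg_get(cfg, "bhc_enabled", FALSE))) {
    bp <- bhc_params(cfg_get(cfg, "bhc_a", 1), cfg_get(cfg, "bhc_b", 0),
                     cfg_get(cfg, "bhc_c", 3))
    att <- bhc_correct(att, bp)
    log <- say(log, "BHC: f(x) = %.4g x + %.4g x^%.3g", bp$a, bp$b, bp$c)
  }

  # --- geometry auto-calibration ---
  if (isTRUE(cfg_get(cfg, "find_cor", FALSE))) {
    rng <- cfg_get(cfg, "cor_range", c(-20, 20))
    est <- tryCatch(
      find_axis_offset(att, geom, lo = rng[1L], hi = rng[2L],
                       step = cfg_get(cfg, "cor_step", 1),
                       slice_index = cfg_get(cfg, "cor_slice")),
      error = function(e) stage_fail("findcor", e))
    geom$axis_offset_px <- as.numeric(est)
    log <- say(log, "COR: estimated axis offset %.3f px", geom$axis_offset_px)
  }
  if (isTRUE(cfg_get(cfg, "find_tilt", FALSE))) {
    slices <- cfg_get(cfg, "tilt_slices")
    if (is.null(slices)) stop("find_tilt requires tilt_slices")
    rng <- cfg_get(cfg, "cor_range", c(-20, 20))
    fit <- tryCatch(
      estimate_axis_tilt(att, geom, slices, lo = rng[1L], hi = rng[2L],
                         step = cfg_get(cfg, "cor_step", 1)),
      error = function(e) stage_fail("findtilt", e))
    geom$axis_offset_px <- 0
    geom$axis_tilt <- c(fit$a, fit$m)
    log <- say(log, "tilt: a %.3f px, m %.5f px/slice (residual %.3g)",
               fit$a, fit$m, fit$residual_norm)
  }

  # --- weight + filter + backproject ---
  vshape <- cfg_get(cfg, "volume_shape", c(d[2L], d[2L], d[1L]))
  budget <- cfg_get(cfg, "budget_mb", 512) * 1024^2
  plan <- tryCatch(plan_chunks(vshape, d[3L], d[1:2], budget),
                   error = function(e) stage_fail("chunking", e))
  log <- say(log, "chunk plan: %d slab(s) x %d batch(es), budget %.0f MiB",
             length(plan$slabs), length(plan$batches), budget / 1024^2)
  t0 <- proc.time()[[3L]]
  vol <- tryCatch(
    reconstruct(att, geom, filter_family = cfg_get(cfg, "filter", "ram-lak"),
                plan = plan),
    error = function(e) stage_fail("backproject", e))
  log <- say(log, "backprojection done in %.1f s", proc.time()[[3L]] - t0)

  if (!is.null(cfg$output)) {
    write_volume(vol, cfg$output, format = cfg_get(cfg, "output_format", "raw"))
    log <- say(log, "volume written to %s", cfg$output)
    writeLines(log, paste0(cfg$output, ".log"))
  }
  list(volume = vol, geometry = geom, log = log)
}
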