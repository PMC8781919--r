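#' Projection stack container
#'
#' A stack of 2-D detector images stored as an \code{n_v x n_u x n_proj}
#' numeric array, tagged with the processing stage it has reached and the
#' projection angle of every image.  Stages advance along the pipeline:
#' \code{raw} (detector counts) -> \code{normalized} (transmission, > 0) ->
#' \code{attenuation} (line integrals, after -log) -> \code{filtered}
#' (weighted and ramp-filtered, ready for backprojection).
#'
#' @param data Numeric array \code{n_v x n_u x n_proj} (a matrix is accepted
#'   for a single projection).
#' @param angles Projection angles in radians, length \code{n_proj}.
#' @param stage Processing stage tag.
#' @return An object of class \code{"projection_stack"}.
#' @export
projection_stack <- function(data, angles,
                             stage = c("raw", "normalized", "attenuation",
                                       "filtered")) {
  stage <- match.arg(stage)
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (length(angles) != dim(data)[3L])
    stop("length(angles) must equal the number of projections")
  if (!all(is.finite(data))) stop("projection data must be finite")
  structure(data, angles = as.numeric(angles), stage = stage,
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Projection stack: %d projections of %d x %d px, stage '%s'\n",
              d[3L], d[1L], d[2L], proj_stage(x)))
  cat(sprintf("  value range [%.5g, %.5g]\n", min(x), max(x)))
  invisible(x)
}

#' Processing stage of a projection stack
#' @param stack A [projection_stack()].
#' @return Character stage tag.
#' @export
proj_stage <- function(stack) attr(stack, "stage")

#' Projection angles of a stack
#' @param stack A [projection_stack()].
#' @return Numeric vector of angles in radians.
#' @export
proj_angles <- function(stack) attr(stack, "angles")

# Replace the data of a stack keeping angles, optionally advancing the stage.
restage <- function(stack, data = stack, stage = proj_stage(stack)) {
  structure(array(as.numeric(data), dim(stack)),
            angles = proj_angles(stack), stage = stage,
            class = "projection_stack")
}

check_stage <- function(stack, expected, what) {
  if (!inherits(stack, "projection_stack"))
    stop(what, ": input must be a projection_stack")
  if (!proj_stage(stack) %in% expected)
    stop(what, ": expected stage ", paste(expected, collapse = "/"),
         " but got '", proj_stage(stack), "'")
  invisible(stack)
}
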