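#' Cosine (distance) weighting image for cone-beam projections
#'
#' Before ramp filtering, every detector pixel is weighted by
#' \deqn{W(X_p, Y_p) = \frac{SDD}{\sqrt{X_p^2 + Y_p^2 + SDD^2}},}
#' the cosine of the angle between the central ray and the ray through the
#' pixel.  \eqn{(X_p, Y_p)} are pixel-center coordinates in mm relative to
#' the piercing point of the central ray; when the rotation axis is off
#' center, the \eqn{X_p} origin shifts by \code{axis_offset_px} pixels.
#'
#' @param geometry A [scan_geometry()].
#' @return \code{n_v x n_u} weight matrix, 1 at the central ray and strictly
#'   decreasing with radial distance.
#' @export
cosine_weights <- function(geometry) {
  ctr <- detector_center(geometry)
  u_mm <- ((0:(geometry$n_u - 1)) - ctr["u"] - geometry$axis_offset_px) *
    geometry$pixel_size
  v_mm <- ((0:(geometry$n_v - 1)) - ctr["v"]) * geometry$pixel_size
  U <- matrix(u_mm, geometry$n_v, geometry$n_u, byrow = TRUE)
  V <- matrix(v_mm, geometry$n_v, geometry$n_u)
  geometry$sdd / sqrt(U^2 + V^2 + geometry$sdd^2)
}

#' Apply cosine weighting to an attenuation stack
#'
#' @param stack A [projection_stack()] at stage \code{attenuation}.
#' @param geometry A [scan_geometry()].
#' @return The weighted stack (still stage \code{attenuation}).
#' @export
apply_cosine_weights <- function(stack, geometry) {
  check_stage(stack, "attenuation", "apply_cosine_weights")
  w <- cosine_weights(geometry)
  restage(stack, unclass(stack) * as.vector(w))
}

new_filter_kernel <- function(taps, delta_s, family) {
  structure(list(taps = taps, delta_s = delta_s, family = family,
                 N = (length(taps) - 1L) %/% 2L),
            class = "filter_kernel")
}

#' @export
print.filter_kernel <- function(x, ...) {
  cat(sprintf("%s ramp filter kernel: 2N+1 = %d taps, delta_s = %g mm\n",
              x$family, length(x$taps), x$delta_s))
  invisible(x)
}

#' Discrete Ram-Lak ramp filter kernel (spatial domain)
#'
#' The band-limited ramp filter sampled at interval \eqn{\Delta s}:
#' \deqn{H(n\Delta s) = \begin{cases}
#'   1/(4\Delta s^2) & n = 0\\
#'   0 & n \ \mathrm{even}, n \neq 0\\
#'   -1/(n \pi \Delta s)^2 & n \ \mathrm{odd}
#' \end{cases}}
#' The discrete spatial-domain form avoids the DC offset error of sampling
#' the continuous ramp in the frequency domain.  Taps are indexed
#' \eqn{n = -N \dots N} and symmetric.
#'
#' @param N Kernel half-length (>= 1).
#' @param delta_s Sampling interval \eqn{\Delta s} in mm.
#' @return A \code{filter_kernel} object.
#' @export
ramlak_kernel <- function(N, delta_s = 1) {
  N <- as.integer(N)
  stopifnot(N >= 1L, delta_s > 0)
  n <- -N:N
  taps <- ifelse(n == 0L, 1 / (4 * delta_s^2),
                 ifelse(n %% 2L == 0L, 0, -1 / (n * pi * delta_s)^2))
  new_filter_kernel(taps, delta_s, "ram-lak")
}

#' Discrete Shepp-Logan ramp filter kernel (spatial domain)
#'
#' \deqn{H(n\Delta s) = \frac{-2}{\pi^2 \Delta s^2 (4n^2 - 1)}}
#' for all \eqn{n = -N \dots N}: a ramp filter with a built-in sinc
#' apodization that damps the highest frequencies, trading a little
#' resolution for noise suppression relative to Ram-Lak.
#'
#' @inheritParams ramlak_kernel
#' @return A \code{filter_kernel} object.
#' @export
shepplogan_kernel <- function(N, delta_s = 1) {
  N <- as.integer(N)
  stopifnot(N >= 1L, delta_s > 0)
  n <- -N:N
  taps <- -2 / (pi^2 * delta_s^2 * (4 * n^2 - 1))
  new_filter_kernel(taps, delta_s, "shepp-logan")
}

#' Make a ramp filter kernel by family name
#'
#' Convenience dispatcher; the default half-length N equals the row length so
#' the kernel's support covers the whole (padded) row.
#'
#' @param family \code{"ram-lak"} or \code{"shepp-logan"}.
#' @param n_u Detector row length (sets the default N).
#' @param delta_s Sampling interval in mm.
#' @param N Kernel half-length; default \code{n_u}.
#' @return A \code{filter_kernel}.
#' @export
make_kernel <- function(family = c("ram-lak", "shepp-logan"), n_u,
                        delta_s = 1, N = n_u) {
  family <- match.arg(family)
  switch(family,
         "ram-lak" = ramlak_kernel(N, delta_s),
         "shepp-logan" = shepplogan_kernel(N, delta_s))
}

# Smallest fast FFT length >= n (factors 2 and 3, via stats::nextn).
fft_length <- function(n) stats::nextn(n, factors = c(2L, 3L))

#' Row-wise ramp filtering of a projection stack
#'
#' Convolves every detector row linearly (acyclic) with the kernel taps and
#' multiplies by \eqn{\Delta s}, approximating the continuous ramp-filter
#' integral.  The convolution is evaluated in the frequency domain: row and
#' kernel are zero-padded to at least \eqn{N_f + N_p - 1} samples (filter
#' length plus row length minus one, rounded up to a fast transform size), so
#' the circular product equals the linear convolution; the result is cropped
#' back to the original row, centered on tap n = 0.
#'
#' @param stack A [projection_stack()] at stage \code{attenuation} (already
#'   cosine-weighted in the standard pipeline).
#' @param kernel A \code{filter_kernel} from [ramlak_kernel()],
#'   [shepplogan_kernel()] or [make_kernel()].
#' @return A [projection_stack()] at stage \code{filtered}.
#' @export
filter_rows <- function(stack, kernel) {
  check_stage(stack, "attenuation", "filter_rows")
  stopifnot(inherits(kernel, "filter_kernel"))
  d <- dim(stack)
  n_u <- d[2L]
  nf <- length(kernel$taps)
  L <- fft_length(nf + n_u - 1L)
  N <- kernel$N
  # kernel laid out wrap-around so output index i aligns with tap n = 0
  hp <- numeric(L)
  hp[1:(N + 1L)] <- kernel$taps[(N + 1L):(2L * N + 1L)]
  hp[(L - N + 1L):L] <- kernel$taps[1:N]
  Hf <- stats::fft(hp)
  out <- unclass(stack)
  buf <- matrix(0, L, d[1L])
  for (k in seq_len(d[3L])) {
    buf[] <- 0
    buf[1:n_u, ] <- t(out[, , k])
    Ff <- stats::mvfft(buf) * Hf
    res <- Re(stats::mvfft(Ff, inverse = TRUE)) / L
    out[, , k] <- t(res[1:n_u, , drop = FALSE]) * kernel$delta_s
  }
  restage(stack, out, "filtered")
}
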