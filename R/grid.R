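#' Discretization of the direction ring
#'
#' Direction space is the circle \eqn{[-\pi, \pi)} sampled at `n` equally
#' spaced points \eqn{\theta_k = -\pi + (k-1)\,\Delta\theta},
#' \eqn{\Delta\theta = 2\pi/n}. All profiles (connectivity kernel, external
#' input, activity) live on this grid, and periodic quadrature on it is
#' spectrally accurate for smooth profiles.
#'
#' @param n number of samples on the ring (default 404).
#' @return an object of class `ring_grid` with fields `n`, `theta`
#'   (radians, in \eqn{[-\pi,\pi)}) and `dtheta`.
#' @examples
#' g <- ring_grid(16)
#' sum(rep(1, g$n)) * g$dtheta  # quadrature of 1 over the circle = 2*pi
#' @export
ring_grid <- function(n = 404L) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 8L)
    stop("ring grid needs at least 8 samples, got ", n)
  dtheta <- 2 * pi / n
  structure(
    list(n = n, theta = -pi + (seq_len(n) - 1L) * dtheta, dtheta = dtheta),
    class = "ring_grid"
  )
}

#' @export
print.ring_grid <- function(x, ...) {
  cat(sprintf("<ring_grid> n = %d, spacing = %.4f rad (%.3f deg)\n",
              x$n, x$dtheta, x$dtheta * 180 / pi))
  invisible(x)
}

#' Wrap angles to the principal interval
#'
#' @param x angles in radians.
#' @return angles wrapped to \eqn{[-\pi, \pi)}.
#' @export
wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Degree/radian conversion
#'
#' User-facing angular parameters (peak separation, peak width, kernel
#' widths, directions, tolerances) are degrees; all internal formulas
#' evaluate in radians.
#' @param x angle(s).
#' @return converted angle(s).
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * 180 / pi

#' Smallest angular distance on the circle
#'
#' @param a,b angles in radians (vectorized).
#' @return the absolute distance the short way around, in \[0, \eqn{\pi}\].
#' @export
circ_dist <- function(a, b) {
  abs(wrap_angle(a - b))
}

## shift index: value at grid angle m*dtheta (wrapped), given values on the
## grid starting at -pi.  Used to align kernels for circular convolution.
#' @noRd
shift_to_zero_start <- function(values, n) {
  values[((seq_len(n) - 1L + n %/% 2L) %% n) + 1L]
}
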