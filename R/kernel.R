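## Connectivity kernels: a two-parameter family of difference-of-Gaussians
## (DoG) profiles over direction differences, with local excitation and
## effectively global lateral inhibition, plus the slow inhibition schedule
## used for the temporal-dynamics experiments.

#' Interpolated excitatory surround width
#'
#' The homotopy parameter `alpha` moves the excitatory width linearly from a
#' narrow to a broad bump:
#' \eqn{\sigma_{e}(\alpha) = \sigma_{e_a} + \alpha(\sigma_{e_b} - \sigma_{e_a})}.
#'
#' @param alpha homotopy parameter in \[0, 1\].
#' @param sigma_e_a narrow endpoint, degrees (default 11.5).
#' @param sigma_e_b broad endpoint, degrees (default 60).
#' @return excitatory width in degrees.
#' @export
excitation_width <- function(alpha, sigma_e_a = 11.5, sigma_e_b = 60) {
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1))
    stop("alpha must lie in [0, 1]")
  if (!(sigma_e_a < sigma_e_b))
    stop("sigma_e_a must be smaller than sigma_e_b")
  sigma_e_a + alpha * (sigma_e_b - sigma_e_a)
}

#' Excitatory gain from the surround width
#'
#' \eqn{g_e = \exp(-\sigma_e^2/2)} with the width in radians; strictly
#' decreasing in the width, in (0, 1) for positive widths.
#'
#' @param sigma_e excitatory width in degrees.
#' @return dimensionless excitatory strength.
#' @export
excitation_gain <- function(sigma_e) {
  if (any(!is.finite(sigma_e)) || any(sigma_e <= 0))
    stop("sigma_e must be positive")
  s <- deg2rad(sigma_e)
  exp(-s^2 / 2)
}

#' Inhibitory gain balancing the excitatory gain
#'
#' \eqn{g_i = (1 + g_e)/0.0797}. The constant 0.0797 is the mass of the
#' unit-integral inhibitory Gaussian (\eqn{\sigma_i = 10\pi} rad) on one
#' period of the ring, rounded to four digits; with this choice the integral
#' of the beta = 0 kernel over \eqn{[-\pi,\pi]} is \eqn{-1} up to a residual
#' of order 1e-3 coming from that rounding (see the methods vignette).
#'
#' @param g_e excitatory gain in (0, 1\].
#' @return dimensionless inhibitory strength (> 12.5).
#' @export
inhibition_gain <- function(g_e) {
  if (any(!is.finite(g_e)) || any(g_e <= 0) || any(g_e > 1))
    stop("g_e must lie in (0, 1]")
  (1 + g_e) / 0.0797
}

#' Kernel parameter set
#'
#' Bundles the free connectivity parameters `alpha` (excitation extent) and
#' `beta` (inhibition offset, added to the balanced inhibitory gain) with
#' the fixed widths of the DoG family, and derives `sigma_e`, `g_e`, `g_i`.
#'
#' @param alpha homotopy parameter in \[0, 1\].
#' @param beta inhibition offset, dimensionless, in \[-10, 15\].
#' @param sigma_e_a,sigma_e_b excitatory width endpoints, degrees.
#' @param sigma_i inhibitory width, degrees (default 1800, i.e. 10\eqn{\pi}
#'   radians: effectively uniform inhibition on the ring).
#' @return an object of class `kernel_params`.
#' @examples
#' kp <- kernel_params(alpha = 0, beta = -10)
#' kp$g_e   # ~0.980
#' kp$g_i   # ~24.84
#' @export
kernel_params <- function(alpha = 0, beta = 0, sigma_e_a = 11.5,
                          sigma_e_b = 60, sigma_i = 1800) {
  if (!is.finite(beta) || beta < -10 || beta > 15)
    stop("beta must lie in [-10, 15]")
  if (!is.finite(sigma_i) || deg2rad(sigma_i) <= 2 * pi)
    stop("sigma_i must be much larger than one period (got ", sigma_i, " deg)")
  sigma_e <- excitation_width(alpha, sigma_e_a, sigma_e_b)
  g_e <- excitation_gain(sigma_e)
  structure(
    list(alpha = alpha, beta = beta,
         sigma_e_a = sigma_e_a, sigma_e_b = sigma_e_b, sigma_i = sigma_i,
         sigma_e = sigma_e, g_e = g_e, g_i = inhibition_gain(g_e)),
    class = "kernel_params"
  )
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf(
    "<kernel_params> alpha = %.3g, beta = %.3g | sigma_e = %.2f deg, g_e = %.4f, g_i = %.3f\n",
    x$alpha, x$beta, x$sigma_e, x$g_e, x$g_i))
  invisible(x)
}

## unit-integral (density) Gaussian, evaluated at the wrapped angular
## difference only; for sigma_e <= 60 deg the neglected replicas are < 1e-8,
## and the sigma_i = 10*pi Gaussian is nearly flat on [-pi, pi].
#' @noRd
gauss_density <- function(theta, sigma_rad) {
  stats::dnorm(theta, mean = 0, sd = sigma_rad)
}

#' Build a discretized connectivity kernel
#'
#' Evaluates
#' \eqn{J(\theta) = g_e G(\theta, \sigma_e) - (g_i + \beta) G(\theta, \sigma_i)}
#' on the grid, with `G` the unit-integral Gaussian density and \eqn{\theta}
#' the signed angular difference wrapped to \eqn{[-\pi, \pi)}. The returned
#' object caches the excitatory and inhibitory parts separately (values and
#' FFTs aligned for circular convolution) so that the inhibitory strength
#' can be rescaled cheaply during slow-inhibition simulations.
#'
#' @param params a [kernel_params()] object.
#' @param grid a [ring_grid()].
#' @return an object of class `ring_kernel` with fields `values`, `exc`,
#'   `inh` (values on `grid$theta`), `params`, `grid` and cached FFTs.
#' @export
build_kernel <- function(params, grid) {
  stopifnot(inherits(params, "kernel_params"), inherits(grid, "ring_grid"))
  se <- deg2rad(params$sigma_e)
  si <- deg2rad(params$sigma_i)
  exc <- params$g_e * gauss_density(grid$theta, se)
  inh <- gauss_density(grid$theta, si)
  coef <- params$g_i + params$beta
  ## same profiles re-evaluated at angles m*dtheta (m = 0..n-1, wrapped):
  ## the natural ordering for FFT-based circular convolution.
  th0 <- wrap_angle((seq_len(grid$n) - 1L) * grid$dtheta)
  exc0 <- params$g_e * gauss_density(th0, se)
  inh0 <- gauss_density(th0, si)
  structure(
    list(values = exc - coef * inh, exc = exc, inh = inh,
         fft_exc = stats::fft(exc0), fft_inh = stats::fft(inh0),
         inh_coef = coef, params = params, grid = grid),
    class = "ring_kernel"
  )
}

#' @export
print.ring_kernel <- function(x, ...) {
  cat(sprintf("<ring_kernel> n = %d | peak %.3f, baseline %.4f\n",
              x$grid$n, max(x$values), min(x$values)))
  print(x$params)
  invisible(x)
}

#' @export
plot.ring_kernel <- function(x, ...) {
  graphics::plot(rad2deg(x$grid$theta), x$values, type = "l",
                 xlab = "direction difference (deg)", ylab = "J", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Cosine Fourier coefficient of a kernel
#'
#' \eqn{\int_{-\pi}^{\pi} J(\theta)\cos(m\theta)\,d\theta} by periodic
#' quadrature on the grid. Mode 0 is the kernel integral: \eqn{-1 - 0.0797\beta}
#' up to the rounding residual of the 0.0797 constant.
#'
#' @param kernel a `ring_kernel`.
#' @param mode non-negative integer harmonic.
#' @return the coefficient (a number).
#' @export
kernel_fourier <- function(kernel, mode = 0L) {
  stopifnot(inherits(kernel, "ring_kernel"), mode >= 0)
  sum(kernel$values * cos(mode * kernel$grid$theta)) * kernel$grid$dtheta
}

#' Slow inhibition schedule
#'
#' Inhibition strength rising exponentially from `g_i_low` towards
#' `g_i_final` with time constant `tau_l` after an optional onset delay:
#' \eqn{g_i(t) = g_{i,low} + (g_{i,final} - g_{i,low})
#'   (1 - e^{-\max(t - onset, 0)/\tau_l})}.
#' The asymptote corresponds to the stationary inhibitory coefficient
#' \eqn{g_i + \beta}. The onset delay (default 0) is an extension used to
#' probe how delayed inhibition prolongs the integration (vector-average)
#' phase.
#'
#' @param g_i_final asymptotic inhibition strength.
#' @param g_i_low initial strength (default 0).
#' @param tau_l time constant in ms (default 100).
#' @param onset delay before the ramp starts, ms (default 0).
#' @return an object of class `inhibition_schedule`.
#' @export
inhibition_schedule <- function(g_i_final, g_i_low = 0, tau_l = 100,
                                onset = 0) {
  if (!is.finite(tau_l) || tau_l <= 0) stop("tau_l must be positive")
  if (!is.finite(onset) || onset < 0) stop("onset must be non-negative")
  structure(list(g_i_low = g_i_low, g_i_final = g_i_final,
                 tau_l = tau_l, onset = onset),
            class = "inhibition_schedule")
}

#' Inhibition strength at a given time
#'
#' @param t time in ms (vectorized).
#' @param schedule an [inhibition_schedule()].
#' @return inhibition strength(s), bounded between `g_i_low` and
#'   `g_i_final`, monotone in `t`.
#' @export
inhibition_at_time <- function(t, schedule) {
  stopifnot(inherits(schedule, "inhibition_schedule"))
  if (any(t < 0)) stop("t must be non-negative")
  tt <- pmax(t - schedule$onset, 0)
  schedule$g_i_low +
    (schedule$g_i_final - schedule$g_i_low) * (1 - exp(-tt / schedule$tau_l))
}

#' Export a kernel as a two-column CSV
#'
#' @param kernel a `ring_kernel`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_kernel_csv <- function(kernel, path) {
  stopifnot(inherits(kernel, "ring_kernel"))
  utils::write.csv(
    data.frame(theta_deg = rad2deg(kernel$grid$theta),
               J_value = kernel$values),
    path, row.names = FALSE)
  invisible(path)
}
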