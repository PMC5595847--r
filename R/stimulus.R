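## External drive profiles: uni- and bi-directional motion stimuli encoded
## as Gaussian bumps over motion direction. Peak width (PW) carries the
## direction uncertainty of the front-end motion estimate (narrow for
## random-dot patterns, broad for gratings/plaids); peak separation (PS) is
## the angular difference between the two component directions.

#' Stimulus specification
#'
#' @param ps peak separation in degrees, in (0, 180\] (ignored for
#'   unidirectional stimuli).
#' @param pw peak width (Gaussian SD) in degrees; the documented stimulus
#'   range is 5-30 degrees.
#' @param va_direction pattern (vector-average) direction in degrees; the
#'   two components sit at `va_direction` +/- `ps`/2.
#' @param rel_strength ratio of the weaker to the stronger component in
#'   \[0, 1\]; 1 = symmetric. The stronger component is the one at
#'   `va_direction - ps/2`.
#' @param n_components 1 or 2.
#' @return an object of class `stimulus_spec`.
#' @examples
#' stimulus_spec(ps = 120, pw = 10)
#' @export
stimulus_spec <- function(ps = 120, pw = 10, va_direction = 0,
                          rel_strength = 1, n_components = 2L) {
  n_components <- as.integer(n_components)
  if (!n_components %in% c(1L, 2L)) stop("n_components must be 1 or 2")
  if (!is.finite(pw) || pw <= 0) stop("pw must be positive")
  if (n_components == 2L && (!is.finite(ps) || ps <= 0 || ps > 180))
    stop("ps must lie in (0, 180] degrees")
  if (!is.finite(rel_strength) || rel_strength < 0 || rel_strength > 1)
    stop("rel_strength must lie in [0, 1]")
  structure(list(ps = ps, pw = pw, va_direction = va_direction,
                 rel_strength = rel_strength, n_components = n_components),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  if (x$n_components == 1L) {
    cat(sprintf("<stimulus_spec> unidirectional at %.1f deg, PW = %.1f deg\n",
                x$va_direction, x$pw))
  } else {
    cat(sprintf(
      "<stimulus_spec> bidirectional: VA %.1f deg, PS = %.1f, PW = %.1f, rel = %.2f\n",
      x$va_direction, x$ps, x$pw, x$rel_strength))
  }
  invisible(x)
}

## peak-normalized Gaussian bump with three-replica wrapping (sufficient
## for PW <= 30 deg: the dropped replicas are below 1e-15)
#' @noRd
bump <- function(theta, center, sigma_rad) {
  v <- 0
  for (r in c(-2 * pi, 0, 2 * pi)) {
    v <- v + exp(-(theta - center + r)^2 / (2 * sigma_rad^2))
  }
  v
}

#' Build the external input profile
#'
#' A linear combination of Gaussian bumps, one per motion component, each
#' peak-normalized (amplitude 1 for the stronger component,
#' `rel_strength` for the weaker). Component "strength" scales the bump
#' height, not its area, so uni- and bi-directional drives are comparable
#' at their peaks; an area-normalized variant is available via `normalize`.
#' The overall input gain is applied in the dynamics, not here.
#'
#' @param spec a [stimulus_spec()].
#' @param grid a [ring_grid()].
#' @param normalize `"peak"` (default) or `"area"`.
#' @return an object of class `input_profile` with fields `values`, `spec`,
#'   `grid`.
#' @export
make_input <- function(spec, grid, normalize = c("peak", "area")) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(grid, "ring_grid"))
  normalize <- match.arg(normalize)
  sig <- deg2rad(spec$pw)
  va <- deg2rad(spec$va_direction)
  if (spec$n_components == 1L) {
    centers <- va
    weights <- 1
  } else {
    half <- deg2rad(spec$ps) / 2
    centers <- c(va - half, va + half)
    weights <- c(1, spec$rel_strength)
  }
  values <- numeric(grid$n)
  for (c_i in seq_along(centers)) {
    b <- bump(grid$theta, wrap_angle(centers[c_i]), sig)
    if (normalize == "area") b <- b / (sig * sqrt(2 * pi))
    values <- values + weights[c_i] * b
  }
  structure(list(values = values, spec = spec, grid = grid,
                 normalize = normalize),
            class = "input_profile")
}

#' Rotate an input profile by a grid-aligned angle
#'
#' Circularly shifts the profile by the nearest integer number of grid
#' steps; exact when `delta` is a multiple of the grid spacing. Used for
#' direction sweeps.
#'
#' @param profile an `input_profile`.
#' @param delta rotation in degrees.
#' @return the rotated `input_profile`.
#' @export
rotate_input <- function(profile, delta) {
  stopifnot(inherits(profile, "input_profile"))
  k <- round(deg2rad(delta) / profile$grid$dtheta)
  profile$values <- rotate_values(profile$values, k)
  profile$spec$va_direction <- profile$spec$va_direction +
    rad2deg(k * profile$grid$dtheta)
  profile
}

## circular shift by k grid steps: value at theta_j becomes the value that
## was at theta_{j-k}
#' @noRd
rotate_values <- function(v, k) {
  n <- length(v)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(v)
  c(v[(n - k + 1L):n], v[1L:(n - k)])
}

#' @export
print.input_profile <- function(x, ...) {
  cat(sprintf("<input_profile> n = %d, peak %.3f at %.1f deg\n",
              x$grid$n, max(x$values),
              rad2deg(x$grid$theta[which.max(x$values)])))
  print(x$spec)
  invisible(x)
}

#' @export
plot.input_profile <- function(x, ...) {
  graphics::plot(rad2deg(x$grid$theta), x$values, type = "l",
                 xlab = "direction (deg)", ylab = "I_ext", ...)
  invisible(x)
}

#' Export an input profile as CSV
#' @param profile an `input_profile`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_input_csv <- function(profile, path) {
  stopifnot(inherits(profile, "input_profile"))
  utils::write.csv(
    data.frame(theta_deg = rad2deg(profile$grid$theta),
               I_value = profile$values),
    path, row.names = FALSE)
  invisible(path)
}
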