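## shared fixtures: small networks keep the unit tests fast; the acceptance
## file builds its own problem sizes

small_grid <- function(n = 64) ring_grid(n)

## the segmentation-capable kernel regime used throughout (narrow
## excitation, strong relative inhibition)
seg_model <- function(n = 64, alpha = 0, beta = -10, ...) {
  ring_network(kernel_params(alpha = alpha, beta = beta),
               network_params(...), ring_grid(n))
}

## pointwise kernel evaluation (independent re-derivation used as oracle)
kernel_value <- function(kp, theta, inh_coef = kp$g_i + kp$beta) {
  gauss <- function(x, s) exp(-x^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  kp$g_e * gauss(theta, deg2rad(kp$sigma_e)) -
    inh_coef * gauss(theta, deg2rad(kp$sigma_i))
}

## dense O(n^2) quadrature of int J(theta_i - phi) v(phi) dphi, the oracle
## for the FFT convolution path
dense_conv <- function(kernel, v, inh_coef = kernel$inh_coef) {
  grid <- kernel$grid
  n <- grid$n
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- wrap_angle(grid$theta[i] - grid$theta)
    m[i, ] <- kernel_value(kernel$params, d, inh_coef)
  }
  as.numeric(m %*% v) * grid$dtheta
}

## synthetic wrapped Gaussian bump profile on a grid (degrees)
bump_profile <- function(grid, center_deg, width_deg = 15, height = 1) {
  d <- circ_dist(grid$theta, deg2rad(center_deg))
  height * exp(-d^2 / (2 * deg2rad(width_deg)^2))
}
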