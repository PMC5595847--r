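## The rate dynamics of the ring: an Amari-type neural field equation
##
##   tau_p du/dt = -u(theta) + Int J(theta - phi) S(mu u(phi), th) dphi
##                 + kappa_i I_ext(theta)
##
## with a bounded sigmoidal rate function that vanishes at u = 0. The
## recurrent term is a circular convolution, computed by FFT on the grid
## (spectrally accurate periodic quadrature).

#' Network (dynamics) parameters
#'
#' @param mu sigmoid gain (default 16).
#' @param th sigmoid threshold (default 3).
#' @param kappa_i input gain (default 0.1).
#' @param tau_p population time constant in ms (default 1; 5 and 10 are the
#'   other documented settings).
#' @param noise_eps additive white-noise amplitude for stochastic runs
#'   (default 0 = deterministic; stochastic experiments use 0.01 unless
#'   stated otherwise).
#' @param dt Euler-Maruyama step in ms (default 0.1).
#' @param ic_amp amplitude of the low random initial activity: initial
#'   conditions are iid uniform on \[0, `ic_amp`\] (default 0.1).
#' @return an object of class `network_params`.
#' @export
network_params <- function(mu = 16, th = 3, kappa_i = 0.1, tau_p = 1,
                           noise_eps = 0, dt = 0.1, ic_amp = 0.1) {
  if (mu <= 0 || th <= 0) stop("mu and th must be positive")
  if (tau_p <= 0) stop("tau_p must be positive")
  if (noise_eps < 0) stop("noise_eps must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  structure(list(mu = mu, th = th, kappa_i = kappa_i, tau_p = tau_p,
                 noise_eps = noise_eps, dt = dt, ic_amp = ic_amp),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(
    "<network_params> mu = %g, th = %g, kappa_i = %g, tau_p = %g ms, noise_eps = %g\n",
    x$mu, x$th, x$kappa_i, x$tau_p, x$noise_eps))
  invisible(x)
}

#' Ring network model object
#'
#' Convenience container bundling the connectivity kernel, the dynamics
#' parameters and the grid; most operations accept it in place of the
#' individual pieces.
#'
#' @param kernel_params a [kernel_params()] object (or a prebuilt
#'   `ring_kernel`).
#' @param network_params a [network_params()] object.
#' @param grid a [ring_grid()].
#' @return an object of class `ring_network`.
#' @examples
#' net <- ring_network(kernel_params(alpha = 0, beta = -10))
#' net
#' @export
ring_network <- function(kernel_params = mtring::kernel_params(),
                         network_params = mtring::network_params(),
                         grid = ring_grid()) {
  kernel <- if (inherits(kernel_params, "ring_kernel")) kernel_params
            else build_kernel(kernel_params, grid)
  stopifnot(inherits(network_params, "network_params"))
  structure(list(kernel = kernel, np = network_params, grid = kernel$grid),
            class = "ring_network")
}

#' @export
print.ring_network <- function(x, ...) {
  cat("Ring network model\n")
  print(x$kernel$params)
  print(x$np)
  cat(sprintf("  grid: n = %d\n", x$grid$n))
  invisible(x)
}

#' Bounded sigmoidal rate function
#'
#' \eqn{S(u) = 1/(1 + e^{-\mu u + th}) - 1/(1 + e^{th})}: strictly
#' increasing, zero at `u = 0`, bounded above by \eqn{1 - 1/(1+e^{th})}.
#' Overflow-safe via `plogis`.
#'
#' @param u activity (membrane-potential-like variable), vectorized.
#' @param mu sigmoid gain.
#' @param th sigmoid threshold.
#' @return firing rate(s).
#' @export
sigmoid <- function(u, mu = 16, th = 3) {
  stats::plogis(mu * u - th) - stats::plogis(-th)
}

#' @rdname sigmoid
#' @details `sigmoid_deriv` is the derivative with respect to `u`, used in
#'   Jacobians: \eqn{\mu\,\sigma(\mu u - th)(1 - \sigma(\mu u - th))}.
#' @export
sigmoid_deriv <- function(u, mu = 16, th = 3) {
  p <- stats::plogis(mu * u - th)
  mu * p * (1 - p)
}

#' Circular convolution of a kernel with an activity profile
#'
#' Computes \eqn{(J * v)(\theta_j) = \sum_k J(\theta_j - \theta_k) v_k
#' \Delta\theta} by FFT. The inhibitory part of the kernel can be rescaled
#' through `inh_coef` without rebuilding the kernel (used by the
#' slow-inhibition dynamics).
#'
#' @param kernel a `ring_kernel`.
#' @param v vector on the kernel's grid.
#' @param inh_coef inhibitory coefficient \eqn{g_i + \beta}; defaults to the
#'   kernel's stationary value.
#' @return the convolved vector.
#' @export
ring_conv <- function(kernel, v, inh_coef = kernel$inh_coef) {
  n <- kernel$grid$n
  fk <- kernel$fft_exc - inh_coef * kernel$fft_inh
  Re(stats::fft(fk * stats::fft(v), inverse = TRUE)) / n * kernel$grid$dtheta
}

#' Dense convolution operator of a kernel
#'
#' The circulant matrix `C` with `C[j, k] = J(theta_j - theta_k) * dtheta`,
#' so that `C %*% S(u)` equals the recurrent integral. Returned as separate
#' excitatory and inhibitory parts (list with `exc`, `inh`, and `C` for the
#' stationary coefficient) so continuation in `beta` and ramped inhibition
#' reuse them.
#'
#' @param kernel a `ring_kernel`.
#' @return list with dense matrices `exc`, `inh` and `C`.
#' @export
conv_matrix <- function(kernel) {
  n <- kernel$grid$n
  idx <- outer(seq_len(n), seq_len(n), function(j, k) ((j - k) %% n) + 1L)
  th0 <- wrap_angle((seq_len(n) - 1L) * kernel$grid$dtheta)
  p <- kernel$params
  exc0 <- p$g_e * gauss_density(th0, deg2rad(p$sigma_e))
  inh0 <- gauss_density(th0, deg2rad(p$sigma_i))
  exc <- matrix(exc0[idx], n, n) * kernel$grid$dtheta
  inh <- matrix(inh0[idx], n, n) * kernel$grid$dtheta
  list(exc = exc, inh = inh, C = exc - kernel$inh_coef * inh)
}

#' Right-hand side of the neural field equation
#'
#' @param u state vector on the grid.
#' @param kernel a `ring_kernel`.
#' @param input an `input_profile` (or numeric vector) on the same grid.
#' @param np a [network_params()].
#' @param inh_coef optional time-varying inhibitory coefficient.
#' @return du/dt as a vector.
#' @export
field_rhs <- function(u, kernel, input, np, inh_coef = kernel$inh_coef) {
  iv <- input_values(input, kernel$grid, length(u))
  (-u + ring_conv(kernel, sigmoid(u, np$mu, np$th), inh_coef) +
     np$kappa_i * iv) / np$tau_p
}

#' @noRd
input_values <- function(input, grid, n) {
  if (inherits(input, "input_profile")) {
    if (input$grid$n != grid$n)
      stop("input and kernel are on different grids (",
           input$grid$n, " vs ", grid$n, " samples)")
    input$values
  } else if (is.numeric(input)) {
    if (length(input) != n) stop("input vector length does not match grid")
    input
  } else stop("input must be an input_profile or a numeric vector")
}

#' Grid-weighted l2 norm of an activity profile
#'
#' \eqn{\sqrt{\sum_k u_k^2 \Delta\theta}}: the discrete L2 norm over the
#' ring, used as the scalar "network energy" of a steady state for
#' bifurcation-diagram projections.
#'
#' @param u state vector.
#' @param grid a [ring_grid()].
#' @return a number.
#' @export
energy <- function(u, grid) {
  sqrt(sum(u^2) * grid$dtheta)
}

#' Integrate the ring dynamics
#'
#' Deterministic runs (`noise_eps = 0`) use an adaptive stiff solver
#' (`deSolve::ode`, `lsoda`, absolute tolerance 1e-12, analytic Jacobian);
#' stochastic runs use fixed-step Euler-Maruyama with additive white noise
#' `noise_eps * sqrt(dt) * N(0,1)` per node per step. A time-varying
#' inhibition `schedule` may replace the kernel's stationary inhibitory
#' coefficient.
#'
#' @param model a [ring_network()] object.
#' @param input an `input_profile` or numeric vector.
#' @param u0 initial state; default low random activity, iid uniform on
#'   \[0, `ic_amp`\].
#' @param t_end end time in ms.
#' @param record_every recording interval in ms (default `t_end`/200).
#' @param schedule optional [inhibition_schedule()].
#' @param seed optional RNG seed (initial condition and noise).
#' @param method `"auto"` picks deterministic vs Euler-Maruyama from
#'   `noise_eps`; `"em"` forces Euler-Maruyama.
#' @return an object of class `trajectory` with fields `times`, `states`
#'   (n x length(times) matrix), `final_residual`, `converged`.
#' @export
integrate_field <- function(model, input, u0 = NULL, t_end = 500,
                            record_every = NULL, schedule = NULL,
                            seed = NULL, method = c("auto", "em")) {
  stopifnot(inherits(model, "ring_network"), t_end > 0)
  method <- match.arg(method)
  kernel <- model$kernel; np <- model$np; n <- model$grid$n
  if (!is.null(seed)) set.seed(seed)
  if (is.null(u0)) u0 <- stats::runif(n, 0, np$ic_amp)
  if (is.null(record_every)) record_every <- t_end / 200
  iv <- input_values(input, model$grid, n)
  coef_at <- if (is.null(schedule)) {
    function(t) kernel$inh_coef
  } else {
    function(t) inhibition_at_time(t, schedule)
  }
  times <- unique(c(seq(0, t_end, by = record_every), t_end))

  if (np$noise_eps > 0 || method == "em") {
    states <- em_path(u0, kernel, iv, np, coef_at, times, t_end)
  } else {
    cm <- conv_matrix(kernel)
    rhs_fn <- function(t, u, parms) {
      list((-u + ring_conv(kernel, sigmoid(u, np$mu, np$th), coef_at(t)) +
              np$kappa_i * iv) / np$tau_p)
    }
    jac_fn <- function(t, u, parms) {
      C <- cm$exc - coef_at(t) * cm$inh
      J <- C * rep(sigmoid_deriv(u, np$mu, np$th), each = n)
      diag(J) <- diag(J) - 1
      J / np$tau_p
    }
    sol <- deSolve::ode(y = u0, times = times, func = rhs_fn, parms = NULL,
                        method = "lsoda", atol = 1e-12, rtol = 1e-8,
                        jacfunc = jac_fn, jactype = "fullusr")
    if (any(!is.finite(sol)))
      stop("integration diverged (non-finite state before t = ", t_end, ")")
    states <- t(unname(sol[, -1, drop = FALSE]))
  }
  u_end <- states[, ncol(states)]
  if (any(!is.finite(u_end)))
    stop("integration diverged: max|u| = ", max(abs(states), na.rm = TRUE),
         " before t = ", t_end)
  res <- max(abs(field_rhs(u_end, kernel, iv, np, coef_at(t_end))))
  structure(list(times = times, states = states, model = model,
                 input = input, schedule = schedule,
                 final_residual = res, converged = res < 1e-6),
            class = "trajectory")
}

#' @noRd
em_path <- function(u0, kernel, iv, np, coef_at, record_times, t_end) {
  dt <- np$dt
  n_steps <- ceiling(t_end / dt)
  u <- u0
  n <- length(u0)
  states <- matrix(NA_real_, n, length(record_times))
  rec <- 1L
  t <- 0
  if (record_times[1] <= 0) { states[, 1] <- u; rec <- 2L }
  sq <- np$noise_eps * sqrt(dt)
  for (s in seq_len(n_steps)) {
    du <- (-u + ring_conv(kernel, sigmoid(u, np$mu, np$th), coef_at(t)) +
             np$kappa_i * iv) / np$tau_p
    u <- u + dt * du
    if (sq > 0) u <- u + sq * stats::rnorm(n)
    t <- t + dt
    if (!all(is.finite(u)))
      stop("Euler-Maruyama diverged at t = ", t, " ms")
    while (rec <= length(record_times) && record_times[rec] <= t + 1e-9) {
      states[, rec] <- u
      rec <- rec + 1L
    }
  }
  if (rec <= length(record_times)) states[, rec:length(record_times)] <- u
  states
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d nodes, t in [0, %g] ms (%d records), final residual %.2e%s\n",
    nrow(x$states), max(x$times), length(x$times), x$final_residual,
    if (x$converged) ", converged" else ""))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ...) {
  graphics::image(x$times, rad2deg(x$model$grid$theta), t(x$states),
                  xlab = "time (ms)", ylab = "direction (deg)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Simulate trajectories from a ring network
#'
#' `simulate` method: runs `nsim` independent simulations (fresh random
#' initial conditions, and noise paths if `noise_eps > 0`).
#'
#' @param object a [ring_network()].
#' @param nsim number of trajectories.
#' @param seed RNG seed.
#' @param input an `input_profile` (required).
#' @param ... passed to [integrate_field()].
#' @return a list of `trajectory` objects.
#' @export
simulate.ring_network <- function(object, nsim = 1, seed = NULL, input, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) integrate_field(object, input, ...))
}

#' Find a steady state of the driven network
#'
#' Integrates deterministically in chunks until the max-norm of the
#' right-hand side falls below `tol_ss` (or `t_max` is reached), then
#' polishes with a damped Newton solve of the fixed-point equation. A
#' failure to converge is reported through the `converged` flag, not an
#' error, so attractor statistics can tally it.
#'
#' @param model a [ring_network()].
#' @param input an `input_profile` or vector.
#' @param u0 initial state (default: low random activity).
#' @param tol_ss convergence tolerance on the residual max-norm
#'   (default 1e-9).
#' @param t_max maximum integration time in ms (default 2000).
#' @param chunk integration chunk length in ms.
#' @param seed optional RNG seed for the initial condition.
#' @param stochastic if `TRUE` and `noise_eps > 0`, a noisy Euler-Maruyama
#'   transient of length `t_settle` ms precedes the deterministic
#'   convergence phase (trial-to-trial variability for attractor sampling).
#' @param t_settle length of the noisy transient, ms (default 200).
#' @return an object of class `steady_state` with fields `u_star`,
#'   `residual`, `energy`, `provenance`, `converged`.
#' @export
find_steady_state <- function(model, input, u0 = NULL, tol_ss = 1e-9,
                              t_max = 2000, chunk = 50, seed = NULL,
                              stochastic = FALSE, t_settle = 200) {
  stopifnot(inherits(model, "ring_network"))
  np <- model$np; n <- model$grid$n
  if (!is.null(seed)) set.seed(seed)
  if (is.null(u0)) u0 <- stats::runif(n, 0, np$ic_amp)
  iv <- input_values(input, model$grid, n)
  u <- u0
  if (stochastic && np$noise_eps > 0) {
    tr <- integrate_field(model, iv, u0 = u, t_end = t_settle,
                          record_every = t_settle, method = "em")
    u <- tr$states[, ncol(tr$states)]
  }
  det_model <- model
  det_model$np$noise_eps <- 0
  t_done <- 0
  res <- max(abs(field_rhs(u, model$kernel, iv, np)))
  while (res > tol_ss && t_done < t_max) {
    tr <- integrate_field(det_model, iv, u0 = u, t_end = chunk,
                          record_every = chunk)
    u <- tr$states[, ncol(tr$states)]
    res <- tr$final_residual
    t_done <- t_done + chunk
    chunk <- min(2 * chunk, 400)
  }
  ns <- newton_steady_state(u, model$kernel, iv, np, tol = min(tol_ss, 1e-10))
  if (ns$converged) {
    u <- ns$u; res <- ns$residual
    prov <- "newton"
  } else prov <- "integration"
  structure(list(u_star = u, residual = res,
                 energy = energy(u, model$grid),
                 provenance = prov, converged = res < tol_ss,
                 model = model, input = input),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf(
    "<steady_state> energy %.4f, residual %.2e (%s)%s\n",
    x$energy, x$residual, x$provenance,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
plot.steady_state <- function(x, ...) {
  graphics::plot(rad2deg(x$model$grid$theta), x$u_star, type = "l",
                 xlab = "preferred direction (deg)", ylab = "u*", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Export a steady state as a CSV tuning curve
#' @param ss a `steady_state`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_steady_state_csv <- function(ss, path) {
  stopifnot(inherits(ss, "steady_state"))
  utils::write.csv(
    data.frame(theta_deg = rad2deg(ss$model$grid$theta), u = ss$u_star),
    path, row.names = FALSE)
  invisible(path)
}
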