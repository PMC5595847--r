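## Steady-state continuation. The fixed-point map
##   F(u; p) = -u + C S(u) + kappa_i I(p)
## (C the dense circulant convolution operator) is solved by damped Newton
## with the analytic Jacobian -I + C diag(S'(u)); branches are tracked in a
## single parameter by pseudo-arclength predictor-corrector steps (secant
## predictor, Newton corrector on the bordered system), continuing around
## folds. Stability comes from the eigenvalues of the Jacobian scaled by
## 1/tau_p; continuation always runs noise-free.

#' Damped Newton solve of the steady-state equation
#'
#' @param u_guess starting state on the grid.
#' @param kernel a `ring_kernel`.
#' @param input an `input_profile` or numeric vector.
#' @param np a [network_params()].
#' @param tol residual max-norm demanded for success (default 1e-10).
#' @param max_iter iteration cap.
#' @param cm optional precomputed [conv_matrix()] of `kernel`.
#' @param inh_coef optional inhibitory coefficient override.
#' @param kappa_i optional input-gain override (used when continuing in
#'   the input gain).
#' @return list with `u`, `residual`, `iterations`, `converged`.
#' @export
newton_steady_state <- function(u_guess, kernel, input, np, tol = 1e-10,
                                max_iter = 50, cm = NULL,
                                inh_coef = kernel$inh_coef,
                                kappa_i = np$kappa_i) {
  n <- length(u_guess)
  iv <- input_values(input, kernel$grid, n)
  if (is.null(cm)) cm <- conv_matrix(kernel)
  C <- cm$exc - inh_coef * cm$inh
  Ffun <- function(u) -u + C %*% sigmoid(u, np$mu, np$th) + kappa_i * iv
  u <- u_guess
  Fu <- Ffun(u)
  res <- max(abs(Fu))
  for (it in seq_len(max_iter)) {
    if (res < tol)
      return(list(u = as.numeric(u), residual = res, iterations = it - 1L,
                  converged = TRUE))
    J <- C * rep(sigmoid_deriv(u, np$mu, np$th), each = n)
    diag(J) <- diag(J) - 1
    step <- tryCatch(solve(J, -Fu), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      u_new <- u + lambda * step
      F_new <- Ffun(u_new)
      if (max(abs(F_new)) < res || lambda < 1 / 64) break
      lambda <- lambda / 2
    }
    if (max(abs(F_new)) >= res && lambda < 1 / 64) break
    u <- u_new; Fu <- F_new; res <- max(abs(Fu))
  }
  list(u = as.numeric(u), residual = res, iterations = max_iter,
       converged = res < tol)
}

#' Jacobian of the dynamics at a state
#'
#' \eqn{(-I + C\,\mathrm{diag}(S'(u)))/\tau_p}; its eigenvalues determine
#' linear stability of a steady state.
#'
#' @param u state vector.
#' @param kernel a `ring_kernel`.
#' @param np a [network_params()].
#' @param cm optional precomputed [conv_matrix()].
#' @param inh_coef optional inhibitory coefficient override.
#' @return dense Jacobian matrix.
#' @export
field_jacobian <- function(u, kernel, np, cm = NULL,
                           inh_coef = kernel$inh_coef) {
  n <- length(u)
  if (is.null(cm)) cm <- conv_matrix(kernel)
  C <- cm$exc - inh_coef * cm$inh
  J <- C * rep(sigmoid_deriv(u, np$mu, np$th), each = n)
  diag(J) <- diag(J) - 1
  J / np$tau_p
}

## leading eigenvalue real parts, total and restricted to the odd
## (antisymmetric about va) subspace; va in radians
#' @noRd
leading_eigs <- function(J, grid, va = 0) {
  e <- eigen(J, only.values = FALSE)
  re <- Re(e$values)
  ## odd/even character of each eigenvector about the reflection axis va
  refl <- reflect_index(grid, va)
  odd_score <- vapply(seq_along(re), function(k) {
    v <- Re(e$vectors[, k])
    s <- sqrt(sum(v^2))
    if (s == 0) return(0)
    sum(abs(v + v[refl])) / (2 * sum(abs(v)))  # 0 = perfectly odd
  }, numeric(1))
  is_odd <- odd_score < 0.25
  list(max_re = max(re),
       max_re_odd = if (any(is_odd)) max(re[is_odd]) else -Inf,
       crit_vec = Re(e$vectors[, which.max(re)]),
       crit_vec_odd = if (any(is_odd))
         Re(e$vectors[, which(is_odd)[which.max(re[is_odd])]]) else NULL)
}

## index permutation implementing reflection theta -> 2*va - theta on the
## grid (exact when va is a multiple of dtheta/2, which covers va = 0)
#' @noRd
reflect_index <- function(grid, va = 0) {
  target <- wrap_angle(2 * va - grid$theta)
  idx <- round((target - grid$theta[1]) / grid$dtheta) %% grid$n + 1L
  as.integer(idx)
}

#' Continue a steady-state branch in one parameter
#'
#' Pseudo-arclength continuation: a secant (first step: tangent) predictor
#' followed by a Newton corrector on the bordered system, with adaptive
#' step length; folds are traversed. Supported parameters: `"ps"`, `"pw"`
#' (stimulus geometry), `"kappa_i"` (input gain) and `"beta"` (inhibition
#' offset). At each accepted point the energy, the leading eigenvalue of
#' the scaled Jacobian and a stability flag are recorded, along with the
#' leading eigenvalue restricted to odd (symmetry-breaking) modes when the
#' stimulus is symmetric.
#'
#' @param model a [ring_network()].
#' @param spec the [stimulus_spec()] template (its `parameter` field is
#'   overridden along the branch).
#' @param u_start converged steady state at `p_from` (vector or
#'   `steady_state`).
#' @param parameter one of `"ps"`, `"pw"`, `"kappa_i"`, `"beta"`.
#' @param p_from,p_to parameter range endpoints (degrees for ps/pw).
#' @param ds0 initial arclength step (default 2).
#' @param ds_max maximal step.
#' @param ds_min floor below which the branch is truncated.
#' @param max_steps cap on accepted points.
#' @param stability_margin a point is stable when the leading eigenvalue
#'   real part is below `-stability_margin` (default 1e-8).
#' @param track_odd compute odd-mode eigenvalues (pitchfork detection on
#'   symmetric branches); default TRUE when `rel_strength == 1`.
#' @param p_limits optional c(lo, hi) stopping bounds for the parameter;
#'   defaults to `range(p_from, p_to)`. Useful when a branch is expected
#'   to fold back past its starting value.
#' @return an object of class `branch`: data frame `points` (columns
#'   `p`, `energy`, `max_re`, `max_re_odd`, `stable`), matrix `states`
#'   (one column per point), and bookkeeping fields.
#' @export
continue_branch <- function(model, spec, u_start, parameter = "ps",
                            p_from, p_to, ds0 = 2, ds_max = 6,
                            ds_min = 1e-4, max_steps = 400,
                            stability_margin = 1e-8, track_odd = NULL,
                            p_limits = NULL) {
  stopifnot(inherits(model, "ring_network"))
  if (inherits(u_start, "steady_state")) u_start <- u_start$u_star
  parameter <- match.arg(parameter, c("ps", "pw", "kappa_i", "beta"))
  np <- model$np; kernel <- model$kernel; grid <- model$grid
  n <- grid$n
  cm <- conv_matrix(kernel)
  if (is.null(track_odd)) track_odd <- isTRUE(spec$rel_strength == 1)
  va <- deg2rad(spec$va_direction)

  setter <- switch(parameter,
    ps = function(p) list(iv = make_input(modify_spec(spec, ps = p), grid)$values,
                          coef = kernel$inh_coef, kap = np$kappa_i),
    pw = function(p) list(iv = make_input(modify_spec(spec, pw = p), grid)$values,
                          coef = kernel$inh_coef, kap = np$kappa_i),
    kappa_i = function(p) list(iv = make_input(spec, grid)$values,
                               coef = kernel$inh_coef, kap = p),
    beta = function(p) list(iv = make_input(spec, grid)$values,
                            coef = kernel$params$g_i + p, kap = np$kappa_i))

  Ffun <- function(u, p) {
    st <- setter(p)
    C <- cm$exc - st$coef * cm$inh
    as.numeric(-u + C %*% sigmoid(u, np$mu, np$th) + st$kap * st$iv)
  }
  Jfun <- function(u, p) {
    st <- setter(p)
    C <- cm$exc - st$coef * cm$inh
    J <- C * rep(sigmoid_deriv(u, np$mu, np$th), each = n)
    diag(J) <- diag(J) - 1
    J
  }
  Fp <- function(u, p) {
    h <- max(1e-5 * max(abs(p), 1), 1e-7)
    (Ffun(u, p + h) - Ffun(u, p - h)) / (2 * h)
  }
  ## scale the state part of the arclength metric so p (often tens of
  ## degrees) and u (order 1) contribute comparably
  w_u <- 1

  corrector <- function(u, p, tu, tp, u_pred, p_pred, tol = 1e-10,
                        max_iter = 12) {
    for (it in seq_len(max_iter)) {
      Fv <- Ffun(u, p)
      g <- w_u * sum(tu * (u - u_pred)) + tp * (p - p_pred)
      res <- max(abs(Fv))
      if (res < tol && abs(g) < 1e-10)
        return(list(u = u, p = p, converged = TRUE, res = res, iter = it - 1L))
      A <- rbind(cbind(Jfun(u, p), Fp(u, p)), c(w_u * tu, tp))
      step <- tryCatch(solve(A, -c(Fv, g)), error = function(e) NULL)
      if (is.null(step)) return(list(converged = FALSE))
      u <- u + step[seq_len(n)]
      p <- p + step[n + 1L]
      if (!all(is.finite(u))) return(list(converged = FALSE))
    }
    Fv <- Ffun(u, p)
    list(u = u, p = p, converged = max(abs(Fv)) < 1e-8,
         res = max(abs(Fv)), iter = max_iter)
  }

  ## make sure the start point is converged
  st0 <- setter(p_from)
  ns <- newton_steady_state(u_start, kernel, st0$iv, np, cm = cm,
                            inh_coef = st0$coef, kappa_i = st0$kap)
  if (!ns$converged) stop("start point failed to converge at ", parameter,
                          " = ", p_from)
  u <- ns$u; p <- p_from

  ## initial tangent from the parameter derivative
  du_dp <- tryCatch(solve(Jfun(u, p), -Fp(u, p)), error = function(e) NULL)
  if (is.null(du_dp)) stop("singular Jacobian at the branch start")
  nr <- sqrt(w_u * sum(du_dp^2) + 1)
  tu <- du_dp / nr; tp <- 1 / nr
  if (sign(p_to - p_from) < 0) { tu <- -tu; tp <- -tp }

  pts <- list(); states <- list()
  record <- function(u, p) {
    J <- Jfun(u, p) / np$tau_p
    if (track_odd) {
      le <- leading_eigs(J, grid, va)
      mo <- le$max_re_odd
      mr <- le$max_re
    } else {
      mr <- max(Re(eigen(J, only.values = TRUE)$values))
      mo <- NA_real_
    }
    list(p = p, energy = energy(u, grid), max_re = mr, max_re_odd = mo,
         stable = mr < -stability_margin)
  }
  pts[[1]] <- record(u, p); states[[1]] <- u

  ds <- ds0
  if (is.null(p_limits)) p_limits <- range(c(p_from, p_to))
  lo <- p_limits[1]; hi <- p_limits[2]
  step_i <- 1L
  while (step_i < max_steps) {
    u_pred <- u + ds * tu
    p_pred <- p + ds * tp
    cr <- corrector(u_pred, p_pred, tu, tp, u_pred, p_pred)
    if (!isTRUE(cr$converged)) {
      ds <- ds / 2
      if (ds < ds_min) break
      next
    }
    du <- cr$u - u; dp <- cr$p - p
    nr <- sqrt(w_u * sum(du^2) + dp^2)
    if (nr == 0) break
    if (nr > 3 * ds) {
      ## the corrector leapt to a distant solution (branch jump, typical
      ## near folds where the Newton basin shrinks): reject and refine
      ds <- ds / 2
      if (ds < ds_min) break
      next
    }
    tu <- du / nr; tp <- dp / nr
    u <- cr$u; p <- cr$p
    step_i <- step_i + 1L
    pts[[step_i]] <- record(u, p)
    states[[step_i]] <- u
    if (cr$iter <= 3) ds <- min(ds * 1.3, ds_max)
    if (p < lo - 1e-9 || p > hi + 1e-9) break
  }

  points <- do.call(rbind, lapply(pts, function(q)
    data.frame(p = q$p, energy = q$energy, max_re = q$max_re,
               max_re_odd = q$max_re_odd, stable = q$stable)))
  structure(list(points = points, states = do.call(cbind, states),
                 parameter = parameter, spec = spec, model = model,
                 special_points = NULL,
                 stability_margin = stability_margin),
            class = "branch")
}

#' @noRd
modify_spec <- function(spec, ...) {
  mods <- list(...)
  for (nm in names(mods)) spec[[nm]] <- mods[[nm]]
  spec
}

#' @export
print.branch <- function(x, ...) {
  rng <- range(x$points$p)
  cat(sprintf(
    "<branch> parameter %s in [%.2f, %.2f], %d points (%d stable)\n",
    x$parameter, rng[1], rng[2], nrow(x$points), sum(x$points$stable)))
  if (!is.null(x$special_points) && nrow(x$special_points) > 0) {
    for (i in seq_len(nrow(x$special_points)))
      cat(sprintf("  %s at %s = %.2f\n", x$special_points$type[i],
                  x$parameter, x$special_points$p[i]))
  }
  invisible(x)
}

#' @export
plot.branch <- function(x, add = FALSE, col_stable = "black",
                        col_unstable = "grey50", ...) {
  pts <- x$points
  if (!add)
    graphics::plot(pts$p, pts$energy, type = "n", xlab = x$parameter,
                   ylab = "energy (l2 norm)", ...)
  seg_col <- ifelse(pts$stable[-1] & pts$stable[-nrow(pts)],
                    col_stable, col_unstable)
  graphics::segments(pts$p[-nrow(pts)], pts$energy[-nrow(pts)],
                     pts$p[-1], pts$energy[-1], col = seg_col,
                     lty = ifelse(seg_col == col_stable, 1, 2))
  invisible(x)
}

#' Detect folds and symmetry-breaking branch points along a branch
#'
#' Folds are flagged where the continuation parameter reverses direction
#' along arclength (refined by a quadratic fit of the parameter against
#' arclength through the turning point). Branch points (pitchforks) are
#' flagged on symmetric branches where the leading odd-mode eigenvalue
#' crosses zero, refined by bisection in the parameter with Newton
#' correction from interpolated states.
#'
#' @param branch a `branch` from [continue_branch()].
#' @param refine_tol parameter tolerance of the bisection refinement
#'   (default 0.5).
#' @return the branch with a `special_points` data frame (`type`, `p`,
#'   `index`) attached.
#' @export
detect_special_points <- function(branch, refine_tol = 0.5) {
  pts <- branch$points
  if (nrow(pts) < 3) { branch$special_points <- empty_special(); return(branch) }
  sp <- list()
  dp <- diff(pts$p)
  ## folds: sign reversal of dp
  for (k in seq_len(length(dp) - 1L)) {
    if (dp[k] != 0 && dp[k + 1] != 0 && sign(dp[k]) != sign(dp[k + 1])) {
      idx <- (max(1, k):min(nrow(pts), k + 2))
      s <- c(0, cumsum(sqrt(diff(pts$p[idx])^2 +
                              diff(pts$energy[idx])^2)))
      fit <- tryCatch(stats::lm(pts$p[idx] ~ s + I(s^2)),
                      error = function(e) NULL)
      p_fold <- pts$p[k + 1]
      if (!is.null(fit) && length(stats::coef(fit)) == 3 &&
          is.finite(stats::coef(fit)[3]) && stats::coef(fit)[3] != 0) {
        b <- stats::coef(fit)
        s_v <- -b[2] / (2 * b[3])
        if (s_v >= min(s) && s_v <= max(s))
          p_fold <- unname(b[1] + b[2] * s_v + b[3] * s_v^2)
      }
      sp[[length(sp) + 1L]] <- data.frame(type = "fold", p = p_fold,
                                          index = k + 1L)
    }
  }
  ## branch points: odd-mode eigenvalue zero crossing
  mo <- pts$max_re_odd
  if (!all(is.na(mo))) {
    for (k in seq_len(nrow(pts) - 1L)) {
      if (is.na(mo[k]) || is.na(mo[k + 1])) next
      if (is.finite(mo[k]) && is.finite(mo[k + 1]) &&
          sign(mo[k]) != sign(mo[k + 1]) && mo[k] != 0) {
        p_bp <- refine_branch_point(branch, k, refine_tol)
        sp[[length(sp) + 1L]] <- data.frame(type = "branch_point", p = p_bp,
                                            index = k)
      }
    }
  }
  branch$special_points <- if (length(sp)) do.call(rbind, sp)
                           else empty_special()
  branch
}

#' @noRd
empty_special <- function() {
  data.frame(type = character(), p = numeric(), index = integer())
}

## bisection on the odd-mode eigenvalue between two consecutive branch
## points; states interpolated linearly, then Newton-corrected at fixed p
#' @noRd
refine_branch_point <- function(branch, k, tol = 0.5) {
  model <- branch$model; spec <- branch$spec
  np <- model$np; kernel <- model$kernel; grid <- model$grid
  cm <- conv_matrix(kernel)
  va <- deg2rad(spec$va_direction)
  p_lo <- branch$points$p[k]; p_hi <- branch$points$p[k + 1]
  u_lo <- branch$states[, k]; u_hi <- branch$states[, k + 1]
  s_lo <- sign(branch$points$max_re_odd[k])
  eval_odd <- function(p, u_guess) {
    iv <- branch_input(branch, p, grid)
    ns <- newton_steady_state(u_guess, kernel, iv, np, cm = cm)
    if (!ns$converged) return(NA_real_)
    J <- field_jacobian(ns$u, kernel, np, cm = cm)
    leading_eigs(J, grid, va)$max_re_odd
  }
  for (i in seq_len(30)) {
    if (abs(p_hi - p_lo) < tol) break
    p_mid <- (p_lo + p_hi) / 2
    w <- (p_mid - p_lo) / (p_hi - p_lo)
    v <- eval_odd(p_mid, (1 - w) * u_lo + w * u_hi)
    if (is.na(v)) break
    if (sign(v) == s_lo) p_lo <- p_mid else p_hi <- p_mid
  }
  (p_lo + p_hi) / 2
}

## rebuild the input (or parameter setting) used by a branch at parameter p
#' @noRd
branch_input <- function(branch, p, grid) {
  spec <- branch$spec
  switch(branch$parameter,
    ps = make_input(modify_spec(spec, ps = p), grid)$values,
    pw = make_input(modify_spec(spec, pw = p), grid)$values,
    make_input(spec, grid)$values)
}

#' Switch onto a bifurcating branch at a branch point
#'
#' Perturbs the symmetric solution along the critical odd eigenvector and
#' Newton-corrects at a nearby parameter value, landing on one of the two
#' mirror asymmetric branches (sign of `direction` selects which).
#'
#' @param branch an annotated `branch` containing a `branch_point`.
#' @param bp_index row of `special_points` to use (default: first
#'   branch_point).
#' @param direction +1 or -1.
#' @param eps perturbation amplitude (default 0.1).
#' @param dp parameter offset from the branch point (default -2, i.e.
#'   stepping into the subcritical side).
#' @return a list with `u`, `p`, `converged` (a corrected point on the new
#'   branch).
#' @export
switch_branch <- function(branch, bp_index = NULL, direction = 1,
                          eps = 0.1, dp = -2) {
  sp <- branch$special_points
  if (is.null(sp) || !any(sp$type == "branch_point"))
    stop("branch has no detected branch_point")
  if (is.null(bp_index)) bp_index <- which(sp$type == "branch_point")[1]
  k <- sp$index[bp_index]
  model <- branch$model; np <- model$np; kernel <- model$kernel
  grid <- model$grid
  cm <- conv_matrix(kernel)
  va <- deg2rad(branch$spec$va_direction)
  u0 <- branch$states[, k]
  J <- field_jacobian(u0, kernel, np, cm = cm)
  le <- leading_eigs(J, grid, va)
  v <- le$crit_vec_odd
  if (is.null(v)) stop("no odd critical eigenvector at the branch point")
  v <- v / sqrt(sum(v^2))
  p_new <- sp$p[bp_index] + dp
  iv <- branch_input(branch, p_new, grid)
  ns <- newton_steady_state(u0 + direction * eps * v, kernel, iv, np,
                            cm = cm)
  list(u = ns$u, p = p_new, converged = ns$converged)
}
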