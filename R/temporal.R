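## Temporal experiments: direction sweeps building the joint population /
## single-cell tuning matrix, and slow-inhibition ramps under which the
## network drifts from integration (VA) towards segmentation (SB/WTA).

#' Tuning matrix over a stimulus-direction sweep
#'
#' Computes one converged steady state per stimulus direction on an even
#' sweep of \[-180, 180) degrees. Columns are population tuning curves
#' (activity vs preferred direction at fixed stimulus direction); rows are
#' single-cell tuning curves (activity of one unit vs stimulus direction).
#' Deterministic sweeps warm-start each direction from the previous
#' solution rotated by the direction increment, so the matrix is circulant
#' for direction-invariant dynamics.
#'
#' @param spec [stimulus_spec()] template; its `va_direction` is swept.
#' @param model a [ring_network()].
#' @param n_directions number of swept directions (default 24).
#' @param mode `"deterministic"` or `"stochastic"` (independent random
#'   initial conditions and noise per direction).
#' @param seed RNG seed (stochastic mode).
#' @param classify_args overrides for [classify_solution()].
#' @param t_max per-direction integration cap, ms.
#' @return an object of class `tuning_matrix`: `stim_directions` (deg),
#'   `response` (n x n_directions), `labels`, `converged`, `spec`, `model`.
#' @export
tuning_sweep <- function(spec, model, n_directions = 24,
                         mode = c("deterministic", "stochastic"),
                         seed = 1, classify_args = list(), t_max = 1000) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(model, "ring_network"),
            n_directions >= 1)
  mode <- match.arg(mode)
  grid <- model$grid
  dirs <- seq(-180, 180, length.out = n_directions + 1)[seq_len(n_directions)]
  ## align the sweep to grid multiples so rotational equivariance is exact
  step_deg <- rad2deg(grid$dtheta)
  dirs <- round(dirs / step_deg) * step_deg
  response <- matrix(NA_real_, grid$n, n_directions)
  labels <- character(n_directions)
  converged <- logical(n_directions)
  prev_u <- NULL
  prev_dir <- NULL
  for (k in seq_len(n_directions)) {
    sp_k <- spec
    sp_k$va_direction <- dirs[k]
    input <- make_input(sp_k, grid)
    if (mode == "deterministic" && !is.null(prev_u)) {
      shift <- round(deg2rad(dirs[k] - prev_dir) / grid$dtheta)
      u0 <- rotate_values(prev_u, shift)
      ss <- find_steady_state(model, input, u0 = u0)
    } else {
      ss <- find_steady_state(model, input,
                              seed = derive_seed(seed, k),
                              stochastic = mode == "stochastic" &&
                                model$np$noise_eps > 0)
    }
    response[, k] <- ss$u_star
    converged[k] <- ss$converged
    lab <- do.call(classify_solution,
                   c(list(u_star = ss$u_star, stimulus = sp_k, grid = grid,
                          converged = ss$converged), classify_args))
    labels[k] <- lab$label
    prev_u <- ss$u_star
    prev_dir <- dirs[k]
  }
  structure(list(stim_directions = dirs, response = response,
                 labels = labels, converged = converged,
                 spec = spec, model = model, mode = mode, seed = seed),
            class = "tuning_matrix")
}

#' @export
print.tuning_matrix <- function(x, ...) {
  cat(sprintf("<tuning_matrix> %d directions x %d units (%s)\n",
              length(x$stim_directions), nrow(x$response), x$mode))
  cat("  labels:", paste(unique(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.tuning_matrix <- function(x, ...) {
  graphics::image(x$stim_directions, rad2deg(x$model$grid$theta),
                  t(x$response),
                  xlab = "stimulus direction (deg)",
                  ylab = "preferred direction (deg)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Extract a single-cell tuning curve (one row of the matrix)
#' @param tm a `tuning_matrix`.
#' @param preferred_direction preferred direction of the unit, degrees.
#' @return data frame (stim_direction, response).
#' @export
single_cell_tuning <- function(tm, preferred_direction = 0) {
  stopifnot(inherits(tm, "tuning_matrix"))
  grid <- tm$model$grid
  k <- which.min(circ_dist(grid$theta, deg2rad(preferred_direction)))
  data.frame(stim_direction = tm$stim_directions,
             response = tm$response[k, ])
}

#' Classify the single-cell tuning curves of a sweep
#'
#' Rows of the tuning matrix, read as functions of stimulus direction, are
#' classified with the same rule as population curves, with the component
#' landmarks re-expressed in stimulus coordinates around the unit's
#' preferred direction.
#'
#' @param tm a `tuning_matrix`.
#' @param classify_args overrides for [classify_solution()].
#' @return character vector of labels, one per unit (grid node).
#' @export
single_cell_labels <- function(tm, classify_args = list()) {
  stopifnot(inherits(tm, "tuning_matrix"))
  nd <- length(tm$stim_directions)
  row_grid <- ring_grid(nd)
  vapply(seq_len(nrow(tm$response)), function(k) {
    pref <- rad2deg(tm$model$grid$theta[k])
    sp <- tm$spec
    sp$va_direction <- pref
    ## row k on the stimulus-direction axis, resampled onto a ring grid
    u_row <- stats::approx(c(tm$stim_directions, 180),
                           c(tm$response[k, ], tm$response[k, 1]),
                           xout = rad2deg(row_grid$theta), rule = 2)$y
    do.call(classify_solution,
            c(list(u_star = u_row, stimulus = sp, grid = row_grid),
              classify_args))$label
  }, character(1))
}

#' Simulate a slow-inhibition ramp
#'
#' Integrates the dynamics while the inhibitory coefficient follows the
#' exponential schedule, classifying the instantaneous profile every
#' `sample_every` ms. Early in the ramp inhibition is weak and the network
#' integrates (VA); as inhibition saturates the solution drifts towards a
#' side-biased / winner-take-all state.
#'
#' @param spec driving [stimulus_spec()].
#' @param model a [ring_network()].
#' @param schedule an [inhibition_schedule()]; its `g_i_final` defaults to
#'   the kernel's stationary coefficient when `NULL`.
#' @param t_end simulation length, ms (should cover several `tau_l`).
#' @param sample_every classification sampling interval, ms (default 10).
#' @param seed RNG seed.
#' @param classify_args overrides for [classify_solution()].
#' @return an object of class `ramp_trajectory`: the `trajectory` fields
#'   plus `g_i` (series at sample times) and `label_track` (data frame
#'   `t`, `g_i`, `label`).
#' @export
simulate_ramp <- function(spec, model, schedule = NULL, t_end = 600,
                          sample_every = 10, seed = NULL,
                          classify_args = list()) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(model, "ring_network"))
  if (is.null(schedule))
    schedule <- inhibition_schedule(g_i_final = model$kernel$inh_coef)
  input <- make_input(spec, model$grid)
  tr <- integrate_field(model, input, t_end = t_end,
                        record_every = sample_every, schedule = schedule,
                        seed = seed)
  g_i <- inhibition_at_time(tr$times, schedule)
  labels <- vapply(seq_along(tr$times), function(j) {
    do.call(classify_solution,
            c(list(u_star = tr$states[, j], stimulus = spec,
                   grid = model$grid), classify_args))$label
  }, character(1))
  tr$schedule <- schedule
  tr$g_i <- g_i
  tr$label_track <- data.frame(t = tr$times, g_i = g_i, label = labels)
  class(tr) <- c("ramp_trajectory", class(tr))
  tr
}

#' @export
print.ramp_trajectory <- function(x, ...) {
  runs <- rle(x$label_track$label)
  cat(sprintf("<ramp_trajectory> t in [0, %g] ms, label sequence: %s\n",
              max(x$times),
              paste(runs$values, collapse = " -> ")))
  invisible(x)
}

#' First sustained label transition of a ramp
#'
#' The baseline label is the first one holding `sustain` consecutive
#' samples after the onset transient (`settle_t` ms); the transition is
#' the first later label change that also holds `sustain` samples.
#'
#' @param ramp a `ramp_trajectory`.
#' @param sustain number of consecutive samples a label must hold
#'   (default 3).
#' @param settle_t time in ms before which the (random) initial transient
#'   is ignored (default 20).
#' @return list `t` (time of the first sustained change, `NA` if none),
#'   `from` (baseline label), `to`.
#' @export
ramp_transition <- function(ramp, sustain = 3, settle_t = 20) {
  lab <- ramp$label_track$label
  tt <- ramp$label_track$t
  n <- length(lab)
  holds <- function(j) {
    j + sustain - 1L <= n && all(lab[j:(j + sustain - 1L)] == lab[j])
  }
  start <- which(tt >= settle_t)[1]
  if (is.na(start)) start <- 1L
  base_j <- NA_integer_
  for (j in start:n) if (holds(j)) { base_j <- j; break }
  if (is.na(base_j)) return(list(t = NA_real_, from = lab[n], to = lab[n]))
  base <- lab[base_j]
  j <- base_j
  while (j <= n) {
    if (lab[j] != base && holds(j))
      return(list(t = tt[j], from = base, to = lab[j]))
    j <- j + 1L
  }
  list(t = NA_real_, from = base, to = base)
}

#' Sensitivity of ramp dynamics to the inhibition schedule
#'
#' Runs [simulate_ramp()] over a grid of (onset, tau_l, g_i_final)
#' settings and tabulates the early label, the late label and the first
#' sustained transition time.
#'
#' @param spec driving [stimulus_spec()].
#' @param model a [ring_network()].
#' @param onsets,tau_ls,g_i_finals vectors defining the grid.
#' @param t_end simulation length per setting, ms.
#' @param g_i_low initial inhibition (default 0).
#' @param sample_every classification interval, ms.
#' @param seed RNG seed.
#' @param ... passed to [simulate_ramp()].
#' @return data frame with one row per setting: `onset`, `tau_l`,
#'   `g_i_final`, `early_label`, `late_label`, `transition_time`.
#' @export
ramp_sensitivity <- function(spec, model, onsets = 0, tau_ls = c(30, 100),
                             g_i_finals, t_end = 600, g_i_low = 0,
                             sample_every = 10, seed = NULL, ...) {
  settings <- expand.grid(onset = onsets, tau_l = tau_ls,
                          g_i_final = g_i_finals)
  out <- settings
  out$early_label <- NA_character_
  out$late_label <- NA_character_
  out$transition_time <- NA_real_
  for (i in seq_len(nrow(settings))) {
    sch <- inhibition_schedule(g_i_final = settings$g_i_final[i],
                               g_i_low = g_i_low,
                               tau_l = settings$tau_l[i],
                               onset = settings$onset[i])
    rp <- simulate_ramp(spec, model, schedule = sch, t_end = t_end,
                        sample_every = sample_every, seed = seed, ...)
    lab <- rp$label_track$label
    tt <- rp$label_track$t
    ## early label: first classification holding >= 2 samples once the
    ## onset transient (~20 ms) has passed
    settled <- which(tt >= 20)
    early <- lab[settled[1]]
    for (j in settled) {
      if (j < length(lab) && lab[j] == lab[j + 1]) { early <- lab[j]; break }
    }
    out$early_label[i] <- early
    out$late_label[i] <- lab[length(lab)]
    out$transition_time[i] <- ramp_transition(rp)$t
  }
  out
}

#' Export a tuning matrix as CSV (plus a JSON label track)
#' @param tm a `tuning_matrix`.
#' @param path CSV output file; labels go to `sub("csv$", "json", path)`.
#' @return the path, invisibly.
#' @export
write_tuning_matrix <- function(tm, path) {
  stopifnot(inherits(tm, "tuning_matrix"))
  m <- as.data.frame(tm$response)
  names(m) <- sprintf("stim_%+.1f", tm$stim_directions)
  m <- cbind(preferred_deg = rad2deg(tm$model$grid$theta), m)
  utils::write.csv(m, path, row.names = FALSE)
  jsonlite::write_json(
    list(stim_directions = tm$stim_directions, labels = tm$labels,
         converged = tm$converged),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
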