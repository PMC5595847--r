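## One-parameter bifurcation diagram in peak separation (PS): the vector-
## average branch with its symmetry-breaking pitchfork, the winner-take-all
## pair born there (continued through its fold), and the two-peaked
## (transparency) branch with its own fold. The projection used for
## plotting and for branch-crossing detection is the l2-norm energy of the
## steady state against PS.

#' Compute the PS bifurcation diagram
#'
#' Continues the three steady-state branches of the symmetrically driven
#' ring in peak separation and extracts the tri-stability window: the VA
#' branch loses stability at a symmetry-breaking pitchfork (upper edge);
#' the WTA and TP branches gain stability at folds (the larger fold is the
#' lower edge). Unstable segments are kept so branch crossings in the
#' energy projection can be located.
#'
#' @param model a [ring_network()] (continuation always runs noise-free).
#' @param pw peak width in degrees (default 10).
#' @param ps_range PS range to cover, degrees (default c(20, 180)).
#' @param ds0,ds_max continuation step control (degrees of arclength).
#' @param max_steps per-branch cap on continuation points.
#' @return an object of class `bifurcation_diagram` with fields
#'   `branches` (named list `va`, `wta`, `tp` of [continue_branch()]
#'   results, annotated), `pitchfork_ps`, `fold_wta_ps`, `fold_tp_ps`,
#'   `window` (c(lower, upper) of simultaneous tri-stability),
#'   `crossings` (data frame of pairwise unstable-branch energy
#'   crossings).
#' @export
bifurcation_diagram <- function(model, pw = 10, ps_range = c(20, 180),
                                ds0 = 2, ds_max = 6, max_steps = 300) {
  stopifnot(inherits(model, "ring_network"))
  grid <- model$grid
  spec <- stimulus_spec(ps = ps_range[1], pw = pw, va_direction = 0,
                        rel_strength = 1, n_components = 2L)

  ## --- VA branch: from the integration attractor at small PS upward
  inp0 <- make_input(spec, grid)
  ss0 <- find_steady_state(model, inp0, u0 = inp0$values, t_max = 1500)
  va_branch <- continue_branch(model, spec, ss0$u_star, "ps",
                               p_from = ps_range[1], p_to = ps_range[2],
                               ds0 = ds0, ds_max = ds_max,
                               max_steps = max_steps, track_odd = TRUE)
  va_branch <- detect_special_points(va_branch)
  sp <- va_branch$special_points
  pitch <- sp$p[sp$type == "branch_point"]
  pitchfork_ps <- if (length(pitch)) pitch[1] else NA_real_

  ## --- WTA branch: warm-start a one-sided (winner) state at large PS by
  ## integrating from a bump over one stimulus component, then continue
  ## down through the fold; the branch returns upward as the unstable
  ## asymmetric segment that terminates near the pitchfork
  wta_branch <- NULL; fold_wta <- NA_real_
  spec_w <- modify_spec(spec, ps = ps_range[2])
  inp_w <- make_input(spec_w, grid)
  comp1 <- deg2rad(spec$va_direction - ps_range[2] / 2)
  bump <- 2 * exp(-circ_dist(grid$theta, comp1)^2 / (2 * deg2rad(25)^2))
  ss_w <- find_steady_state(model, inp_w, u0 = bump, t_max = 1500)
  pk_w <- grid$theta[which.max(ss_w$u_star)]
  asymmetric <- abs(circ_dist(pk_w, deg2rad(spec$va_direction))) >
    deg2rad(20)
  if (ss_w$converged && asymmetric) {
    wta_branch <- continue_branch(model, spec, ss_w$u_star, "ps",
                                  p_from = ps_range[2], p_to = ps_range[1],
                                  ds0 = ds0, ds_max = ds_max,
                                  max_steps = max_steps, track_odd = FALSE,
                                  p_limits = ps_range)
    ## the asymmetric branch ends where it merges with the symmetric one
    ## (the pitchfork); past that the continuation retraces the mirror
    ## image and may hop onto the VA branch, so truncate there
    va_rad <- deg2rad(spec$va_direction)
    asym <- apply(wta_branch$states, 2, function(u)
      abs(circ_dist(grid$theta[which.max(u)], va_rad)))
    sym_idx <- which(asym < deg2rad(5))
    if (length(sym_idx)) {
      keep <- seq_len(min(sym_idx))
      wta_branch$points <- wta_branch$points[keep, , drop = FALSE]
      wta_branch$states <- wta_branch$states[, keep, drop = FALSE]
    }
    wta_branch <- detect_special_points(wta_branch)
    spw <- wta_branch$special_points
    folds <- spw$p[spw$type == "fold"]
    if (length(folds)) fold_wta <- min(folds)
  }

  ## --- TP branch: symmetric two-bump attractor at large PS, continued
  ## downward through its fold
  spec_hi <- modify_spec(spec, ps = ps_range[2])
  inp_hi <- make_input(spec_hi, grid)
  ss_tp <- find_steady_state(model, inp_hi, u0 = inp_hi$values, t_max = 1500)
  tp_branch <- continue_branch(model, spec, ss_tp$u_star, "ps",
                               p_from = ps_range[2], p_to = ps_range[1],
                               ds0 = ds0, ds_max = ds_max,
                               max_steps = max_steps, track_odd = TRUE)
  tp_branch <- detect_special_points(tp_branch)
  spt <- tp_branch$special_points
  folds_tp <- spt$p[spt$type == "fold"]
  fold_tp <- if (length(folds_tp)) min(folds_tp) else NA_real_

  window <- c(lower = suppressWarnings(max(fold_wta, fold_tp, na.rm = TRUE)),
              upper = pitchfork_ps)
  if (!is.finite(window[1])) window[1] <- NA_real_

  branches <- list(va = va_branch, wta = wta_branch, tp = tp_branch)
  crossings <- unstable_crossings(branches)
  structure(list(branches = branches, pitchfork_ps = pitchfork_ps,
                 fold_wta_ps = fold_wta, fold_tp_ps = fold_tp,
                 window = window, crossings = crossings,
                 pw = pw, model = model),
            class = "bifurcation_diagram")
}

## contiguous unstable runs of a branch, as (p, energy) segments
#' @noRd
unstable_segments <- function(branch, min_len = 3L) {
  if (is.null(branch)) return(list())
  uns <- !branch$points$stable
  r <- rle(uns)
  out <- list(); idx_end <- cumsum(r$lengths)
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= min_len) {
      i <- (idx_end[k] - r$lengths[k] + 1L):idx_end[k]
      out[[length(out) + 1L]] <- branch$points[i, c("p", "energy")]
    }
  }
  out
}

## pairwise crossings of unstable-segment energy curves across branches
#' @noRd
unstable_crossings <- function(branches) {
  segs <- list()
  for (nm in names(branches)) {
    ss <- unstable_segments(branches[[nm]])
    for (i in seq_along(ss))
      segs[[paste0(nm, i)]] <- ss[[i]]
  }
  out <- list()
  nms <- names(segs)
  seg_branch <- sub("[0-9]+$", "", nms)
  if (length(nms) >= 2) {
    for (a in seq_along(nms)) for (b in seq_along(nms)) {
      if (a >= b) next
      ## segments of one branch overlap in the energy projection (mirror
      ## asymmetric states) without being distinct solutions; skip them
      if (seg_branch[a] == seg_branch[b]) next
      A <- segs[[a]]; B <- segs[[b]]
      lo <- max(min(A$p), min(B$p)); hi <- min(max(A$p), max(B$p))
      if (hi - lo < 1) next
      fa <- stats::approxfun(A$p, A$energy, ties = mean)
      fb <- stats::approxfun(B$p, B$energy, ties = mean)
      ps <- seq(lo, hi, length.out = 200)
      d <- fa(ps) - fb(ps)
      ok <- which(is.finite(d))
      if (length(ok) < 2) next
      sgn <- sign(d[ok])
      cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
      for (ci in cross) {
        root <- tryCatch(
          stats::uniroot(function(p) fa(p) - fb(p),
                         c(ps[ok[ci]], ps[ok[ci + 1]]))$root,
          error = function(e) NA_real_)
        if (!is.na(root))
          out[[length(out) + 1L]] <- data.frame(branch_a = nms[a],
                                                branch_b = nms[b],
                                                ps = root)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(branch_a = character(), branch_b = character(),
                  ps = numeric())
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("<bifurcation_diagram> PW = %g deg, alpha = %g, beta = %g\n",
              x$pw, x$model$kernel$params$alpha, x$model$kernel$params$beta))
  cat(sprintf("  pitchfork (VA stability loss): PS = %.1f deg\n",
              x$pitchfork_ps))
  cat(sprintf("  WTA fold: PS = %.1f | TP fold: PS = %.1f\n",
              x$fold_wta_ps, x$fold_tp_ps))
  cat(sprintf("  tri-stability window: [%.1f, %.1f] deg\n",
              x$window[1], x$window[2]))
  if (nrow(x$crossings))
    cat(sprintf("  unstable-branch energy crossing(s) at PS = %s\n",
                paste(sprintf("%.1f", x$crossings$ps), collapse = ", ")))
  invisible(x)
}

#' @export
plot.bifurcation_diagram <- function(x, ...) {
  all_pts <- do.call(rbind, lapply(Filter(Negate(is.null), x$branches),
                                   function(b) b$points[, c("p", "energy")]))
  graphics::plot(all_pts$p, all_pts$energy, type = "n",
                 xlab = "PS (deg)", ylab = "energy (l2 norm)", ...)
  for (b in Filter(Negate(is.null), x$branches)) plot(b, add = TRUE)
  if (is.finite(x$window[1]))
    graphics::abline(v = x$window, col = "red", lty = 3)
  invisible(x)
}

#' Export a branch as CSV
#' @param branch a `branch`.
#' @param path output file.
#' @param states_path optional CSV for the per-point steady states.
#' @return `path`, invisibly.
#' @export
write_branch_csv <- function(branch, path, states_path = NULL) {
  stopifnot(inherits(branch, "branch"))
  pts <- branch$points
  pts$special_type <- ""
  sp <- branch$special_points
  if (!is.null(sp) && nrow(sp)) {
    for (i in seq_len(nrow(sp)))
      pts$special_type[sp$index[i]] <- sp$type[i]
  }
  utils::write.csv(pts, path, row.names = FALSE)
  if (!is.null(states_path))
    utils::write.csv(as.data.frame(branch$states), states_path,
                     row.names = FALSE)
  invisible(path)
}
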