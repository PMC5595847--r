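## Labeling of converged tuning curves relative to the driving stimulus:
## vector average (VA, single peak at the pattern direction), winner-take-
## all (WTA, single peak at one component), side-biased (SB, WTA with a
## residual bump at the suppressed component), two-peaked / transparency
## (TP, both components represented), or untuned.

#' Find peaks of a periodic tuning curve
#'
#' Local maxima on the circular grid that clear both a height threshold
#' (relative to the positive maximum) and a prominence threshold. Peak
#' positions are refined to sub-grid accuracy by quadratic interpolation
#' through the three samples around each maximum.
#'
#' @param u activity profile on the grid.
#' @param grid a [ring_grid()].
#' @param min_height_frac minimal height as a fraction of `max(u)`
#'   (default 0.1).
#' @param min_prominence_frac minimal circular prominence as a fraction of
#'   `max(u)` (default 0.05).
#' @return data frame with columns `direction` (degrees, in \[-180, 180)),
#'   `height`, sorted by height descending; zero rows when the profile is
#'   nowhere positive.
#' @export
find_peaks <- function(u, grid, min_height_frac = 0.1,
                       min_prominence_frac = 0.05) {
  stopifnot(inherits(grid, "ring_grid"), all(is.finite(u)))
  n <- grid$n
  umax <- max(u)
  if (umax <= 0)
    return(data.frame(direction = numeric(), height = numeric()))
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  is_max <- u > u[prv] & u >= u[nxt]
  cand <- which(is_max)
  if (!length(cand))
    return(data.frame(direction = numeric(), height = numeric()))
  prom <- vapply(cand, function(k) circular_prominence(u, k), numeric(1))
  keep <- u[cand] >= min_height_frac * umax &
          prom >= min_prominence_frac * umax
  cand <- cand[keep]
  if (!length(cand))
    return(data.frame(direction = numeric(), height = numeric()))
  ## sub-grid refinement
  dirs <- numeric(length(cand)); hts <- numeric(length(cand))
  for (i in seq_along(cand)) {
    k <- cand[i]
    ym <- u[prv[k]]; y0 <- u[k]; yp <- u[nxt[k]]
    denom <- ym - 2 * y0 + yp
    off <- if (denom != 0) 0.5 * (ym - yp) / denom else 0
    off <- max(min(off, 0.5), -0.5)
    dirs[i] <- rad2deg(wrap_angle(grid$theta[k] + off * grid$dtheta))
    hts[i] <- y0 - 0.25 * (ym - yp) * off
  }
  out <- data.frame(direction = dirs, height = hts)
  out[order(out$height, decreasing = TRUE), , drop = FALSE]
}

## prominence of local max k on the circle: height minus the key col, the
## higher of the two minima encountered walking each way until terrain
## higher than u[k] is met; for the global max, height minus global min
#' @noRd
circular_prominence <- function(u, k) {
  n <- length(u)
  h <- u[k]
  if (h >= max(u)) return(h - min(u))
  walk <- function(step) {
    m <- h
    j <- k
    for (i in seq_len(n - 1L)) {
      j <- ((j - 1L + step) %% n) + 1L
      if (u[j] > h) return(m)
      m <- min(m, u[j])
    }
    m
  }
  h - max(walk(1L), walk(-1L))
}

#' Classify a converged tuning curve
#'
#' Decision rule for a two-component stimulus with components at
#' `va_direction` +/- `ps`/2: no qualifying peak gives UNTUNED; a dominant
#' peak at the pattern direction gives VA; a dominant peak at one component
#' gives WTA, upgraded to SB when a secondary bump at the other component
#' exceeds `sb_frac` of the main height, or to TP when it exceeds
#' `tp_frac` (comparable peaks at both components); anything else is
#' UNTUNED. Unidirectional stimuli are classified trivially: VA when the
#' single peak matches the stimulus direction. `tol_dir` absorbs the
#' outward repulsion of transparency peaks.
#'
#' @param u_star converged activity profile (or a `steady_state`).
#' @param stimulus the driving [stimulus_spec()].
#' @param grid a [ring_grid()] (taken from `u_star` when it is a
#'   `steady_state`).
#' @param tol_dir angular tolerance in degrees (default 20).
#' @param sb_frac secondary-bump fraction above which WTA becomes SB
#'   (default 0.1).
#' @param tp_frac secondary-peak fraction above which the state counts as
#'   two-peaked (default 0.5).
#' @param min_height_frac,min_prominence_frac passed to [find_peaks()].
#' @param converged set `FALSE` to record a NONCONVERGED outcome.
#' @return an object of class `solution_label`: fields `label` (one of
#'   `"VA"`, `"WTA"`, `"SB"`, `"TP"`, `"UNTUNED"`, `"NONCONVERGED"`),
#'   `peaks`, `dominant_component` (degrees, or NA).
#' @export
classify_solution <- function(u_star, stimulus, grid = NULL, tol_dir = 20,
                              sb_frac = 0.1, tp_frac = 0.5,
                              min_height_frac = 0.1,
                              min_prominence_frac = 0.05,
                              converged = NULL) {
  if (inherits(u_star, "steady_state")) {
    if (is.null(grid)) grid <- u_star$model$grid
    if (is.null(converged)) converged <- u_star$converged
    u_star <- u_star$u_star
  }
  if (is.null(converged)) converged <- TRUE
  stopifnot(inherits(stimulus, "stimulus_spec"), inherits(grid, "ring_grid"))
  mk <- function(label, peaks, dom = NA_real_)
    structure(list(label = label, peaks = peaks, dominant_component = dom,
                   stimulus = stimulus), class = "solution_label")
  empty <- data.frame(direction = numeric(), height = numeric())
  if (!converged) return(mk("NONCONVERGED", empty))
  peaks <- find_peaks(u_star, grid, min_height_frac, min_prominence_frac)
  if (nrow(peaks) == 0) return(mk("UNTUNED", empty))

  va <- stimulus$va_direction
  near <- function(a, b) rad2deg(circ_dist(deg2rad(a), deg2rad(b))) <= tol_dir
  if (stimulus$n_components == 1L) {
    if (near(peaks$direction[1], va)) return(mk("VA", peaks, va))
    return(mk("UNTUNED", peaks))
  }
  comps <- c(va - stimulus$ps / 2, va + stimulus$ps / 2)
  p1 <- peaks[1, ]
  ## secondary peak nearest to each component
  sec_at <- function(comp) {
    if (nrow(peaks) < 2) return(NULL)
    rest <- peaks[-1, , drop = FALSE]
    hit <- rest[near(rest$direction, comp), , drop = FALSE]
    if (nrow(hit) == 0) NULL else hit[1, ]
  }
  ## assign the dominant peak to the nearest stimulus landmark (pattern
  ## direction or either component); when PS/2 <= tol_dir the tolerance
  ## bands overlap and proximity decides
  targets <- c(va, comps)
  dists <- rad2deg(circ_dist(deg2rad(p1$direction), deg2rad(targets)))
  if (min(dists) > tol_dir) return(mk("UNTUNED", peaks))
  nearest <- which.min(dists)
  if (nearest == 1L) return(mk("VA", peaks, va))
  {
    main_comp <- targets[nearest]
    other_comp <- comps[comps != main_comp][1]
    s <- sec_at(other_comp)
    if (!is.null(s) && s$height >= tp_frac * p1$height)
      return(mk("TP", peaks, NA_real_))
    if (!is.null(s) && s$height >= sb_frac * p1$height)
      return(mk("SB", peaks, main_comp))
    ## also honor sub-threshold secondary bumps (too small for find_peaks)
    if (is.null(s)) {
      s2 <- secondary_bump_height(u_star, grid, other_comp, tol_dir)
      if (!is.na(s2) && s2 >= sb_frac * p1$height)
        return(mk("SB", peaks, main_comp))
    }
    return(mk("WTA", peaks, main_comp))
  }
}

## height of the largest positive local maximum within tol of a direction,
## without the find_peaks height/prominence gates
#' @noRd
secondary_bump_height <- function(u, grid, dir_deg, tol_dir) {
  n <- grid$n
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  is_max <- u > u[prv] & u >= u[nxt] & u > 0
  cand <- which(is_max)
  if (!length(cand)) return(NA_real_)
  d <- rad2deg(circ_dist(grid$theta[cand], deg2rad(dir_deg)))
  cand <- cand[d <= tol_dir]
  if (!length(cand)) return(NA_real_)
  max(u[cand])
}

#' @export
print.solution_label <- function(x, ...) {
  cat(sprintf("<solution_label> %s", x$label))
  if (!is.na(x$dominant_component))
    cat(sprintf(" (dominant component %.1f deg)", x$dominant_component))
  cat("\n")
  if (nrow(x$peaks) > 0) {
    for (i in seq_len(nrow(x$peaks)))
      cat(sprintf("  peak %.1f deg, height %.3f\n",
                  x$peaks$direction[i], x$peaks$height[i]))
  }
  invisible(x)
}

#' Serialize a classification to JSON
#' @param label a `solution_label`.
#' @param path output file; `NULL` returns the JSON string.
#' @param extra named list merged into the record (e.g. seed, params).
#' @return path or JSON string, invisibly.
#' @export
write_label_json <- function(label, path = NULL, extra = list()) {
  stopifnot(inherits(label, "solution_label"))
  rec <- c(list(label = label$label,
                peaks = label$peaks,
                dominant_component = label$dominant_component,
                stimulus = unclass(label$stimulus)), extra)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
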