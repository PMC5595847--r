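## Attractor-strength estimation: the probability of reaching each tuning
## class from repeated simulations with random initial conditions, swept
## over stimulus (PS x PW) or connectivity (alpha x beta) grids, and the
## migration (transition) percentages between stimulus conditions obtained
## by intersecting binarized maps.

label_levels <- c("VA", "WTA", "SB", "TP", "UNTUNED", "NONCONVERGED")
pooled_levels <- c("VA", "WTA/SB", "TP", "UNTUNED", "NONCONVERGED")

#' @noRd
pool_label <- function(label) {
  ifelse(label %in% c("WTA", "SB"), "WTA/SB", label)
}

#' Attractor strength of the tuning classes
#'
#' Runs `n_trials` independent simulations from fresh low random initial
#' conditions (with a noisy transient when `noise_eps > 0`), classifies
#' each converged steady state and returns the empirical label
#' frequencies. Deterministic given `seed`. WTA and SB are tallied
#' separately and also pooled (`"WTA/SB"`), matching how probability maps
#' group them.
#'
#' @param model a [ring_network()].
#' @param spec the driving [stimulus_spec()].
#' @param n_trials number of repetitions (default 100).
#' @param seed master seed; trial seeds are derived from it.
#' @param t_max,t_settle passed to [find_steady_state()].
#' @param tol_class quasi-steady residual tolerance for classification
#'   (default 1e-6): trials whose final residual beats it are classified
#'   even when the strict steady-state tolerance was not yet reached
#'   (narrow-bump competition approaches its attractor exponentially
#'   slowly); only trials above `tol_class` count as NONCONVERGED.
#' @param classify_args list of overrides for [classify_solution()].
#' @param count_nonconverged keep NONCONVERGED runs in the denominator
#'   (default TRUE).
#' @return list with `probs` (named vector over the pooled labels), `raw`
#'   (named vector over all labels), `labels` (per-trial), `n_trials`,
#'   `seed`.
#' @export
attractor_strength <- function(model, spec, n_trials = 100, seed = 1,
                               t_max = 2000, t_settle = 200,
                               tol_class = 1e-6,
                               classify_args = list(),
                               count_nonconverged = TRUE) {
  stopifnot(inherits(model, "ring_network"), n_trials >= 1)
  input <- make_input(spec, model$grid)
  labels <- character(n_trials)
  for (trial in seq_len(n_trials)) {
    ss <- find_steady_state(model, input,
                            seed = derive_seed(seed, trial),
                            t_max = t_max,
                            stochastic = model$np$noise_eps > 0,
                            t_settle = t_settle)
    conv <- ss$converged || ss$residual < tol_class
    lab <- do.call(classify_solution,
                   c(list(u_star = ss, stimulus = spec, converged = conv),
                     classify_args))
    labels[trial] <- lab$label
  }
  counts <- table(factor(labels, levels = label_levels))
  pooled <- table(factor(pool_label(labels), levels = pooled_levels))
  denom <- if (count_nonconverged) n_trials
           else max(sum(labels != "NONCONVERGED"), 1L)
  probs <- as.numeric(pooled) / denom
  names(probs) <- pooled_levels
  raw <- as.numeric(counts) / n_trials
  names(raw) <- label_levels
  list(probs = probs, raw = raw, raw_counts = as.integer(counts),
       labels = labels, n_trials = n_trials, seed = seed)
}

## deterministic per-trial / per-cell seed derivation, kept below 2^31
#' @noRd
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 1000003 + as.numeric(p) * 7919 + 17) %% 2147483629
  as.integer(s) + 1L
}

#' Probability map of attractor strength over a parameter grid
#'
#' Evaluates [attractor_strength()] at every cell of a two-parameter grid.
#' Axes may be stimulus parameters (`ps`, `pw`) or connectivity parameters
#' (`alpha`, `beta`); the kernel is rebuilt per cell when a connectivity
#' axis is swept. Per-cell seeds are derived from the master seed and the
#' cell indices, so the map is reproducible and independent of evaluation
#' order.
#'
#' @param axis1,axis2 named lists `list(name = "ps", values = ...)`;
#'   names among `"ps"`, `"pw"`, `"alpha"`, `"beta"`.
#' @param spec baseline [stimulus_spec()].
#' @param kp baseline [kernel_params()].
#' @param np a [network_params()].
#' @param grid a [ring_grid()].
#' @param n_trials trials per cell (default 100).
#' @param seed master seed.
#' @param ... passed to [attractor_strength()].
#' @return an object of class `probability_map`: `axes`, `probs` (named
#'   list of matrices, one per pooled label, axis1 in rows), `n_trials`,
#'   `seed`.
#' @export
probability_map <- function(axis1, axis2, spec, kp = kernel_params(),
                            np = network_params(), grid = ring_grid(),
                            n_trials = 100, seed = 1, ...) {
  check_axis <- function(ax) {
    stopifnot(is.list(ax), ax$name %in% c("ps", "pw", "alpha", "beta"),
              length(ax$values) >= 1)
    ax
  }
  axis1 <- check_axis(axis1); axis2 <- check_axis(axis2)
  n1 <- length(axis1$values); n2 <- length(axis2$values)
  probs <- lapply(pooled_levels, function(l) matrix(0, n1, n2))
  names(probs) <- pooled_levels
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      sp <- spec; k <- kp
      for (ax in list(list(a = axis1, v = axis1$values[i]),
                      list(a = axis2, v = axis2$values[j]))) {
        nm <- ax$a$name
        if (nm %in% c("ps", "pw")) sp[[nm]] <- ax$v
        else k[[nm]] <- ax$v
      }
      k <- kernel_params(alpha = k$alpha, beta = k$beta,
                         sigma_e_a = k$sigma_e_a, sigma_e_b = k$sigma_e_b,
                         sigma_i = k$sigma_i)
      model <- ring_network(k, np, grid)
      as_ <- attractor_strength(model, sp, n_trials = n_trials,
                                seed = derive_seed(seed, i, j), ...)
      for (l in pooled_levels) probs[[l]][i, j] <- as_$probs[[l]]
    }
  }
  structure(list(axes = list(axis1 = axis1, axis2 = axis2),
                 probs = probs, spec = spec, kp = kp, np = np,
                 n_trials = n_trials, seed = seed),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %s (%d) x %s (%d), %d trials/cell\n",
              x$axes$axis1$name, length(x$axes$axis1$values),
              x$axes$axis2$name, length(x$axes$axis2$values), x$n_trials))
  for (l in names(x$probs))
    cat(sprintf("  P(%s): mean %.3f, max %.3f\n", l, mean(x$probs[[l]]),
                max(x$probs[[l]])))
  invisible(x)
}

#' @export
plot.probability_map <- function(x, label = "VA", ...) {
  graphics::image(x$axes$axis1$values, x$axes$axis2$values,
                  x$probs[[label]], zlim = c(0, 1),
                  xlab = x$axes$axis1$name, ylab = x$axes$axis2$name,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = paste0("P(", label, ")"), ...)
  invisible(x)
}

#' Migration (transition) percentages between two stimulus conditions
#'
#' Binarizes both probability maps at `threshold` and, for each ordered
#' label pair (x under condition A, y under condition B), reports the
#' intersection area of the two supported regions as a percentage of the
#' full parameter grid.
#'
#' @param mapA,mapB [probability_map()]s on identical axes (e.g. the
#'   alpha-beta plane under a random-dot vs a plaid input).
#' @param threshold binarization threshold (default 0.5: a class is
#'   "supported" where it is the majority outcome).
#' @param labels which pooled labels to cross (default VA, WTA/SB, TP).
#' @return an object of class `migration_result` with the percentage
#'   matrix `overlap` (rows: label under A, columns: label under B).
#' @export
migration <- function(mapA, mapB, threshold = 0.5,
                      labels = c("VA", "WTA/SB", "TP")) {
  stopifnot(inherits(mapA, "probability_map"),
            inherits(mapB, "probability_map"))
  if (!identical(mapA$axes$axis1$values, mapB$axes$axis1$values) ||
      !identical(mapA$axes$axis2$values, mapB$axes$axis2$values) ||
      !identical(mapA$axes$axis1$name, mapB$axes$axis1$name) ||
      !identical(mapA$axes$axis2$name, mapB$axes$axis2$name))
    stop("maps must share identical axes")
  ncell <- length(mapA$probs[[1]])
  overlap <- matrix(NA_real_, length(labels), length(labels),
                    dimnames = list(from = labels, to = labels))
  for (a in labels) {
    for (b in labels) {
      inter <- (mapA$probs[[a]] >= threshold) & (mapB$probs[[b]] >= threshold)
      overlap[a, b] <- 100 * sum(inter) / ncell
    }
  }
  structure(list(overlap = overlap, threshold = threshold,
                 condition_pair = list(A = mapA$spec, B = mapB$spec)),
            class = "migration_result")
}

#' @export
print.migration_result <- function(x, ...) {
  cat(sprintf("<migration_result> threshold %.2f; overlap %% (A rows -> B cols)\n",
              x$threshold))
  print(round(x$overlap, 1))
  invisible(x)
}

#' Export a probability map as per-label CSVs plus a JSON manifest
#'
#' @param map a `probability_map`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return the manifest path, invisibly.
#' @export
write_probability_map <- function(map, dir, prefix = "pmap") {
  stopifnot(inherits(map, "probability_map"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (l in names(map$probs)) {
    safe <- gsub("/", "_", l)
    f <- file.path(dir, sprintf("%s_%s.csv", prefix, safe))
    g <- expand.grid(a1 = map$axes$axis1$values, a2 = map$axes$axis2$values)
    names(g) <- c(map$axes$axis1$name, map$axes$axis2$name)
    g$probability <- as.vector(map$probs[[l]])
    utils::write.csv(g, f, row.names = FALSE)
    files[l] <- f
  }
  manifest <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(
    list(axes = map$axes, n_trials = map$n_trials, seed = map$seed,
         files = as.list(files)),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
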