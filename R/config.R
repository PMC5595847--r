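## Configuration: a flat YAML file of named scalars covering the model
## constants, solver tolerances and classifier thresholds. Angles in the
## config (and everywhere user-facing) are degrees. Unknown keys are
## rejected; values are range-checked on load.

#' Default run configuration
#'
#' All documented model constants and the package's numerical and
#' classifier defaults, as a named list.
#'
#' @return an object of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    ## grid and network constants
    ## (named n_units, not n: YAML 1.1 would parse a bare "n" key as FALSE)
    n_units = 404L,      # samples on the direction ring
    th = 3.0,            # sigmoid threshold
    mu = 16.0,           # sigmoid gain
    kappa_i = 0.1,       # input gain
    tau_p = 1.0,         # population time constant, ms (1, 5 or 10)
    tau_l = 100.0,       # slow inhibition time constant, ms (30-100)
    onset = 0.0,         # inhibition onset delay, ms
    g_i_low = 0.0,       # initial inhibition strength of the ramp
    ## connectivity kernel
    alpha = 0.0,         # excitation-extent homotopy, [0, 1]
    beta = 0.0,          # inhibition offset, [-10, 15]
    sigma_e_a = 11.5,    # narrow excitation width, deg
    sigma_e_b = 60.0,    # broad excitation width, deg
    sigma_i = 1800.0,    # inhibition width, deg (10*pi rad)
    ## stimulus
    ps = 120.0,          # peak separation, deg, (0, 180]
    pw = 10.0,           # peak width, deg (documented range 5-30)
    va_direction = 0.0,  # pattern direction, deg
    rel_strength = 1.0,  # weaker/stronger component ratio, [0, 1]
    n_components = 2L,
    normalize = "peak",  # bump normalization: "peak" or "area"
    pw_rds = 10.0,       # peak width encoding random-dot patterns
    pw_plaid = 25.0,     # peak width encoding plaids/gratings
    ## integration
    noise_eps = 0.0,     # additive noise amplitude (0.01 for noisy runs)
    dt = 0.1,            # Euler-Maruyama step, ms
    ic_amp = 0.1,        # amplitude of the low random initial activity
    tol_ss = 1e-9,       # steady-state residual tolerance (max-norm)
    t_max = 2000.0,      # integration cap, ms
    sample_every = 10.0, # ramp classification interval, ms
    ## classifier
    tol_dir = 20.0,            # angular tolerance, deg
    sb_frac = 0.1,             # secondary bump fraction (WTA -> SB)
    tp_frac = 0.5,             # secondary peak fraction (-> TP)
    min_height_frac = 0.1,
    min_prominence_frac = 0.05,
    ## maps / migration
    n_trials = 100L,
    binarize_threshold = 0.5,
    ## bookkeeping
    seed = 1L,
    out_dir = "mtring_out"
  ), class = "run_config")
}

#' @noRd
validate_config <- function(cfg) {
  chk <- function(cond, key, msg)
    if (!cond) stop("config key '", key, "': ", msg, call. = FALSE)
  chk(cfg$n_units >= 8, "n_units", "needs at least 8 samples")
  chk(cfg$alpha >= 0 && cfg$alpha <= 1, "alpha", "must lie in [0, 1]")
  chk(cfg$beta >= -10 && cfg$beta <= 15, "beta", "must lie in [-10, 15]")
  chk(cfg$sigma_e_a > 0 && cfg$sigma_e_a < cfg$sigma_e_b, "sigma_e_a",
      "must be positive and below sigma_e_b")
  chk(deg2rad(cfg$sigma_i) > 2 * pi, "sigma_i",
      "must be much larger than one period")
  chk(cfg$ps > 0 && cfg$ps <= 180, "ps", "must lie in (0, 180] degrees")
  chk(cfg$pw > 0, "pw", "must be positive")
  chk(cfg$rel_strength >= 0 && cfg$rel_strength <= 1, "rel_strength",
      "must lie in [0, 1]")
  chk(cfg$n_components %in% c(1, 2), "n_components", "must be 1 or 2")
  chk(cfg$mu > 0 && cfg$th > 0, "mu", "mu and th must be positive")
  chk(cfg$tau_p > 0, "tau_p", "must be positive")
  chk(cfg$tau_l > 0, "tau_l", "must be positive")
  chk(cfg$onset >= 0, "onset", "must be non-negative")
  chk(cfg$noise_eps >= 0, "noise_eps", "must be non-negative")
  chk(cfg$dt > 0, "dt", "must be positive")
  chk(cfg$normalize %in% c("peak", "area"), "normalize",
      "must be 'peak' or 'area'")
  chk(cfg$binarize_threshold > 0 && cfg$binarize_threshold <= 1,
      "binarize_threshold", "must lie in (0, 1]")
  chk(cfg$n_trials >= 1, "n_trials", "must be at least 1")
  invisible(cfg)
}

#' Load a run configuration
#'
#' Reads a flat YAML file of overrides on top of [default_config()].
#' Unknown keys are rejected with the offending name; all values are
#' range-checked. An empty (or missing `path = NULL`) file yields the
#' defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list applied after the file (e.g. CLI flags).
#' @return a validated `run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(user)) {
    v <- user[[nm]]
    if (is.integer(cfg[[nm]])) v <- as.integer(v)
    cfg[[nm]] <- v
  }
  validate_config(cfg)
}

#' Write the effective configuration next to run outputs
#' @param cfg a `run_config`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Build model components from a configuration
#'
#' @param cfg a `run_config`.
#' @return `config_model()` gives a [ring_network()]; `config_stimulus()`
#'   a [stimulus_spec()]; `config_schedule()` an [inhibition_schedule()]
#'   whose asymptote is the configured stationary coefficient.
#' @export
config_model <- function(cfg) {
  ring_network(
    kernel_params(alpha = cfg$alpha, beta = cfg$beta,
                  sigma_e_a = cfg$sigma_e_a, sigma_e_b = cfg$sigma_e_b,
                  sigma_i = cfg$sigma_i),
    network_params(mu = cfg$mu, th = cfg$th, kappa_i = cfg$kappa_i,
                   tau_p = cfg$tau_p, noise_eps = cfg$noise_eps,
                   dt = cfg$dt, ic_amp = cfg$ic_amp),
    ring_grid(cfg$n_units))
}

#' @rdname config_model
#' @export
config_stimulus <- function(cfg) {
  stimulus_spec(ps = cfg$ps, pw = cfg$pw, va_direction = cfg$va_direction,
                rel_strength = cfg$rel_strength,
                n_components = cfg$n_components)
}

#' @rdname config_model
#' @export
config_schedule <- function(cfg) {
  kp <- kernel_params(alpha = cfg$alpha, beta = cfg$beta,
                      sigma_e_a = cfg$sigma_e_a, sigma_e_b = cfg$sigma_e_b,
                      sigma_i = cfg$sigma_i)
  inhibition_schedule(g_i_final = kp$g_i + kp$beta, g_i_low = cfg$g_i_low,
                      tau_l = cfg$tau_l, onset = cfg$onset)
}
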