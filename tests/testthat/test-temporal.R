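test_that("tuning sweep covers all directions and is rotation-consistent", {
  m <- seg_model(72)   # 5-degree spacing
  spec <- stimulus_spec(ps = 40, pw = 15)
  tm <- tuning_sweep(spec, m, n_directions = 8)
  expect_s3_class(tm, "tuning_matrix")
  expect_equal(dim(tm$response), c(72, 8))
  expect_length(tm$stim_directions, 8)
  expect_true(all(tm$converged))
  ## the symmetric small-PS stimulus integrates at every direction, so all
  ## labels agree
  expect_equal(length(unique(tm$labels)), 1)
  ## rotational equivariance: the response to direction d+45 is the
  ## response to d shifted by 45 degrees (9 grid steps)
  i1 <- which(tm$stim_directions == 0)
  i2 <- which(tm$stim_directions == 45)
  shift <- 9L
  r1 <- tm$response[, i1]
  expect_equal(tm$response[, i2],
               c(r1[(72 - shift + 1):72], r1[1:(72 - shift)]),
               tolerance = 1e-4)
})

test_that("single-cell tuning extracts the preferred unit's row", {
  m <- seg_model(72)
  spec <- stimulus_spec(ps = 40, pw = 15)
  tm <- tuning_sweep(spec, m, n_directions = 8)
  sc <- single_cell_tuning(tm, preferred_direction = 0)
  expect_equal(nrow(sc), 8)
  k <- which.min(circ_dist(m$grid$theta, 0))
  expect_equal(sc$response, tm$response[k, ])
  labs <- single_cell_labels(tm)
  expect_length(labs, 72)
})

test_that("a constant schedule reproduces stationary dynamics", {
  m <- seg_model(64)
  spec <- stimulus_spec(ps = 120, pw = 10)
  const <- inhibition_schedule(g_i_final = m$kernel$inh_coef,
                               g_i_low = m$kernel$inh_coef, tau_l = 50)
  ramp <- simulate_ramp(spec, m, schedule = const, t_end = 300, seed = 5)
  inp <- make_input(spec, m$grid)
  set.seed(5)
  u0 <- runif(64, 0, m$np$ic_amp)
  tr <- integrate_field(m, inp, u0 = u0, t_end = 300, record_every = 10)
  expect_equal(ramp$states[, ncol(ramp$states)],
               tr$states[, ncol(tr$states)], tolerance = 1e-6)
  expect_true(all(ramp$g_i == m$kernel$inh_coef))
})

test_that("rising inhibition drives the integration-to-segmentation switch", {
  m <- seg_model(102)
  ## PS above the tri-stability window: the integrated state cannot
  ## survive the full-inhibition regime
  spec <- stimulus_spec(ps = 150, pw = 10)
  ## start from weak inhibition (integration regime) and ramp up to the
  ## stationary segmentation value
  sc <- inhibition_schedule(g_i_final = m$kernel$inh_coef, g_i_low = 2,
                            tau_l = 60)
  ramp <- simulate_ramp(spec, m, schedule = sc, t_end = 600, seed = 3)
  labs <- ramp$label_track$label
  expect_equal(labs[length(labs)], "WTA")
  ## the weak-inhibition phase integrates: a sustained VA run precedes
  ## the final segregated phase (the first few samples are the transient
  ## from the random initial condition and carry other labels)
  runs <- rle(labs)
  va_runs <- which(runs$values == "VA" & runs$lengths >= 3)
  expect_gt(length(va_runs), 0)
  ends <- cumsum(runs$lengths)
  last_wta_start <- ends[length(ends)] - runs$lengths[length(runs$lengths)] + 1
  expect_lt(ends[va_runs[1]], last_wta_start)
  ## the schedule itself is recorded monotonically
  expect_true(all(diff(ramp$g_i) >= 0))
})

test_that("ramp_transition reports the first sustained change", {
  fake <- list(label_track = data.frame(
    t = seq(0, 150, by = 10),
    g_i = 1,
    label = c("UNTUNED", "VA", "VA", "VA", "VA", "TP", "VA", "TP", "TP",
              "TP", "TP", "TP", "TP", "TP", "TP", "TP")))
  tr <- ramp_transition(fake, sustain = 3, settle_t = 10)
  expect_equal(tr$from, "VA")
  expect_equal(tr$to, "TP")
  expect_equal(tr$t, 70)   # the isolated TP at t = 50 does not sustain
  ## no change: NA transition
  fake2 <- list(label_track = data.frame(
    t = seq(0, 50, by = 10), g_i = 1, label = rep("VA", 6)))
  tr2 <- ramp_transition(fake2)
  expect_true(is.na(tr2$t))
  expect_equal(tr2$from, "VA")
})

test_that("ramp sensitivity tabulates the schedule grid", {
  m <- seg_model(64)
  spec <- stimulus_spec(ps = 120, pw = 10)
  out <- ramp_sensitivity(spec, m, onsets = c(0, 50), tau_ls = 40,
                          g_i_finals = m$kernel$inh_coef, t_end = 200,
                          seed = 2)
  expect_equal(nrow(out), 2)
  expect_true(all(c("onset", "tau_l", "g_i_final", "early_label",
                    "late_label", "transition_time") %in% names(out)))
})

test_that("tuning matrix export roundtrips", {
  m <- seg_model(36)
  spec <- stimulus_spec(ps = 40, pw = 15)
  tm <- tuning_sweep(spec, m, n_directions = 4)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_tuning_matrix(tm, path)
  df <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(df), 36)
  expect_equal(ncol(df), 5)   # preferred direction + 4 stimulus columns
  expect_equal(df[[2]], tm$response[, 1])
})
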