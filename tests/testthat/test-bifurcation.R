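## continuation tests run at n = 102 (grid-refinement agreement with the
## full resolution is checked in the acceptance file)

test_that("analytic Jacobian matches central finite differences", {
  g <- small_grid(24)
  k <- build_kernel(kernel_params(0.4, -3), g)
  np <- network_params()
  set.seed(1)
  u <- runif(24, -0.2, 0.4)
  J <- field_jacobian(u, k, np)
  iv <- numeric(24)
  h <- 1e-6
  J_num <- matrix(0, 24, 24)
  for (j in seq_len(24)) {
    e <- numeric(24); e[j] <- h
    J_num[, j] <- (field_rhs(u + e, k, iv, np) -
                     field_rhs(u - e, k, iv, np)) / (2 * h)
  }
  expect_equal(J, J_num, tolerance = 1e-6)
})

test_that("newton converges quickly from an integration endpoint", {
  m <- seg_model(64)
  inp <- make_input(stimulus_spec(ps = 120, pw = 10), m$grid)
  tr <- integrate_field(m, inp, u0 = inp$values, t_end = 300)
  ns <- newton_steady_state(tr$states[, ncol(tr$states)], m$kernel,
                            inp$values, m$np)
  expect_true(ns$converged)
  expect_lt(ns$residual, 1e-10)
})

test_that("zero input yields the zero fixed point", {
  m <- seg_model(32)
  ns <- newton_steady_state(numeric(32), m$kernel, numeric(32), m$np)
  expect_true(ns$converged)
  expect_equal(ns$u, numeric(32))
})

test_that("continuation in kappa_i starts at the rest state and is smooth", {
  ## input-dominated regime (broad excitation, balanced inhibition): the
  ## driven branch deforms smoothly without folds
  m <- seg_model(64, alpha = 1, beta = 0)
  spec <- stimulus_spec(ps = 120, pw = 10)
  ## at kappa_i = 0 the rest state u = 0 solves the system exactly
  b <- continue_branch(m, spec, numeric(64), "kappa_i",
                       p_from = 0, p_to = 0.1, ds0 = 0.01, ds_max = 0.02)
  b <- detect_special_points(b)
  expect_gt(nrow(b$points), 5)
  expect_equal(b$points$energy[1], 0, tolerance = 1e-9)
  expect_true(all(diff(b$points$p) > 0))       # no fold on this branch
  expect_equal(nrow(b$special_points), 0)
  expect_true(all(abs(diff(b$points$energy)) < 0.2))  # continuous growth
})

test_that("VA is the only stable solution at small PS and loses stability at a pitchfork", {
  m <- seg_model(102)
  spec <- stimulus_spec(ps = 20, pw = 10)
  inp <- make_input(spec, m$grid)
  ss <- find_steady_state(m, inp, u0 = inp$values, t_max = 1500)
  b <- continue_branch(m, spec, ss$u_star, "ps", 20, 180,
                       ds0 = 2, ds_max = 5, max_steps = 150)
  b <- detect_special_points(b)
  pts <- b$points
  expect_true(all(pts$stable[pts$p < 100]))
  expect_false(all(pts$stable))
  bp <- b$special_points[b$special_points$type == "branch_point", ]
  expect_gt(nrow(bp), 0)
  ## stability is lost exactly at the first branch point
  expect_equal(max(pts$p[pts$stable & pts$p < 150]), bp$p[1], tolerance = 6)
})

test_that("switch_branch lands on the two mirror WTA states", {
  m <- seg_model(102)
  spec <- stimulus_spec(ps = 20, pw = 10)
  inp <- make_input(spec, m$grid)
  ss <- find_steady_state(m, inp, u0 = inp$values, t_max = 1500)
  b <- detect_special_points(
    continue_branch(m, spec, ss$u_star, "ps", 20, 180,
                    ds0 = 2, ds_max = 5, max_steps = 150))
  sw_p <- switch_branch(b, direction = 1, eps = 0.8, dp = -2)
  sw_m <- switch_branch(b, direction = -1, eps = 0.8, dp = -2)
  expect_true(sw_p$converged && sw_m$converged)
  g <- m$grid
  pk_p <- rad2deg(g$theta[which.max(sw_p$u)])
  pk_m <- rad2deg(g$theta[which.max(sw_m$u)])
  expect_gt(abs(pk_p), 2)                      # genuinely asymmetric
  expect_equal(pk_p, -pk_m, tolerance = 1e-6)  # mirror pair
  ## reflecting one solution reproduces the other
  n <- g$n
  refl <- c(1L, n:2L)   # theta -> -theta on this grid
  expect_equal(sw_p$u[refl], sw_m$u, tolerance = 1e-6)
})

test_that("branch stability flags agree with integration escape", {
  m <- seg_model(102)
  spec <- stimulus_spec(ps = 20, pw = 10)
  inp <- make_input(spec, m$grid)
  ss <- find_steady_state(m, inp, u0 = inp$values, t_max = 1500)
  b <- continue_branch(m, spec, ss$u_star, "ps", 20, 180,
                       ds0 = 2, ds_max = 5, max_steps = 150)
  pts <- b$points
  probe <- function(row) {
    sp_p <- stimulus_spec(ps = pts$p[row], pw = 10)
    iv <- make_input(sp_p, m$grid)
    u0 <- b$states[, row]
    ## odd (symmetry-breaking) perturbation
    u0 <- u0 + 1e-3 * sin(m$grid$theta)
    tr <- integrate_field(m, iv, u0 = u0, t_end = 400, record_every = 400)
    max(abs(tr$states[, ncol(tr$states)] - b$states[, row]))
  }
  i_stable <- which(pts$stable & pts$p > 50 & pts$p < 80)[1]
  i_unstable <- which(!pts$stable & pts$p > 130 & pts$p < 160)[1]
  expect_lt(probe(i_stable), 1e-3)    # returns to the branch state
  expect_gt(probe(i_unstable), 0.05)  # escapes
})

test_that("continuation fold agrees with a dense hysteresis sweep", {
  m <- seg_model(102)
  spec <- stimulus_spec(ps = 110, pw = 10)
  inp <- make_input(spec, m$grid)
  ## two-peaked attractor at PS = 110, inside the multistable window
  ss <- find_steady_state(m, inp, u0 = inp$values, t_max = 1500)
  expect_equal(classify_solution(ss, spec)$label, "TP")
  b <- detect_special_points(
    continue_branch(m, spec, ss$u_star, "ps", 110, 20,
                    ds0 = 1, ds_max = 2, max_steps = 120))
  folds <- b$special_points$p[b$special_points$type == "fold"]
  expect_gt(length(folds), 0)
  ## brute-force oracle: carry the TP state downward in 0.5-degree steps
  ## until it stops existing
  u <- ss$u_star
  ps_lost <- NA_real_
  for (ps in seq(109.5, 70, by = -0.5)) {
    sp_k <- stimulus_spec(ps = ps, pw = 10)
    sk <- find_steady_state(m, make_input(sp_k, m$grid), u0 = u)
    if (classify_solution(sk, sp_k)$label != "TP") { ps_lost <- ps; break }
    u <- sk$u_star
  }
  expect_false(is.na(ps_lost))
  expect_equal(folds[1], ps_lost, tolerance = 2)
})

test_that("branch export writes special point annotations", {
  m <- seg_model(64)
  spec <- stimulus_spec(ps = 40, pw = 10)
  inp <- make_input(spec, m$grid)
  ss <- find_steady_state(m, inp, u0 = inp$values)
  b <- detect_special_points(
    continue_branch(m, spec, ss$u_star, "ps", 40, 80, ds0 = 2, ds_max = 5))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_branch_csv(b, path)
  df <- read.csv(path)
  expect_true(all(c("p", "energy", "max_re", "stable", "special_type")
                  %in% names(df)))
  expect_equal(nrow(df), nrow(b$points))
})
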