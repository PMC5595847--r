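test_that("sigmoid matches its closed form and vanishes at rest", {
  ## S(u) = logistic(mu*u - th) - logistic(-th): S(0) = 0 by construction
  expect_equal(sigmoid(0), 0)
  expect_equal(sigmoid(0.5, mu = 16, th = 3), 0.945881, tolerance = 1e-6)
  expect_equal(sigmoid(0.5, mu = 16, th = 3),
               plogis(16 * 0.5 - 3) - plogis(-3))
  u <- seq(-1, 2, length.out = 200)
  s <- sigmoid(u)
  expect_true(all(diff(s) > 0))                    # strictly increasing
  expect_true(all(s > -plogis(-3) - 1e-12 & s < 1))
})

test_that("sigmoid derivative matches central finite differences", {
  u <- c(-0.5, 0, 0.1, 0.3, 1)
  h <- 1e-6
  num <- (sigmoid(u + h) - sigmoid(u - h)) / (2 * h)
  expect_equal(sigmoid_deriv(u), num, tolerance = 1e-7)
})

test_that("FFT circular convolution matches dense quadrature", {
  set.seed(42)
  for (n in c(32, 101)) {
    g <- ring_grid(n)
    for (a in c(0, 0.6)) {
      k <- build_kernel(kernel_params(alpha = a, beta = -7), g)
      v <- rnorm(n)
      expect_equal(ring_conv(k, v), dense_conv(k, v), tolerance = 1e-10)
      ## rescaled inhibition (slow-inhibition path) stays consistent
      expect_equal(ring_conv(k, v, inh_coef = 3),
                   dense_conv(k, v, inh_coef = 3), tolerance = 1e-10)
    }
  }
})

test_that("convolution of a constant is the kernel integral times it", {
  g <- ring_grid(128)
  k <- build_kernel(kernel_params(0, 0), g)
  f0 <- kernel_fourier(k)
  expect_equal(ring_conv(k, rep(2, 128)), rep(2 * f0, 128),
               tolerance = 1e-10)
})

test_that("conv_matrix agrees with ring_conv", {
  g <- ring_grid(48)
  k <- build_kernel(kernel_params(0.3, -2), g)
  cm <- conv_matrix(k)
  C <- cm$exc - k$inh_coef * cm$inh
  set.seed(7)
  v <- rnorm(48)
  expect_equal(as.numeric(C %*% v), ring_conv(k, v), tolerance = 1e-10)
})

test_that("zero input leaves the rest state fixed", {
  m <- seg_model(48)
  tr <- integrate_field(m, numeric(48), u0 = numeric(48), t_end = 50)
  expect_lt(max(abs(tr$states[, ncol(tr$states)])), 1e-9)
})

test_that("deterministic integration reaches a steady state", {
  m <- seg_model(64)
  inp <- make_input(stimulus_spec(ps = 120, pw = 10), m$grid)
  ss <- find_steady_state(m, inp, seed = 1)
  expect_s3_class(ss, "steady_state")
  expect_true(ss$converged)
  expect_lt(ss$residual, 1e-9)
  expect_gt(ss$energy, 0)
  ## the residual really is the fixed-point defect
  r <- field_rhs(ss$u_star, m$kernel, inp$values, m$np)
  expect_lt(max(abs(r)), 1e-9)
})

test_that("Euler-Maruyama without noise tracks the adaptive solver", {
  m <- seg_model(64)
  inp <- make_input(stimulus_spec(ps = 60, pw = 15), m$grid)
  set.seed(3)
  u0 <- runif(64, 0, 0.1)
  det <- integrate_field(m, inp, u0 = u0, t_end = 200, record_every = 200)
  em <- integrate_field(m, inp, u0 = u0, t_end = 200, record_every = 200,
                        method = "em")
  expect_equal(em$states[, ncol(em$states)], det$states[, ncol(det$states)],
               tolerance = 1e-3)
})

test_that("stochastic paths are seed-reproducible and noise-dependent", {
  m <- seg_model(48, noise_eps = 0.01)
  inp <- make_input(stimulus_spec(ps = 120, pw = 10), m$grid)
  t1 <- integrate_field(m, inp, t_end = 20, seed = 11)
  t2 <- integrate_field(m, inp, t_end = 20, seed = 11)
  t3 <- integrate_field(m, inp, t_end = 20, seed = 12)
  expect_identical(t1$states, t2$states)
  expect_gt(max(abs(t1$states - t3$states)), 0)
})

test_that("steady states rotate with the stimulus", {
  m <- seg_model(90)   # 4-degree spacing
  sp <- stimulus_spec(ps = 120, pw = 10, va_direction = 0)
  inp <- make_input(sp, m$grid)
  ss <- find_steady_state(m, inp, u0 = inp$values)
  sp_r <- stimulus_spec(ps = 120, pw = 10, va_direction = 40)
  inp_r <- make_input(sp_r, m$grid)
  shift <- round(deg2rad(40) / m$grid$dtheta)
  u0_r <- c(ss$u_star[(90 - shift + 1):90], ss$u_star[1:(90 - shift)])
  ss_r <- find_steady_state(m, inp_r, u0 = u0_r)
  expect_equal(ss_r$u_star, u0_r, tolerance = 1e-6)
})

test_that("simulate method returns reproducible trajectory lists", {
  m <- seg_model(32, noise_eps = 0.01)
  inp <- make_input(stimulus_spec(ps = 90, pw = 15), m$grid)
  s1 <- simulate(m, nsim = 2, seed = 5, input = inp, t_end = 10)
  s2 <- simulate(m, nsim = 2, seed = 5, input = inp, t_end = 10)
  expect_length(s1, 2)
  expect_identical(s1[[1]]$states, s2[[1]]$states)
  expect_identical(s1[[2]]$states, s2[[2]]$states)
  expect_gt(max(abs(s1[[1]]$states - s1[[2]]$states)), 0)
})

test_that("energy is the l2 norm with quadrature weight", {
  g <- ring_grid(36)
  u <- rep(1, 36)
  expect_equal(energy(u, g), sqrt(2 * pi), tolerance = 1e-12)
})

test_that("steady-state CSV export roundtrips", {
  m <- seg_model(32)
  inp <- make_input(stimulus_spec(ps = 120, pw = 15), m$grid)
  ss <- find_steady_state(m, inp, seed = 2)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_steady_state_csv(ss, path)
  df <- read.csv(path)
  expect_equal(df$u, ss$u_star)
})
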