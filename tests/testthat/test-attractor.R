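test_that("attractor strength is seed-reproducible and sums to one", {
  m <- seg_model(64, noise_eps = 0.01)
  spec <- stimulus_spec(ps = 120, pw = 10)
  a1 <- attractor_strength(m, spec, n_trials = 6, seed = 9, t_max = 500)
  a2 <- attractor_strength(m, spec, n_trials = 6, seed = 9, t_max = 500)
  expect_identical(a1$labels, a2$labels)
  expect_equal(sum(a1$probs), 1)
  expect_equal(sum(a1$raw), 1)
  expect_true(all(a1$labels %in%
                    c("VA", "WTA", "SB", "TP", "UNTUNED", "NONCONVERGED")))
})

test_that("WTA and SB pool into one class", {
  m <- seg_model(64, noise_eps = 0.01)
  spec <- stimulus_spec(ps = 120, pw = 10)
  a <- attractor_strength(m, spec, n_trials = 6, seed = 9, t_max = 500)
  expect_equal(a$probs[["WTA/SB"]],
               a$raw[["WTA"]] + a$raw[["SB"]])
})

test_that("deterministic trials at large PS yield segregated solutions", {
  m <- seg_model(102)
  spec <- stimulus_spec(ps = 160, pw = 10)
  a <- attractor_strength(m, spec, n_trials = 4, seed = 2, t_max = 1000)
  ## in the segmentation regime no trial integrates to VA at PS = 160
  expect_equal(a$probs[["VA"]], 0)
  expect_gt(a$probs[["WTA/SB"]] + a$probs[["TP"]], 0.5)
})

test_that("derived seeds are deterministic, distinct and below 2^31", {
  s1 <- mtring:::derive_seed(1, 3, 7)
  s2 <- mtring:::derive_seed(1, 3, 7)
  expect_identical(s1, s2)
  expect_true(is.integer(s1))
  expect_lt(s1, 2^31)
  expect_gte(s1, 1)
  grid_seeds <- outer(1:20, 1:20,
                      Vectorize(function(i, j) mtring:::derive_seed(5, i, j)))
  expect_equal(length(unique(as.vector(grid_seeds))), 400)
})

test_that("probability map cells reproduce standalone evaluations", {
  np <- network_params(noise_eps = 0.01)
  grid <- ring_grid(64)
  kp <- kernel_params(0, -10)
  spec <- stimulus_spec(ps = 120, pw = 10)
  pm <- probability_map(axis1 = list(name = "ps", values = c(60, 150)),
                        axis2 = list(name = "pw", values = c(10, 20)),
                        spec = spec, kp = kp, np = np, grid = grid,
                        n_trials = 3, seed = 4, t_max = 400)
  ## recompute cell (2, 1) independently: ps = 150, pw = 10
  sp <- stimulus_spec(ps = 150, pw = 10)
  m <- ring_network(kp, np, grid)
  a <- attractor_strength(m, sp, n_trials = 3,
                          seed = mtring:::derive_seed(4, 2, 1), t_max = 400)
  for (l in names(pm$probs))
    expect_equal(pm$probs[[l]][2, 1], a$probs[[l]])
})

test_that("connectivity axes rebuild the kernel per cell", {
  np <- network_params()
  grid <- ring_grid(48)
  spec <- stimulus_spec(ps = 120, pw = 10)
  pm <- probability_map(axis1 = list(name = "alpha", values = c(0, 1)),
                        axis2 = list(name = "beta", values = c(-10, 10)),
                        spec = spec, kp = kernel_params(), np = np,
                        grid = grid, n_trials = 2, seed = 1, t_max = 300)
  expect_equal(dim(pm$probs$VA), c(2, 2))
  expect_true(all(vapply(pm$probs, function(p) all(p >= 0 & p <= 1),
                         logical(1))))
})

test_that("migration of identical maps is diagonal", {
  np <- network_params()
  grid <- ring_grid(48)
  spec <- stimulus_spec(ps = 120, pw = 10)
  ## an odd trial count means no class can tie at probability exactly 0.5,
  ## so each cell supports at most one class and the overlap matrix of a
  ## map with itself is purely diagonal
  pm <- probability_map(axis1 = list(name = "ps", values = c(40, 160)),
                        axis2 = list(name = "pw", values = c(10, 25)),
                        spec = spec, kp = kernel_params(0, -10), np = np,
                        grid = grid, n_trials = 3, seed = 3, t_max = 400)
  mg <- migration(pm, pm)
  ov <- mg$overlap
  for (a in rownames(ov)) for (b in colnames(ov)) {
    if (a != b) expect_equal(ov[a, b], 0)
  }
  ## diagonal entries equal each class's own support area
  for (a in rownames(ov))
    expect_equal(ov[a, a], 100 * sum(pm$probs[[a]] >= 0.5) /
                   length(pm$probs[[a]]))
})

test_that("migration rejects mismatched axes", {
  np <- network_params(); grid <- ring_grid(32)
  spec <- stimulus_spec(ps = 120, pw = 10)
  mk <- function(vals)
    probability_map(axis1 = list(name = "ps", values = vals),
                    axis2 = list(name = "pw", values = c(10, 25)),
                    spec = spec, kp = kernel_params(0, -10), np = np,
                    grid = grid, n_trials = 1, seed = 1, t_max = 200)
  expect_error(migration(mk(c(40, 160)), mk(c(40, 150))), "axes")
})

test_that("probability-map export writes CSVs and a manifest", {
  np <- network_params(); grid <- ring_grid(32)
  spec <- stimulus_spec(ps = 120, pw = 10)
  pm <- probability_map(axis1 = list(name = "ps", values = c(60, 150)),
                        axis2 = list(name = "pw", values = 10),
                        spec = spec, kp = kernel_params(0, -10), np = np,
                        grid = grid, n_trials = 1, seed = 1, t_max = 200)
  dir <- tempfile("pmap")
  on.exit(unlink(dir, recursive = TRUE))
  manifest <- write_probability_map(pm, dir)
  expect_true(file.exists(manifest))
  meta <- jsonlite::read_json(manifest)
  expect_equal(meta$n_trials, 1)
  f <- file.path(dir, "pmap_VA.csv")
  expect_true(file.exists(f))
  df <- read.csv(f)
  expect_equal(nrow(df), 2)
  expect_true(all(c("ps", "pw", "probability") %in% names(df)))
})
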