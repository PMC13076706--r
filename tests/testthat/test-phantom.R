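# Synthetic study generator: phantoms, forward measurement chain, raw-S11
# layer, CT synthesis, whole-study assembly.

test_that("hole layouts honor the study designs and lattice spacing", {
  for (n in c(16, 20, 25)) {
    l <- hole_layout(n)
    expect_equal(nrow(l), n)
    dmin <- min(stats::dist(cbind(l$x_mm, l$y_mm)))
    expect_gte(dmin, 4 - 1e-9)
  }
})

test_that("phantoms are deterministic and match requested field statistics", {
  p1 <- make_phantom(16, 1.771, 0.185, seed = 13, specimen = "A")
  p2 <- make_phantom(16, 1.771, 0.185, seed = 13, specimen = "A")
  expect_identical(p1$field, p2$field)
  expect_lt(abs(mean(p1$field) - 1.771) / 1.771, 0.10)
  expect_lt(abs(stats::sd(p1$field) - 0.185) / 0.185, 0.10)
  p0 <- make_phantom(0, 1.3, 0.05, seed = 14)
  expect_equal(nrow(p0$holes), 0)
  expect_equal(phantom_true_volume(p0), 0)
})

test_that("gain profiles hit the target inter-antenna CV", {
  g <- antenna_gain_profile(0.08, seed = 15)
  expect_length(g, 16)
  expect_true(all(g > 0))
  expect_equal(100 * stats::sd(g) / mean(g), 8, tolerance = 1e-9)
})

test_that("hole-free constant phantoms give constant noise-free grids", {
  ph <- make_phantom(0, 1.5, 0, seed = 16)
  k <- gaussian_kernel(3)
  g <- simulate_coarse_grids(ph, k, noise_sd = 0, coupling_sd = 0,
                             condition = "pre", seed = 1)[[1]]
  expect_lt(diff(range(g$values)), 1e-9)
  expect_equal(g$values[1, 1], 1.5, tolerance = 1e-9)
})

test_that("pre and post readings differ only near hole footprints", {
  ph <- make_phantom(16, 1.6, 0.1, seed = 17, specimen = "L")
  k <- gaussian_kernel(3)
  pre <- simulate_coarse_grids(ph, k, noise_sd = 0, coupling_sd = 0,
                               condition = "pre", seed = 1)[[1]]
  post <- simulate_coarse_grids(ph, k, noise_sd = 0, coupling_sd = 0,
                                condition = "post", seed = 1)[[1]]
  d <- abs(post$values - pre$values)
  cellx <- (0:15) * 4
  far <- outer(cellx, cellx, function(y, x) {
    dmin <- apply(cbind(x, y), 1, function(p)
      min(sqrt((ph$holes$x_mm - p[1])^2 + (ph$holes$y_mm - p[2])^2)))
    matrix(dmin, length(y))
  })
  support <- max(k$radii_mm) + 1
  expect_true(all(d[far > support] < 1e-12))
  expect_gt(max(d[far <= 2]), 0.1)
})

test_that("a single-hole reading matches a brute-force quadrature oracle", {
  ph <- make_phantom(0, 1.5, 0, seed = 18)
  ph$holes <- data.frame(x_mm = 28, y_mm = 28, diameter_mm = 2,
                         depth_mm = 8, fill_fraction = 1)
  k <- gaussian_kernel(3)
  prof <- default_depth_profile()
  g <- simulate_coarse_grids(ph, k, profile = prof, noise_sd = 0,
                             coupling_sd = 0, condition = "post",
                             seed = 1)[[1]]
  # cell (8, 8) sits at (28, 28), concentric with the hole: brute-force
  # radial quadrature of kernel x column refractive index
  r <- seq(5e-5, 9, by = 1e-4)
  w <- kernel_density_at(k, r) * 2 * pi * r * 1e-4
  lw <- mwivol:::column_layer_weights(1, 8, prof$delta_mm)
  colsq <- ifelse(r <= 1, lw$fluid * sqrt(62) + lw$air + lw$bone * sqrt(1.5),
                  sqrt(1.5))
  oracle <- (sum(w * colsq) / sum(w))^2
  expect_equal(g$values[8, 8], oracle, tolerance = 1e-5)
})

test_that("the raw-S11 layer closes the loop through calibration", {
  pp <- probe_params(25e-15, 20e-15)
  f <- default_sweep_frequencies()
  terms <- error_terms(f, 0.1 + 0.05i, 0.9 + 0i, -0.02 + 0i)
  set.seed(19)
  vals <- matrix(runif(256, 1, 4), 16, 16)
  grid <- coarse_grid(vals)
  layer <- simulate_s11_layer(grid, pp, terms)
  rec <- invert_sweeps_to_grid(layer$sweeps, layer$standards, pp)
  expect_lt(max(abs(rec - vals) / vals), 0.005)
  # identity error terms leave the raw forward coefficients untouched
  layer_id <- simulate_s11_layer(grid, pp, identity_terms(f))
  raw <- forward_gamma(rep(vals[1, 1], length(f)), f, pp)
  expect_lt(max(Mod(layer_id$sweeps[[1, 1]]$gamma - raw)), 1e-12)
})

test_that("study generation is deterministic and mirrors the design", {
  cfg <- study_config(seed = 3, include_ct = FALSE)
  st <- generate_study(cfg)
  expect_equal(st$ground_truth$n_holes, c(16L, 16L, 25L, 25L, 20L, 20L, 16L))
  expect_equal(st$ground_truth$injected_ul,
               st$ground_truth$n_holes * pi * 8, tolerance = 1e-12)
  expect_equal(st$ground_truth$scaled_ul,
               st$ground_truth$injected_ul * 0.16875, tolerance = 1e-9)
  st2 <- generate_study(study_config(seed = 3, include_ct = FALSE))
  expect_identical(st$specimens[[4]]$pre_grids[[2]]$values,
                   st2$specimens[[4]]$pre_grids[[2]]$values)
})

test_that("realized inter-antenna CV sits in the study's observed range", {
  cfg <- study_config(seed = 5, include_ct = FALSE)
  st <- generate_study(cfg)
  cvs <- vapply(st$specimens, function(sp) interantenna_cv(sp$pre_grids), 0)
  expect_true(all(cvs >= 5 & cvs <= 11))
})
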