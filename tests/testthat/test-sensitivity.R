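# Radial-kernel inversion, sigmoid fits, depth profile.

test_that("kernel inversion recovers uniform and compactly supported kernels", {
  d <- seq(4, 16, by = 2)
  # R(D) proportional to D^2: uniform disc sensitivity
  unif <- response_curve(d, (d / 16)^2)
  k <- invert_radial_kernel(unif)
  expect_lt(diff(range(k$density)), 1e-12)
  # response saturating at D = 6: no sensitivity beyond r = 3 mm
  sat <- response_curve(d, c(0.5, 1, 1, 1, 1, 1, 1))
  ks <- invert_radial_kernel(sat)
  expect_true(all(ks$density[ks$radii_mm > 3] == 0))
  expect_lte(ks$r_eq_mm, 3)
})

test_that("kernel inversion matches annulus-averaged truth for a Gaussian", {
  d <- seq(4, 16, by = 2)
  dens <- function(r) exp(-r^2 / (2 * 3^2))
  curve <- response_curve(d, forward_cumulative(dens, d))
  k <- invert_radial_kernel(curve)
  # annulus-averaged truth, normalized over the same support
  edges <- c(0, d / 2)
  truth <- vapply(seq_along(d), function(i)
    stats::integrate(function(r) dens(r) * 2 * pi * r,
                     edges[i], edges[i + 1])$value /
      (pi * (edges[i + 1]^2 - edges[i]^2)), 0)
  truth <- truth / sum(truth * pi * diff(edges^2))
  expect_lt(max(abs(k$density - truth)), 0.02)
})

test_that("non-monotone curves are rejected beyond the isotonic tolerance", {
  d <- seq(4, 16, by = 2)
  bad <- response_curve(d, c(0.2, 0.6, 0.4, 0.8, 0.9, 1.0, 0.95))
  expect_error(invert_radial_kernel(bad), "non-monotone")
})

test_that("r_eq grows with the quantile parameter", {
  d <- seq(4, 16, by = 2)
  curve <- response_curve(d, forward_cumulative(function(r)
    exp(-r^2 / 18), d))
  q <- c(0.5, 0.7, 0.9, 0.95)
  r_eq <- vapply(q, function(x) invert_radial_kernel(curve, x)$r_eq_mm, 0)
  expect_true(all(diff(r_eq) > 0))
})

test_that("sigmoid fit is self-consistent and robust to mild noise", {
  x <- seq(-15, 15, by = 1)
  y <- 0.05 + 0.9 / (1 + exp(-(x - 1.5) / 2.5))
  fit <- fit_sigmoid(response_curve(x, y, "side_to_side"))
  expect_equal(fit$midpoint_mm, 1.5, tolerance = 1e-6)
  expect_equal(fit$scale_mm, 2.5, tolerance = 1e-6)
  expect_equal(fit$lo, 0.05, tolerance = 1e-6)
  expect_equal(fit$hi, 0.95, tolerance = 1e-6)

  expect_error(fit_sigmoid(response_curve(x, rep(0.5, 31), "side_to_side")),
               "unidentifiable|constant")

  set.seed(21)
  fitn <- fit_sigmoid(response_curve(x, y + rnorm(31, 0, 0.01),
                                     "side_to_side"))
  expect_lt(abs(fitn$midpoint_mm - 1.5), 0.2)
})

test_that("depth profile fit recovers the decay constant", {
  t <- seq(0.5, 8, by = 0.5)
  prof <- fit_depth_profile(t, 1 - exp(-t / 1.35))
  expect_equal(prof$delta_mm, 1.35, tolerance = 1e-6)
  # at t = delta the visibility is 1 - 1/e by definition
  expect_equal(1 - exp(-prof$delta_mm / prof$delta_mm), 0.6321206,
               tolerance = 1e-6)
  expect_error(fit_depth_profile(t, rep(0.5, length(t))), "all-equal")
  set.seed(31)
  v <- pmin(pmax(1 - exp(-t / 1.35) + rnorm(length(t), 0, 0.02), 0), 1)
  profn <- fit_depth_profile(t, v)
  expect_lt(abs(profn$delta_mm - 1.35) / 1.35, 0.10)
})

test_that("effective depth saturates and the depth factor decreases in H", {
  prof <- depth_profile(1.35)
  expect_equal(effective_depth(prof, 1e-4), 1e-4, tolerance = 1e-4)
  expect_equal(effective_depth(prof, 100), 1.35, tolerance = 1e-9)
  h <- seq(0.5, 20, by = 0.5)
  rho <- depth_factor(prof, h)
  expect_true(all(rho > 0 & rho < 1))
  expect_true(all(diff(rho) < 0))
  expect_true(all(diff(effective_depth(prof, h)) > 0))
})

test_that("the default profile reproduces the study's depth scaling", {
  prof <- default_depth_profile()
  rho <- depth_factor(prof, 8)
  expect_equal(rho, 0.16875, tolerance = 1e-9)
  expect_equal(402.12 * rho, 67.86, tolerance = 1e-2)
})

test_that("kernel inversion is the discrete inverse of forward integration", {
  # random piecewise kernels: forward-integrate over discs, invert, compare
  set.seed(41)
  d <- seq(4, 16, by = 2)
  for (rep in 1:20) {
    dens <- runif(length(d), 0, 1)
    mass <- cumsum(dens * pi * diff(c(0, (d / 2)^2)))
    curve <- response_curve(d, mass / max(mass))
    k <- invert_radial_kernel(curve)
    expect_equal(k$density, dens / max(mass), tolerance = 1e-10)
  }
})
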