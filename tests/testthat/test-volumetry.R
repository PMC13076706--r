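# CRIM inversion, ROI derivation, depth-weighted integration, repeatability.

test_that("CRIM fraction inverts the mixing rule exactly", {
  expect_equal(as.numeric(crim_fraction(2, 2, 62)), 0)
  expect_equal(as.numeric(crim_fraction(2, 62, 62)), 1)
  phi <- 0.3
  eps_mix <- (phi * sqrt(62) + (1 - phi) * sqrt(2))^2
  expect_equal(as.numeric(crim_fraction(2, eps_mix, 62)), 0.3,
               tolerance = 1e-12)
  expect_error(crim_fraction(5, 6, 4), "contrast")
  clipped <- crim_fraction(c(2, 2), c(1.5, 70), 62)
  expect_equal(attr(clipped, "n_clipped"), 2L)
  expect_true(all(clipped >= 0 & clipped <= 1))
})

test_that("ROI keeps contiguous super-threshold blocks, drops singletons", {
  d <- matrix(0, 30, 30)
  expect_equal(sum(derive_roi(d, 1)), 0)
  d[10:14, 10:14] <- 5   # 5x5 block
  d[25, 25] <- 5         # isolated singleton
  roi <- derive_roi(d, 1, k = 3, min_pixels = 4)
  expect_true(all(roi[10:14, 10:14]))
  expect_false(roi[25, 25])
  expect_equal(sum(roi), 25)
})

test_that("ROI component count matches a flood-fill oracle on a phantom map", {
  ph <- make_phantom(16, 1.5, 0, seed = 77, specimen = "X")
  k <- gaussian_kernel(1.2, max_radius_mm = 4.2)
  pre <- simulate_coarse_grids(ph, k, noise_sd = 0, coupling_sd = 0,
                               condition = "pre", seed = 1)[[1]]
  post <- simulate_coarse_grids(ph, k, noise_sd = 0, coupling_sd = 0,
                                condition = "post", seed = 1)[[1]]
  mpre <- upscale(rotate_to_common(pre), k)
  mpost <- upscale(rotate_to_common(post), k)
  ds <- sqrt(mpost$pixels) - sqrt(mpre$pixels)
  roi <- derive_roi(ds, noise_sd = max(ds) / 50, k = 3)
  lab_pkg <- mwivol:::label_components8(roi)
  lab_oracle <- flood_components(roi, eight = TRUE)
  expect_equal(max(lab_pkg), max(lab_oracle))
  expect_gte(max(lab_pkg), 1)
})

test_that("volume integration matches the closed-form cylinder", {
  prof <- default_depth_profile()
  px <- 0.1
  # phi = 1 over exactly one 2-mm hole footprint
  n <- 100
  phi <- matrix(0, n, n)
  cx <- (n / 2 - 0.5)
  for (i in 1:n) for (j in 1:n)
    if (((i - 1) - cx)^2 + ((j - 1) - cx)^2 <= (1 / px)^2) phi[i, j] <- 1
  fm <- fluid_fraction_map(phi, px, phi > 0)
  v <- integrate_volume(fm, prof, 8)
  expect_equal(v, 25.13 * 0.16875, tolerance = 0.01)
  # empty ROI integrates to zero
  fm0 <- fluid_fraction_map(phi, px, matrix(FALSE, n, n))
  expect_equal(integrate_volume(fm0, prof, 8), 0)
})

test_that("a noiseless 16-hole specimen recovers the depth-scaled truth", {
  ph <- make_phantom(16, 1.771, 0.185, seed = 42, specimen = "A")
  k <- gaussian_kernel(3)
  pre <- simulate_coarse_grids(ph, k, noise_sd = 0, coupling_sd = 0,
                               condition = "pre", seed = 1)
  post <- simulate_coarse_grids(ph, k, noise_sd = 0, coupling_sd = 0,
                                condition = "post", seed = 1)
  est <- estimate_specimen_volume(pre[1], post[1], k)
  expect_lt(abs(est$mean_ul - 16 * 4.24) / (16 * 4.24), 0.10)
})

test_that("estimated volume is monotone in contrast and fill (noise-free)", {
  k <- gaussian_kernel(3)
  run <- function(eps_fluid, fill) {
    ph <- make_phantom(16, 1.5, 0, eps_fluid = eps_fluid,
                       fill_fraction = fill, seed = 5, specimen = "m")
    pre <- simulate_coarse_grids(ph, k, noise_sd = 0, coupling_sd = 0,
                                 condition = "pre", seed = 1)
    post <- simulate_coarse_grids(ph, k, noise_sd = 0, coupling_sd = 0,
                                  condition = "post", seed = 1)
    # the analysis assumes a fixed gel permittivity; the phantom's actual
    # contrast varies, so estimated volume must grow with it
    estimate_specimen_volume(pre[1], post[1], k, eps_fluid = 62)$mean_ul
  }
  v_contrast <- c(run(30, 1), run(62, 1), run(80, 1))
  expect_true(all(diff(v_contrast) >= -1e-9))
  v_fill <- c(run(62, 0.4), run(62, 0.7), run(62, 1))
  expect_true(all(diff(v_fill) >= -1e-9))
})

test_that("halving the pixel size changes the integrated volume by < 1%", {
  ph <- make_phantom(16, 1.6, 0.1, seed = 8, specimen = "R")
  k <- gaussian_kernel(3)
  pre <- simulate_coarse_grids(ph, k, noise_sd = 0, coupling_sd = 0,
                               condition = "pre", seed = 1)
  post <- simulate_coarse_grids(ph, k, noise_sd = 0, coupling_sd = 0,
                                condition = "post", seed = 1)
  v1 <- estimate_specimen_volume(pre[1], post[1], k,
                                 pixel_size_mm = 1)$mean_ul
  v05 <- estimate_specimen_volume(pre[1], post[1], k,
                                  pixel_size_mm = 0.5)$mean_ul
  expect_lt(abs(v05 - v1) / v1, 0.01)
})

test_that("repeatability reproduces the printed summary arithmetic", {
  # four values engineered to the printed specimen-A mean and SD
  z <- c(-3, -1, 1, 3); z <- z / stats::sd(z)
  va <- 75.50 + 2.26 * z
  est <- repeatability(va, "A")
  expect_equal(round(est$cv_percent, 2), 2.99)
  expect_equal(round(est$ci95_ul, 1), c(71.9, 79.1))
  ident <- repeatability(rep(50, 4))
  expect_equal(ident$cv_percent, 0)
  expect_equal(ident$ci95_ul, c(50, 50))
  hand <- repeatability(1:4)
  expect_equal(hand$mean_ul, 2.5)
  expect_equal(round(hand$sd_ul, 4), 1.2910)
  expect_equal(round(hand$cv_percent, 2), 51.64)
  expect_error(repeatability(1), "at least 2")
})
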