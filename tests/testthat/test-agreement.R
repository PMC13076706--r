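# Method-comparison battery against the packaged study fixture and on
# constructed cases.

inj <- function() table2_fixture()$scaled_injected_ul
ctv <- function() table2_fixture()$ct_scaled_ul
mwi <- function() table2_fixture()$mwi_ul

test_that("Pearson/Fisher reproduces both study comparisons", {
  pf <- pearson_fisher(inj(), mwi())
  expect_equal(round(pf$r, 3), 0.811)
  expect_equal(round(pf$ci, 2), c(0.15, 0.97))
  expect_equal(round(pf$p, 3), 0.027)
  expect_equal(round(pearson_fisher(ctv(), mwi())$r, 2), 0.58)
  x <- 1:10
  expect_equal(pearson_fisher(x, 2 * x + 1)$r, 1)
  expect_error(pearson_fisher(rep(1, 5), 1:5), "variance")
})

test_that("Lin's CCC (sample moments) reproduces the study values", {
  cc <- lins_ccc(inj(), mwi())
  expect_equal(round(cc$ccc, 2), 0.70)
  expect_equal(round(cc$cb, 2), 0.86)
  expect_equal(round(lins_ccc(ctv(), mwi())$ccc, 2), 0.23)
  ident <- lins_ccc(1:10, 1:10)
  expect_equal(ident$ccc, 1)
  expect_equal(ident$cb, 1)
})

test_that("Bland-Altman percent differences use the reference denominator", {
  ba <- bland_altman_percent(inj(), mwi())
  expect_equal(round(ba$bias, 1), 12.4)
  expect_equal(round(ba$loa, 1), c(-17.4, 42.2))
  bact <- bland_altman_percent(ctv(), mwi())
  expect_equal(round(bact$bias, 1), 40.9)
  expect_equal(round(bact$sd, 1), 26.1)
  exact <- bland_altman_percent(1:5, 1:5)
  expect_equal(exact$bias, 0)
  expect_equal(exact$loa, c(0, 0))
  expect_error(bland_altman_percent(c(1, 0), c(1, 1)), "> 0")
})

test_that("Deming regression: study slope, symmetry, and OLS limit", {
  expect_equal(round(deming(inj(), mwi())$slope, 2), 0.89)
  ident <- deming(1:10, 1:10)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)
  set.seed(61)
  x <- rnorm(30); y <- 0.7 * x + rnorm(30, 0, 0.3)
  s_xy <- deming(x, y)$slope
  s_yx <- deming(y, x)$slope
  expect_equal(s_xy * s_yx, 1, tolerance = 1e-10)
  # lambda -> Inf approaches ordinary least squares of y on x
  ols <- unname(stats::coef(stats::lm(y ~ x))[2])
  expect_equal(deming(x, y, lambda_ratio = 1e8)$slope, ols,
               tolerance = 1e-3)
})

test_that("paired tests reproduce the study's t and exact Wilcoxon", {
  pt_ct <- paired_tests(ctv(), mwi())
  expect_equal(round(pt_ct$mean_diff, 1), 25.6)
  expect_equal(round(pt_ct$t, 2), 4.99)
  expect_equal(pt_ct$df, 6)
  pt_inj <- paired_tests(inj(), mwi())
  expect_equal(pt_inj$p_wilcoxon, 2 / 128)
  expect_equal(pt_inj$mean_diff, 9.27, tolerance = 1e-3)
  same <- paired_tests(c(1, 2, 3), c(1, 2, 3) + 1e-14 * c(1, -1, 1))
  expect_lt(abs(same$t), 1)
  expect_error(paired_tests(1:3, 1:3), "all-zero")
})

test_that("exact Wilcoxon enumeration matches reference implementations", {
  set.seed(71)
  for (i in 1:5) {
    d <- rnorm(10)
    ours <- mwivol:::signed_rank_exact_p(d)
    ref <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  # corrected normal approximation tracks the exact tail closely at n = 12
  for (i in 1:5) {
    d <- rnorm(12)
    ours <- mwivol:::signed_rank_exact_p(d)
    approx_p <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(ours - approx_p), 0.02)
  }
})

test_that("MAPE reproduces the study accuracy and scales proportionally", {
  expect_equal(round(mape(inj(), mwi()), 1), 12.4)
  expect_equal(mape(1:5, 1:5), 0)
  expect_equal(mape(c(10, 20), c(11, 22)), 10)
})

test_that("CCC = r x Cb and |CCC| <= |r| on random data", {
  set.seed(81)
  for (i in 1:50) {
    x <- rnorm(15, 10, 3)
    y <- 0.8 * x + rnorm(15, 2, 1)
    cc <- lins_ccc(x, y)
    r <- stats::cor(x, y)
    expect_equal(cc$ccc, r * cc$cb, tolerance = 1e-10)
    expect_lte(abs(cc$ccc), abs(r) + 1e-12)
  }
})

test_that("Bland-Altman limits contain ~95% of large Gaussian samples", {
  set.seed(91)
  ref <- runif(10000, 50, 150)
  est <- ref * (1 + rnorm(10000, 0.05, 0.1))
  ba <- bland_altman_percent(ref, est)
  inside <- mean(ba$d >= ba$loa[1] & ba$d <= ba$loa[2])
  expect_gte(inside, 0.945)
})

test_that("bootstrap CIs are seeded, stable, and match the study's scale", {
  degen <- bootstrap_ci(function(a, b) mean(b - a), rep(1, 7), rep(2, 7),
                        B = 200, seed = 1)
  expect_equal(degen$ci[1], degen$ci[2])
  bias_stat <- function(a, b) mean(100 * (b - a) / a)
  ci1 <- bootstrap_ci(bias_stat, inj(), mwi(), B = 10000, seed = 1)$ci
  ci2 <- bootstrap_ci(bias_stat, inj(), mwi(), B = 10000, seed = 2)$ci
  expect_lt(max(abs(ci1 - ci2)), 0.5)
  # study printed bootstrap bias CI (+4.4, +24.3): stochastic tolerance
  expect_lt(abs(ci1[1] - 4.4), 3)
  expect_lt(abs(ci1[2] - 24.3), 3)
})

test_that("ICC(2,1) behaves across degenerate and constructed designs", {
  perfect <- matrix(rep(c(10, 20, 30), each = 4), nrow = 3, byrow = TRUE)
  expect_equal(icc_2_1(perfect), 1)
  expect_error(icc_2_1(matrix(5, 3, 4)), "undefined")
  set.seed(95)
  rows <- rnorm(7, 90, 15)
  m <- matrix(rows, 7, 4) + matrix(rnorm(28, 0, 2.5), 7, 4)
  expect_gt(icc_2_1(m), 0.97)
})
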