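# Debye reference models, Stuchly forward/inverse, one-port calibration.

test_that("Debye model hits its static, optical and omega*tau = 1 points", {
  liq <- debye_liquid(80, 5, 1 / (2 * pi * 1e9))
  lo <- debye_permittivity(liq, 1e3)
  expect_equal(Re(lo$eps_complex), 80, tolerance = 1e-10)
  hi <- debye_permittivity(liq, 1e15)
  expect_lt(abs(Re(hi$eps_complex) - 5), 0.01)
  at1 <- debye_permittivity(liq, 1e9)$eps_complex
  expect_equal(Re(at1), 42.5, tolerance = 1e-12)
  expect_equal(-Im(at1), 37.5, tolerance = 1e-12)
  expect_error(debye_permittivity(liq, c(1e9, -1)), "frequencies")
})

test_that("forward model is passive and the inversion is its exact inverse", {
  pp <- default_params()
  g_lossless <- forward_gamma(4 + 0i, 2.5e9, pp)
  expect_equal(Mod(g_lossless), 1, tolerance = 1e-12)
  g_lossy <- forward_gamma(4 - 0.5i, 2.5e9, pp)
  expect_lt(Mod(g_lossy), 1)
  expect_lt(Mod(invert_permittivity(g_lossy, 2.5e9, pp) - (4 - 0.5i)), 1e-10)
  g_air <- forward_gamma(1 + 0i, 2.5e9, pp)
  expect_lt(Mod(invert_permittivity(g_air, 2.5e9, pp) - 1), 1e-10)
  expect_error(invert_permittivity(-1 + 0i, 2.5e9, pp), "short")
})

test_that("forward/inverse round trip holds across the physical range", {
  pp <- default_params()
  set.seed(101)
  eps <- complex(real = runif(1000, 1, 80), imaginary = -runif(1000, 0, 40))
  f <- runif(1000, 2.25e9, 3e9)
  back <- invert_permittivity(forward_gamma(eps, f, pp), f, pp)
  expect_lt(max(Mod(back - eps) / Mod(eps)), 1e-9)
})

test_that("error-term solve recovers identity and synthetic terms", {
  pp <- default_params()
  f <- default_sweep_frequencies()
  terms_id <- solve_error_terms(make_standards(pp, f), pp)
  expect_lt(max(Mod(terms_id$e_d)), 1e-10)
  expect_lt(max(Mod(terms_id$e_s)), 1e-10)
  expect_lt(max(Mod(terms_id$e_r - 1)), 1e-10)

  truth <- error_terms(f, 0.1 + 0.05i, 0.9 + 0i, -0.02 + 0i)
  rec <- solve_error_terms(make_standards(pp, f, truth)[1:3], pp)
  expect_lt(max(Mod(rec$e_d - truth$e_d)), 1e-9)
  expect_lt(max(Mod(rec$e_r - truth$e_r)), 1e-9)
  expect_lt(max(Mod(rec$e_s - truth$e_s)), 1e-9)

  # four standards, noisy: least-squares recovery
  set.seed(7)
  noisy <- make_standards(pp, f, truth)
  for (i in seq_along(noisy)) {
    n <- length(f)
    noisy[[i]]$measured$gamma <- noisy[[i]]$measured$gamma +
      complex(real = rnorm(n, 0, 1e-3), imaginary = rnorm(n, 0, 1e-3))
  }
  rec4 <- solve_error_terms(noisy, pp)
  expect_lt(max(Mod(rec4$e_d - truth$e_d)), 1e-2)
  expect_lt(max(Mod(rec4$e_r - truth$e_r)), 1e-2)
  expect_lt(max(Mod(rec4$e_s - truth$e_s)), 1e-2)

  expect_error(solve_error_terms(make_standards(pp, f)[1:2], pp), "3")
  dup <- make_standards(pp, f)
  dup[[2L]] <- dup[[1L]]
  expect_error(solve_error_terms(dup, pp), "degenerate")
})

test_that("de-embedding inverts embedding and handles grid misalignment", {
  f <- default_sweep_frequencies()
  set.seed(11)
  sw <- s11_sweep(f, complex(real = runif(101, -0.5, 0.5),
                             imaginary = runif(101, -0.5, 0.5)), "random")
  expect_equal(de_embed(sw, identity_terms(f))$gamma, sw$gamma,
               tolerance = 1e-14)
  terms <- error_terms(f, 0.1 + 0.05i, 0.9 - 0.1i, -0.02 + 0.01i)
  back <- de_embed(embed_sweep(sw, terms), terms)
  expect_lt(max(Mod(back$gamma - sw$gamma)), 1e-10)
  # terms on a coarser covering grid: linear interpolation, same length out
  coarse <- error_terms(seq(2.2e9, 3.1e9, length.out = 10),
                        0.1 + 0i, 0.9 + 0i, -0.02 + 0i)
  out <- de_embed(sw, coarse)
  expect_length(out$gamma, length(f))
})

test_that("probe capacitances are recoverable from liquid standards", {
  pp <- default_params()
  f <- default_sweep_frequencies()
  liquids <- list(water_22c(), propylene_glycol_22c())
  sweeps <- lapply(liquids, function(lq) {
    eps <- debye_permittivity(lq, f)$eps_complex
    list(sweep = s11_sweep(f, forward_gamma(eps, f, pp), lq$label),
         liquid = lq)
  })
  fit <- fit_probe_params(sweeps)
  expect_lt(abs(fit$c0 - pp$c0) / pp$c0, 1e-3)
  expect_lt(abs(fit$cf - pp$cf) / pp$cf, 1e-3)
  expect_error(fit_probe_params(sweeps[1]), "2")

  set.seed(5)
  noisy <- lapply(sweeps, function(s) {
    s$sweep$gamma <- s$sweep$gamma +
      complex(real = rnorm(101, 0, 1e-3), imaginary = rnorm(101, 0, 1e-3))
    s
  })
  fitn <- fit_probe_params(noisy)
  expect_lt(abs(fitn$c0 - pp$c0) / pp$c0, 0.05)
  expect_lt(abs(fitn$cf - pp$cf) / pp$cf, 0.05)
})

test_that("frequency extraction interpolates linearly within the span", {
  f <- c(2e9, 2.5e9, 3e9)
  spec <- permittivity_spectrum(f, c(10, 20, 30) + 0i)
  expect_equal(extract_at_frequency(spec, 2.5e9), 20 + 0i)
  expect_equal(extract_at_frequency(spec, 2.25e9), 15 + 0i)
  const <- permittivity_spectrum(f, rep(7 - 1i, 3))
  expect_equal(extract_at_frequency(const, 2.83e9), 7 - 1i)
  expect_error(extract_at_frequency(spec, 3.5e9), "span")
})

test_that("calibrated pipeline recovers permittivity at 2.5 GHz within 1%", {
  pp <- default_params()
  f <- default_sweep_frequencies()
  truth <- error_terms(f, 0.08 - 0.03i, 0.95 + 0.05i, -0.04 + 0.02i)
  eps_true <- 1.62
  raw <- embed_sweep(s11_sweep(f, forward_gamma(rep(eps_true + 0i, 101), f, pp),
                               "specimen"), truth)
  terms <- solve_error_terms(make_standards(pp, f, truth), pp)
  cal <- de_embed(raw, terms)
  expect_true(all(Mod(cal$gamma) <= 1 + 1e-6))  # passivity after correction
  spec <- permittivity_spectrum(f, invert_permittivity(cal$gamma, f, pp))
  got <- Re(extract_at_frequency(spec, 2.5e9))
  expect_lt(abs(got - eps_true) / eps_true, 0.01)
})
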