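# One-port probe model: error-term calibration and Stuchly capacitive
# inversion.  Convention used throughout the package: time-harmonic factor
# e^{+j omega t}, lossy relative permittivity written eps = eps' - j eps''
# with eps'' >= 0 for passive media.

EPS0 <- 8.8541878128e-12  # vacuum permittivity, F/m

#' One-port reflection sweep
#'
#' Container for a frequency sweep of complex reflection coefficients
#' (S11) measured at a single probe/position.
#'
#' @param frequencies_hz Strictly ascending numeric vector of frequencies in
#'   Hz, within 1e8--1e11 Hz.
#' @param gamma Complex vector of reflection coefficients, same length.
#' @param label Free-text label (antenna id, calibration-standard name).
#' @return An object of class `s11_sweep`.
#' @export
s11_sweep <- function(frequencies_hz, gamma, label = "") {
  frequencies_hz <- as.numeric(frequencies_hz)
  gamma <- as.complex(gamma)
  if (length(frequencies_hz) < 2L || length(gamma) != length(frequencies_hz))
    stop("frequencies and gamma must be aligned vectors of length >= 2")
  if (is.unsorted(frequencies_hz, strictly = TRUE))
    stop("frequencies must be strictly ascending")
  if (any(frequencies_hz < 1e8) || any(frequencies_hz > 1e11))
    stop("frequencies outside the supported 0.1-100 GHz band")
  if (any(!is.finite(Mod(gamma))))
    stop("non-finite reflection coefficients")
  structure(list(frequencies_hz = frequencies_hz, gamma = gamma,
                 label = as.character(label)),
            class = "s11_sweep")
}

#' @export
print.s11_sweep <- function(x, ...) {
  cat(sprintf("<s11_sweep> %s: %d points, %.4g-%.4g GHz, |Gamma| in [%.3f, %.3f]\n",
              if (nzchar(x$label)) x$label else "(unlabeled)",
              length(x$frequencies_hz),
              min(x$frequencies_hz) / 1e9, max(x$frequencies_hz) / 1e9,
              min(Mod(x$gamma)), max(Mod(x$gamma))))
  invisible(x)
}

#' Complex relative permittivity spectrum
#'
#' @param frequencies_hz Ascending numeric frequencies in Hz.
#' @param eps_complex Complex relative permittivity, convention
#'   `eps' - 1i*eps''` with `eps'' >= 0` for passive media.
#' @param label Free-text label.
#' @return An object of class `permittivity_spectrum`.  Negative real parts
#'   (unphysical for the media considered here) are flagged with a warning,
#'   never silently clipped.
#' @export
permittivity_spectrum <- function(frequencies_hz, eps_complex, label = "") {
  frequencies_hz <- as.numeric(frequencies_hz)
  eps_complex <- as.complex(eps_complex)
  if (length(frequencies_hz) != length(eps_complex))
    stop("frequencies and eps_complex must be aligned")
  if (any(Re(eps_complex) < 0))
    warning("negative real permittivity in spectrum '", label,
            "': flagged, not clipped")
  structure(list(frequencies_hz = frequencies_hz, eps_complex = eps_complex,
                 label = as.character(label)),
            class = "permittivity_spectrum")
}

#' @export
print.permittivity_spectrum <- function(x, ...) {
  cat(sprintf("<permittivity_spectrum> %s: %d points, %.4g-%.4g GHz, eps' in [%.3g, %.3g]\n",
              if (nzchar(x$label)) x$label else "(unlabeled)",
              length(x$frequencies_hz),
              min(x$frequencies_hz) / 1e9, max(x$frequencies_hz) / 1e9,
              min(Re(x$eps_complex)), max(Re(x$eps_complex))))
  invisible(x)
}

#' Stuchly probe parameters
#'
#' Parameters of the capacitive aperture model `Y = j w (C0 eps + Cf)` for an
#' open-ended coaxial probe: `c0` is the aperture capacitance that scales with
#' the sample permittivity, `cf` the fringe capacitance internal to the probe,
#' `z0` the reference impedance.
#'
#' @param c0 Aperture capacitance in farad, > 0.
#' @param cf Fringe capacitance in farad, >= 0.
#' @param z0 Reference impedance in ohm (default 50).
#' @return An object of class `probe_params`.
#' @export
probe_params <- function(c0, cf, z0 = 50) {
  if (!is.numeric(c0) || c0 <= 0) stop("c0 must be > 0")
  if (!is.numeric(cf) || cf < 0) stop("cf must be >= 0")
  if (!is.numeric(z0) || z0 <= 0) stop("z0 must be > 0")
  structure(list(c0 = c0, cf = cf, z0 = z0), class = "probe_params")
}

#' @export
print.probe_params <- function(x, ...) {
  cat(sprintf("<probe_params> C0 = %.4g fF, Cf = %.4g fF, Z0 = %g ohm\n",
              x$c0 * 1e15, x$cf * 1e15, x$z0))
  invisible(x)
}

#' Single-relaxation Debye liquid
#'
#' Reference model for the polar calibration liquids (deionized water,
#' propylene glycol).  Defaults for the two standards at 22 degC are provided
#' by [water_22c()] and [propylene_glycol_22c()].
#'
#' @param eps_static Static relative permittivity (>= eps_inf).
#' @param eps_inf High-frequency relative permittivity (>= 1).
#' @param tau_s Relaxation time in seconds, > 0.
#' @param sigma_dc DC conductivity in S/m, >= 0.
#' @param temperature_c Temperature in degC (metadata only).
#' @param label Free-text name.
#' @return An object of class `debye_liquid`.
#' @export
debye_liquid <- function(eps_static, eps_inf, tau_s, sigma_dc = 0,
                         temperature_c = NA_real_, label = "") {
  if (!(eps_static >= eps_inf && eps_inf >= 1))
    stop("require eps_static >= eps_inf >= 1")
  if (tau_s <= 0) stop("tau_s must be > 0")
  if (sigma_dc < 0) stop("sigma_dc must be >= 0")
  structure(list(eps_static = eps_static, eps_inf = eps_inf, tau_s = tau_s,
                 sigma_dc = sigma_dc, temperature_c = temperature_c,
                 label = as.character(label)),
            class = "debye_liquid")
}

#' @rdname debye_liquid
#' @export
water_22c <- function() {
  debye_liquid(79.2, 5.2, 9.36e-12, 0, 22, "deionized water 22C")
}

#' @rdname debye_liquid
#' @export
propylene_glycol_22c <- function() {
  debye_liquid(19.0, 3.0, 320e-12, 0, 22, "propylene glycol 22C")
}

#' Evaluate a Debye liquid's permittivity spectrum
#'
#' `eps(f) = eps_inf + (eps_s - eps_inf)/(1 + j w tau) - j sigma_dc/(w eps0)`
#' with `w = 2 pi f`, under the `eps' - j eps''` sign convention.
#'
#' @param liquid A [debye_liquid()].
#' @param frequencies_hz Positive numeric frequencies in Hz.
#' @return A [permittivity_spectrum()].
#' @export
debye_permittivity <- function(liquid, frequencies_hz) {
  stopifnot(inherits(liquid, "debye_liquid"))
  if (any(frequencies_hz <= 0)) stop("frequencies must be > 0")
  w <- 2 * pi * frequencies_hz
  eps <- liquid$eps_inf +
    (liquid$eps_static - liquid$eps_inf) / (1 + 1i * w * liquid$tau_s) -
    1i * liquid$sigma_dc / (w * EPS0)
  permittivity_spectrum(frequencies_hz, eps, liquid$label)
}

#' Forward Stuchly model: permittivity to reflection coefficient
#'
#' `Y = j w (C0 eps + Cf)`; `Gamma = (1 - Y Z0)/(1 + Y Z0)`.  Vectorized over
#' `eps` and `f_hz`.
#'
#' @param eps Complex relative permittivity (convention `eps' - j eps''`).
#' @param f_hz Frequency in Hz, > 0.
#' @param params A [probe_params()].
#' @return Complex reflection coefficient(s).
#' @export
forward_gamma <- function(eps, f_hz, params) {
  stopifnot(inherits(params, "probe_params"))
  if (any(f_hz <= 0)) stop("frequency must be > 0")
  y <- 1i * 2 * pi * f_hz * (params$c0 * as.complex(eps) + params$cf)
  (1 - y * params$z0) / (1 + y * params$z0)
}

#' Invert the Stuchly model: reflection coefficient to permittivity
#'
#' Exact algebraic inverse of [forward_gamma()]:
#' `eps = (1 - Gamma)/(j w Z0 C0 (1 + Gamma)) - Cf/C0`.
#'
#' @param gamma Complex reflection coefficient(s); must not equal -1 (a short
#'   is outside the capacitive model's domain).
#' @param f_hz Frequency in Hz, > 0.
#' @param params A [probe_params()].
#' @return Complex relative permittivity.
#' @export
invert_permittivity <- function(gamma, f_hz, params) {
  stopifnot(inherits(params, "probe_params"))
  if (any(f_hz <= 0)) stop("frequency must be > 0")
  gamma <- as.complex(gamma)
  if (any(Mod(gamma + 1) < 1e-12))
    stop("Gamma = -1 (short): singular for the capacitive probe model")
  w <- 2 * pi * f_hz
  (1 - gamma) / (1i * w * params$z0 * params$c0 * (1 + gamma)) -
    params$cf / params$c0
}

#' One-port error terms
#'
#' Directivity `e_d`, reflection tracking `e_r` and source match `e_s` per
#' frequency, relating actual to measured reflection by
#' `Gamma_m = e_d + e_r Gamma_a / (1 - e_s Gamma_a)`.
#'
#' @param frequencies_hz Ascending numeric frequencies in Hz.
#' @param e_d,e_r,e_s Complex vectors aligned with `frequencies_hz`.
#' @return An object of class `error_terms`.
#' @export
error_terms <- function(frequencies_hz, e_d, e_r, e_s) {
  n <- length(frequencies_hz)
  e_d <- as.complex(e_d); e_r <- as.complex(e_r); e_s <- as.complex(e_s)
  if (length(e_d) == 1L) e_d <- rep(e_d, n)
  if (length(e_r) == 1L) e_r <- rep(e_r, n)
  if (length(e_s) == 1L) e_s <- rep(e_s, n)
  if (length(e_d) != n || length(e_r) != n || length(e_s) != n)
    stop("error-term vectors must align with frequencies")
  if (any(Mod(e_r) == 0)) stop("|e_r| must be > 0 at every frequency")
  structure(list(frequencies_hz = as.numeric(frequencies_hz),
                 e_d = e_d, e_r = e_r, e_s = e_s),
            class = "error_terms")
}

#' @export
print.error_terms <- function(x, ...) {
  cat(sprintf("<error_terms> %d frequencies, mean |e_d| = %.3g, |e_r| = %.3g, |e_s| = %.3g\n",
              length(x$frequencies_hz), mean(Mod(x$e_d)), mean(Mod(x$e_r)),
              mean(Mod(x$e_s))))
  invisible(x)
}

#' Apply the one-port error model (embed a sweep)
#'
#' Forward counterpart of [de_embed()], used by the simulator and in
#' round-trip checks.
#'
#' @param sweep An [s11_sweep()] of actual reflection coefficients.
#' @param terms An [error_terms()] on the same (or covering) frequency grid.
#' @return An [s11_sweep()] of measured (embedded) coefficients.
#' @export
embed_sweep <- function(sweep, terms) {
  stopifnot(inherits(sweep, "s11_sweep"), inherits(terms, "error_terms"))
  tt <- align_terms(terms, sweep$frequencies_hz)
  gm <- tt$e_d + tt$e_r * sweep$gamma / (1 - tt$e_s * sweep$gamma)
  s11_sweep(sweep$frequencies_hz, gm, sweep$label)
}

# Interpolate error terms onto a target frequency grid (linear, per real and
# imaginary part); exact pass-through when grids already coincide.
align_terms <- function(terms, frequencies_hz) {
  if (length(terms$frequencies_hz) == length(frequencies_hz) &&
      all(terms$frequencies_hz == frequencies_hz))
    return(terms)
  if (min(frequencies_hz) < min(terms$frequencies_hz) - 1e-6 ||
      max(frequencies_hz) > max(terms$frequencies_hz) + 1e-6)
    stop("sweep frequencies outside the span of the error terms")
  interp_c <- function(z) {
    complex(real = stats::approx(terms$frequencies_hz, Re(z), frequencies_hz)$y,
            imaginary = stats::approx(terms$frequencies_hz, Im(z), frequencies_hz)$y)
  }
  list(frequencies_hz = frequencies_hz,
       e_d = interp_c(terms$e_d), e_r = interp_c(terms$e_r),
       e_s = interp_c(terms$e_s))
}

#' Solve one-port error terms from calibration standards
#'
#' Per frequency, finds `(e_d, e_r, e_s)` fitting
#' `Gamma_m = e_d + e_r Gamma_a / (1 - e_s Gamma_a)` across the standards.
#' The bilinear model is rearranged to a form linear in `(e_d, b, e_s)` with
#' `b = e_r - e_d e_s`:
#' `Gamma_m = e_d + b Gamma_a + e_s (Gamma_a Gamma_m)`,
#' solved exactly for three standards and by complex linear least squares for
#' four or more.  The usual standards are open (air, via the Stuchly forward
#' model), short (`Gamma_a = -1`), and two Debye reference liquids.
#'
#' @param standards List with one entry per standard; each entry is a list
#'   with elements `measured` (an [s11_sweep()]) and `actual` (either a
#'   [permittivity_spectrum()] or the string `"short"` meaning
#'   `Gamma_a = -1` at every frequency).
#' @param params [probe_params()] used to map actual permittivities to actual
#'   reflection coefficients.
#' @return An [error_terms()] on the standards' common frequency grid.
#' @export
solve_error_terms <- function(standards, params) {
  if (length(standards) < 3L)
    stop("at least 3 calibration standards are required")
  f <- standards[[1L]]$measured$frequencies_hz
  for (s in standards) {
    if (!inherits(s$measured, "s11_sweep"))
      stop("each standard needs a 'measured' s11_sweep")
    if (length(s$measured$frequencies_hz) != length(f) ||
        any(s$measured$frequencies_hz != f))
      stop("all standards must share one frequency grid")
  }
  gact <- vapply(standards, function(s) {
    if (identical(s$actual, "short")) return(rep(-1 + 0i, length(f)))
    stopifnot(inherits(s$actual, "permittivity_spectrum"))
    forward_gamma(s$actual$eps_complex, f, params)
  }, complex(length(f)))
  gact <- matrix(gact, nrow = length(f))
  gmeas <- vapply(standards, function(s) s$measured$gamma, complex(length(f)))
  gmeas <- matrix(gmeas, nrow = length(f))

  n <- length(f)
  e_d <- e_r <- e_s <- complex(n)
  for (k in seq_len(n)) {
    ga <- gact[k, ]; gm <- gmeas[k, ]
    if (min(Mod(outer(ga, ga, `-`))[lower.tri(diag(length(ga)))]) < 1e-9)
      stop("degenerate standards: two standards share the same actual Gamma")
    a <- cbind(1 + 0i, ga, ga * gm)
    sol <- qr.solve(Conj(t(a)) %*% a, Conj(t(a)) %*% gm)
    e_d[k] <- sol[1L]
    e_s[k] <- sol[3L]
    e_r[k] <- sol[2L] + sol[1L] * sol[3L]
  }
  error_terms(f, e_d, e_r, e_s)
}

#' De-embed a measured sweep through known error terms
#'
#' `Gamma_a = (Gamma_m - e_d) / (e_s (Gamma_m - e_d) + e_r)`; error terms on a
#' different grid are linearly interpolated onto the sweep's grid.
#'
#' @param sweep Measured [s11_sweep()].
#' @param terms [error_terms()].
#' @return Corrected [s11_sweep()].
#' @export
de_embed <- function(sweep, terms) {
  stopifnot(inherits(sweep, "s11_sweep"), inherits(terms, "error_terms"))
  tt <- align_terms(terms, sweep$frequencies_hz)
  num <- sweep$gamma - tt$e_d
  den <- tt$e_s * num + tt$e_r
  bad <- which(Mod(den) < 1e-12)
  if (length(bad))
    stop(sprintf("de-embedding singular at %.6g Hz",
                 sweep$frequencies_hz[bad[1L]]))
  s11_sweep(sweep$frequencies_hz, num / den, sweep$label)
}

#' Fit probe capacitances from de-embedded liquid standards
#'
#' Estimates `(C0, Cf)` from at least two reference-liquid sweeps: a linear
#' admittance-domain solve (`Y/(j w) = C0 eps + Cf` stacked over frequencies
#' and liquids) provides the starting point, refined by minimizing the
#' reflection-domain residual `sum |Gamma_model - Gamma_meas|^2`.
#'
#' @param liquid_sweeps List with one entry per liquid: a list with elements
#'   `sweep` (de-embedded [s11_sweep()]) and `liquid` (a [debye_liquid()]).
#' @param z0 Reference impedance in ohm.
#' @return A [probe_params()].
#' @export
fit_probe_params <- function(liquid_sweeps, z0 = 50) {
  if (length(liquid_sweeps) < 2L)
    stop("at least 2 distinct reference liquids are required (under-determined otherwise)")
  eps_all <- c(); y_all <- c(); f_all <- c(); g_all <- c()
  for (ls in liquid_sweeps) {
    stopifnot(inherits(ls$sweep, "s11_sweep"), inherits(ls$liquid, "debye_liquid"))
    f <- ls$sweep$frequencies_hz
    eps <- debye_permittivity(ls$liquid, f)$eps_complex
    y <- (1 - ls$sweep$gamma) / (z0 * (1 + ls$sweep$gamma))
    eps_all <- c(eps_all, eps)
    y_all <- c(y_all, y / (1i * 2 * pi * f))
    f_all <- c(f_all, f)
    g_all <- c(g_all, ls$sweep$gamma)
  }
  eps_stat <- vapply(liquid_sweeps, function(ls) ls$liquid$eps_static, 0)
  if (max(eps_stat) - min(eps_stat) < 1e-6)
    stop("liquids must have distinct permittivities")
  # linear solve in (C0, Cf): stack real/imaginary parts
  a <- rbind(cbind(Re(eps_all), 1), cbind(Im(eps_all), 0))
  b <- c(Re(y_all), Im(y_all))
  start <- qr.solve(a, b)
  obj <- function(p) {
    pp <- probe_params(p[1L], max(p[2L], 0), z0)
    sum(Mod(forward_gamma(eps_all, f_all, pp) - g_all)^2)
  }
  fit <- stats::optim(pmax(start, 1e-18), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (fit$convergence != 0)
    stop("probe-parameter fit did not converge (start C0 = ", start[1L],
         ", Cf = ", start[2L], "; optim code ", fit$convergence, ")")
  probe_params(fit$par[1L], max(fit$par[2L], 0), z0)
}

#' Extract permittivity at a target frequency
#'
#' Linear interpolation between the bracketing sweep samples; exact when the
#' target sits on the grid.  The working value for the whole pipeline is the
#' extraction at 2.5 GHz.
#'
#' @param spec A [permittivity_spectrum()].
#' @param f_target_hz Target frequency, within the sweep span.
#' @return A single complex permittivity.
#' @export
extract_at_frequency <- function(spec, f_target_hz) {
  stopifnot(inherits(spec, "permittivity_spectrum"))
  f <- spec$frequencies_hz
  if (f_target_hz < min(f) || f_target_hz > max(f))
    stop("target frequency outside the sweep span")
  complex(real = stats::approx(f, Re(spec$eps_complex), f_target_hz)$y,
          imaginary = stats::approx(f, Im(spec$eps_complex), f_target_hz)$y)
}

#' Default acquisition sweep grid
#'
#' 101 points spanning 2.25--3.00 GHz.
#' @return Numeric vector of frequencies in Hz.
#' @export
default_sweep_frequencies <- function() seq(2.25e9, 3.00e9, length.out = 101L)
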