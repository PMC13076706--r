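# Probe sensing-footprint characterization: radial kernel inversion from the
# center-to-edge cylinder experiment, sigmoidal fit of the side-to-side
# lateral scan, and exponential depth decay from the visibility-thickness
# curve.

#' Cumulative response curve from a characterization experiment
#'
#' @param sizes_mm Ascending sizes: cylinder diameters (center-to-edge) or
#'   lateral offsets (side-to-side), in mm.
#' @param response Normalized response in `[0, 1]`, same length.
#' @param type `"center_to_edge"` or `"side_to_side"`.
#' @return An object of class `response_curve`.
#' @export
response_curve <- function(sizes_mm, response,
                           type = c("center_to_edge", "side_to_side")) {
  type <- match.arg(type)
  sizes_mm <- as.numeric(sizes_mm); response <- as.numeric(response)
  if (length(sizes_mm) != length(response))
    stop("sizes and response must align")
  if (is.unsorted(sizes_mm, strictly = TRUE))
    stop("sizes must be strictly ascending")
  structure(list(sizes_mm = sizes_mm, response = response, type = type),
            class = "response_curve")
}

#' Radial sensitivity kernel
#'
#' Annular per-area sensitivity density recovered from a cumulative
#' center-to-edge curve, normalized to unit mass over the disc of maximum
#' radius, together with the equivalent lateral radius `r_eq`.
#'
#' @param radii_mm Ascending annulus outer radii starting after 0.
#' @param density Non-negative per-area densities, one per annulus.
#' @param r_eq_mm Equivalent lateral radius (cumulative-quantile radius).
#' @return An object of class `radial_kernel`.
#' @export
radial_kernel <- function(radii_mm, density, r_eq_mm) {
  radii_mm <- as.numeric(radii_mm); density <- as.numeric(density)
  if (length(radii_mm) != length(density)) stop("radii and density must align")
  if (any(density < 0)) stop("density must be >= 0")
  mass <- sum(density * pi * diff(c(0, radii_mm)^2))
  if (abs(mass - 1) > 1e-6)
    stop(sprintf("kernel mass %.8f != 1", mass))
  if (r_eq_mm < 0 || r_eq_mm > max(radii_mm))
    stop("r_eq outside the kernel support")
  structure(list(radii_mm = radii_mm, density = density, r_eq_mm = r_eq_mm),
            class = "radial_kernel")
}

#' @export
print.radial_kernel <- function(x, ...) {
  cat(sprintf("<radial_kernel> %d annuli to %.3g mm, r_eq = %.3g mm\n",
              length(x$radii_mm), max(x$radii_mm), x$r_eq_mm))
  invisible(x)
}

#' Evaluate a radial kernel's density at arbitrary radii
#'
#' Piecewise-constant per annulus, zero beyond the support.
#'
#' @param kernel A [radial_kernel()].
#' @param r_mm Radii in mm (vectorized).
#' @return Numeric densities.
#' @export
kernel_density_at <- function(kernel, r_mm) {
  idx <- findInterval(r_mm, c(0, kernel$radii_mm), left.open = TRUE,
                      rightmost.closed = TRUE)
  idx[r_mm == 0] <- 1L
  out <- numeric(length(r_mm))
  inside <- idx >= 1L & idx <= length(kernel$density) & r_mm <= max(kernel$radii_mm)
  out[inside] <- kernel$density[idx[inside]]
  out
}

#' Invert a center-to-edge cumulative curve to a radial kernel
#'
#' The cumulative response `R(D)` to centered cylinders of diameter `D` is the
#' integral of the radial sensitivity density over the disc of radius `D/2`,
#' so annulus densities follow as
#' `s_k = (R_k - R_(k-1)) / (pi (r_k^2 - r_(k-1)^2))` with `r_k = D_k/2` and
#' `R_0 = 0` at `r_0 = 0`.  Noisy curves are first cleaned by isotonic
#' regression (an error is raised if the cleanup moves any point by more than
#' `monotone_tol`); negative annuli are floored at zero and the kernel
#' renormalized to unit mass.  `r_eq` is the smallest radius at which the
#' (renormalized) cumulative reaches `quantile`, linearly interpolated.
#'
#' @param curve A center-to-edge [response_curve()] with >= 3 points and a
#'   positive first diameter.
#' @param quantile Cumulative-mass quantile defining `r_eq` (default 0.9).
#' @param monotone_tol Maximum tolerated isotonic adjustment (default 0.05).
#' @return A [radial_kernel()].
#' @export
invert_radial_kernel <- function(curve, quantile = 0.9, monotone_tol = 0.05) {
  stopifnot(inherits(curve, "response_curve"))
  if (curve$type != "center_to_edge")
    stop("kernel inversion requires a center-to-edge curve")
  if (length(curve$sizes_mm) < 3L) stop("need >= 3 points")
  if (curve$sizes_mm[1L] <= 0) stop("first diameter must be > 0")
  iso <- stats::isoreg(curve$sizes_mm, curve$response)$yf
  if (max(abs(iso - curve$response)) > monotone_tol)
    stop("center-to-edge curve non-monotone beyond tolerance ", monotone_tol)
  r <- curve$sizes_mm / 2
  cum <- c(0, iso)
  dens <- pmax(diff(cum), 0) / (pi * diff(c(0, r)^2))
  mass <- sum(dens * pi * diff(c(0, r)^2))
  if (mass <= 0) stop("degenerate curve: zero total response")
  dens <- dens / mass
  cum_n <- cumsum(dens * pi * diff(c(0, r)^2))
  r_eq <- stats::approx(c(0, cum_n), c(0, r), xout = quantile, ties = "ordered")$y
  radial_kernel(r, dens, r_eq)
}

#' Logistic (sigmoidal) fit of a response curve
#'
#' Least-squares fit of `lo + (hi - lo) / (1 + exp(-(x - x0)/s))`, the
#' nonlinear interpolation family used for the lateral sensitivity profile.
#'
#' @param curve A [response_curve()] with >= 4 points.
#' @return An object of class `sigmoid_fit` with fields `midpoint_mm`,
#'   `scale_mm`, `lo`, `hi`, `rmse`.
#' @export
fit_sigmoid <- function(curve) {
  stopifnot(inherits(curve, "response_curve"))
  x <- curve$sizes_mm; y <- curve$response
  if (length(x) < 4L) stop("need >= 4 points for a sigmoid fit")
  if (diff(range(y)) < 1e-9)
    stop("constant curve: sigmoid scale unidentifiable")
  lo0 <- min(y); hi0 <- max(y)
  x0 <- stats::approx(y + seq_along(y) * 1e-12, x,
                      xout = (lo0 + hi0) / 2, rule = 2, ties = "ordered")$y
  s0 <- diff(range(x)) / 6
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ lo + (hi - lo) / (1 + exp(-(x - x0) / s)),
                      start = list(lo = lo0, hi = hi0, x0 = x0, s = s0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("sigmoid fit failed (starts lo=", signif(lo0, 3),
                             " hi=", signif(hi0, 3), " x0=", signif(x0, 3),
                             " s=", signif(s0, 3), "): ", conditionMessage(e)))
  p <- stats::coef(fit)
  if (p[["hi"]] <= p[["lo"]]) {  # canonicalize a descending fit
    p[c("lo", "hi")] <- p[c("hi", "lo")]
    p[["s"]] <- -p[["s"]]
  }
  if (p[["s"]] <= 0) stop("sigmoid fit returned non-positive scale")
  structure(list(midpoint_mm = unname(p[["x0"]]), scale_mm = unname(p[["s"]]),
                 lo = unname(p[["lo"]]), hi = unname(p[["hi"]]),
                 rmse = sqrt(mean(stats::resid(fit)^2))),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> midpoint %.3g mm, scale %.3g mm, range [%.3g, %.3g], rmse %.3g\n",
              x$midpoint_mm, x$scale_mm, x$lo, x$hi, x$rmse))
  invisible(x)
}

#' Lateral weight derived from a side-to-side sigmoid fit
#'
#' The side-to-side cumulative response is the integral of the lateral
#' sensitivity profile, so the profile itself is the derivative of the fitted
#' logistic: `w(d) = sech^2(d / (2 s))`, centered and normalized to peak 1.
#'
#' @param fit A [sigmoid_fit()].
#' @param d_mm Lateral distances in mm (vectorized).
#' @return Weights in `(0, 1]`.
#' @export
lateral_weight_at <- function(fit, d_mm) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  1 / cosh(d_mm / (2 * fit$scale_mm))^2
}

#' Exponential depth-sensitivity profile
#'
#' Depth weight `w(z) = exp(-z / delta)` with `w(0) = 1`; `delta` is the
#' decay constant in mm.
#'
#' @param delta_mm Positive decay constant in mm.
#' @return An object of class `depth_profile`.
#' @export
depth_profile <- function(delta_mm) {
  if (!is.numeric(delta_mm) || delta_mm <= 0) stop("delta_mm must be > 0")
  structure(list(delta_mm = delta_mm), class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> delta = %.4g mm (d_eff(8 mm) = %.4g mm, rho = %.5g)\n",
              x$delta_mm, effective_depth(x, 8), effective_depth(x, 8) / 8))
  invisible(x)
}

#' Fit the depth-decay constant from a visibility-thickness curve
#'
#' Least-squares fit of `V(t) = 1 - exp(-t / delta)` to measured visibilities.
#'
#' @param thickness_mm Target thicknesses in mm (>= 3 points).
#' @param visibility Visibilities in `[0, 1]`.
#' @return A [depth_profile()].
#' @export
fit_depth_profile <- function(thickness_mm, visibility) {
  if (length(thickness_mm) < 3L || length(visibility) != length(thickness_mm))
    stop("need >= 3 aligned (thickness, visibility) points")
  if (any(visibility < 0 | visibility > 1))
    stop("visibility must lie in [0, 1]")
  if (diff(range(visibility)) < 1e-12)
    stop("all-equal visibility: decay constant unidentifiable")
  mid <- which.min(abs(visibility - 0.6))
  d0 <- if (visibility[mid] < 1 && visibility[mid] > 0)
    -thickness_mm[mid] / log(1 - visibility[mid]) else mean(thickness_mm)
  t <- thickness_mm; v <- visibility
  fit <- minpack.lm::nlsLM(v ~ 1 - exp(-t / delta),
                           start = list(delta = max(d0, 1e-3)),
                           lower = 1e-6,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  depth_profile(unname(stats::coef(fit)[["delta"]]))
}

#' Effective sensing depth of a finite slab
#'
#' `d_eff = delta (1 - exp(-H / delta))`: the integral of the depth weight
#' over a slab of thickness `H`.  Tends to `H` for shallow slabs and
#' saturates at `delta` for deep ones.
#'
#' @param profile A [depth_profile()].
#' @param hole_depth_mm Slab (hole) depth `H` in mm, > 0.
#' @return Effective depth in mm.
#' @export
effective_depth <- function(profile, hole_depth_mm) {
  stopifnot(inherits(profile, "depth_profile"))
  if (any(hole_depth_mm <= 0)) stop("hole depth must be > 0")
  profile$delta_mm * (1 - exp(-hole_depth_mm / profile$delta_mm))
}

#' Depth-rescale factor rho = d_eff(H) / H
#'
#' @inheritParams effective_depth
#' @return Factor in `(0, 1)`, monotonically decreasing in `H`.
#' @export
depth_factor <- function(profile, hole_depth_mm) {
  effective_depth(profile, hole_depth_mm) / hole_depth_mm
}

#' Default depth profile calibrated to the 8-mm hole study
#'
#' The decay constant solves `delta (1 - exp(-8/delta)) = 1.35` mm, i.e. a
#' depth-rescale factor `rho(8 mm) = 0.16875` for the standard 8-mm holes.
#'
#' @return A [depth_profile()].
#' @export
default_depth_profile <- function() {
  delta <- stats::uniroot(function(d) d * (1 - exp(-8 / d)) - 1.35,
                          c(0.5, 3), tol = 1e-12)$root
  depth_profile(delta)
}

#' Idealized Gaussian radial kernel
#'
#' Convenience generator for simulation and testing: a Gaussian radial
#' density discretized on annuli and normalized, with `r_eq` at the requested
#' quantile.  Mirrors what [invert_radial_kernel()] recovers from a
#' Gaussian-footprint probe.
#'
#' @param sigma_mm Gaussian scale in mm.
#' @param max_radius_mm Support radius (default `3 sigma`).
#' @param n_annuli Number of annuli.
#' @param quantile Quantile defining `r_eq`.
#' @return A [radial_kernel()].
#' @export
gaussian_kernel <- function(sigma_mm, max_radius_mm = 3 * sigma_mm,
                            n_annuli = 24L, quantile = 0.9) {
  r <- seq(0, max_radius_mm, length.out = n_annuli + 1L)[-1L]
  mid <- r - diff(c(0, r)) / 2
  dens <- exp(-mid^2 / (2 * sigma_mm^2))
  mass <- sum(dens * pi * diff(c(0, r)^2))
  dens <- dens / mass
  cum <- cumsum(dens * pi * diff(c(0, r)^2))
  r_eq <- stats::approx(c(0, cum), c(0, r), xout = quantile, ties = "ordered")$y
  radial_kernel(r, dens, r_eq)
}
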