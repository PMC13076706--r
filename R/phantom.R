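# Synthetic specimen phantoms and the forward measurement chain: smooth
# baseline permittivity fields with drilled hole matrices, kernel- and
# depth-weighted coarse grid simulation with per-antenna gain variation,
# optional raw-S11 synthesis with embedded error terms, and synthetic CT
# volumes with the empty/filled Hounsfield-unit group statistics.

#' Hole-matrix layout on a 4-mm lattice
#'
#' Standard layouts: 16 holes as 4x4, 20 as 4x5, 25 as 5x5, centered at
#' `center_mm`.
#'
#' @param n_holes One of 16, 20, 25 (other counts: squarest grid that fits).
#' @param pitch_mm Lattice pitch (default 4).
#' @param center_mm `(x, y)` of the layout center.
#' @return Data frame with `x_mm`, `y_mm`.
#' @export
hole_layout <- function(n_holes, pitch_mm = 4, center_mm = c(30, 30)) {
  if (n_holes == 0L)
    return(data.frame(x_mm = numeric(0), y_mm = numeric(0)))
  dims <- switch(as.character(n_holes),
                 "16" = c(4L, 4L), "20" = c(4L, 5L), "25" = c(5L, 5L), {
                   nr <- floor(sqrt(n_holes))
                   c(nr, ceiling(n_holes / nr))
                 })
  g <- expand.grid(row = seq_len(dims[1L]), col = seq_len(dims[2L]))
  g <- g[seq_len(n_holes), , drop = FALSE]
  data.frame(
    x_mm = center_mm[1L] + (g$col - (dims[2L] + 1) / 2) * pitch_mm,
    y_mm = center_mm[2L] + (g$row - (dims[1L] + 1) / 2) * pitch_mm)
}

#' Synthetic specimen phantom
#'
#' Ground-truth object: a smooth baseline permittivity field (Gaussian random
#' field with configurable correlation length) over the specimen extent, plus
#' a drilled hole matrix with per-hole fill fractions.
#'
#' @param n_holes Number of holes (16/20/25 in the standard layouts).
#' @param baseline_mean,baseline_sd Target mean and SD of the baseline
#'   permittivity field (the study's specimens span roughly 1.13-1.79).
#' @param eps_fluid Real permittivity of the injected gel at the working
#'   frequency (default 62).
#' @param fill_fraction Scalar or per-hole vector in `[0, 1]`.
#' @param extent_mm Specimen extent (field spans `-margin .. extent - margin`
#'   so the 16x16 grid at 0..60 mm sits inside; default 70).
#' @param corr_length_mm Correlation length of the baseline field (default 8).
#' @param field_res_mm Resolution of the stored field (default 1).
#' @param hole_depth_mm Hole depth (default 8).
#' @param specimen Specimen id.
#' @param seed Integer seed (mandatory: phantoms are deterministic given it).
#' @return An object of class `specimen_phantom`.
#' @export
make_phantom <- function(n_holes = 16L, baseline_mean = 1.5,
                         baseline_sd = 0.15, eps_fluid = 62,
                         fill_fraction = 1, extent_mm = 70,
                         corr_length_mm = 8, field_res_mm = 1,
                         hole_depth_mm = 8, specimen = "", seed) {
  if (missing(seed)) stop("a seed is mandatory")
  layout <- hole_layout(n_holes)
  margin <- (extent_mm - 60) / 2
  if (any(layout$x_mm < -margin | layout$x_mm > 60 + margin |
          layout$y_mm < -margin | layout$y_mm > 60 + margin))
    stop("hole layout does not fit the specimen extent")
  fill <- rep_len(fill_fraction, n_holes)
  if (any(fill < 0 | fill > 1)) stop("fill fractions must lie in [0, 1]")
  set.seed(seed)
  ax <- seq(-margin, extent_mm - margin, by = field_res_mm)
  n <- length(ax)
  # separable Gaussian smoothing of white noise, then moment matching
  z <- matrix(stats::rnorm(n * n), n, n)
  s <- corr_length_mm / field_res_mm / sqrt(2)
  k <- stats::dnorm(seq(-ceiling(3 * s), ceiling(3 * s)), sd = s)
  sm <- apply(apply(z, 2L, smooth_1d, k = k), 1L, smooth_1d, k = k)
  sm <- (sm - mean(sm)) / stats::sd(sm)
  field <- pmax(baseline_mean + baseline_sd * sm, 1.02)
  holes <- data.frame(x_mm = layout$x_mm, y_mm = layout$y_mm,
                      diameter_mm = rep(2, n_holes),
                      depth_mm = rep(hole_depth_mm, n_holes),
                      fill_fraction = fill)
  structure(list(field = field, axis_mm = ax, field_res_mm = field_res_mm,
                 holes = holes, eps_fluid = eps_fluid,
                 extent_mm = extent_mm, specimen = specimen, seed = seed),
            class = "specimen_phantom")
}

# Reflect-padded 1-D convolution used by the field generator.
smooth_1d <- function(v, k) {
  h <- (length(k) - 1L) / 2L
  pad <- c(rev(v[seq_len(h)]), v, rev(v[length(v) - seq_len(h) + 1L]))
  stats::convolve(pad, k, type = "filter") / sum(k)
}

#' @export
print.specimen_phantom <- function(x, ...) {
  cat(sprintf("<specimen_phantom> %s: %d holes, baseline %.3f +/- %.3f, eps_fluid %.3g\n",
              if (nzchar(x$specimen)) x$specimen else "?", nrow(x$holes),
              mean(x$field), stats::sd(x$field), x$eps_fluid))
  invisible(x)
}

#' True injected volume of a phantom
#'
#' `sum(pi (d/2)^2 depth fill)` in uL; `scaled = TRUE` applies the depth
#' factor `rho(H)` so the value is comparable with probe-frame estimates.
#'
#' @param phantom A [specimen_phantom()].
#' @param profile [depth_profile()] used when `scaled = TRUE`.
#' @param scaled Return the depth-rescaled volume?
#' @return Volume in uL.
#' @export
phantom_true_volume <- function(phantom, profile = default_depth_profile(),
                                scaled = FALSE) {
  h <- phantom$holes
  v <- sum(pi * (h$diameter_mm / 2)^2 * h$depth_mm * h$fill_fraction)
  if (scaled) v <- depth_rescale(v, profile, h$depth_mm[1L])
  v
}

# Area of the intersection of two discs: radius a at the origin, radius b
# centered at distance d (standard lens formula).
lens_area <- function(a, b, d) {
  if (d >= a + b) return(0)
  if (d <= abs(a - b)) return(pi * min(a, b)^2)
  a2 <- a^2; b2 <- b^2
  x <- (d^2 + a2 - b2) / (2 * d)
  a2 * acos(pmin(pmax(x / a, -1), 1)) +
    b2 * acos(pmin(pmax((d - x) / b, -1), 1)) -
    d * sqrt(pmax(a2 - x^2, 0))
}

# Exact integral of a piecewise-constant radial kernel over a disc of radius
# `hole_r` centered `d` away from the kernel origin.
kernel_disc_weight <- function(kernel, d, hole_r) {
  edges <- c(0, kernel$radii_mm)
  areas <- vapply(edges, lens_area, 0, b = hole_r, d = d)
  sum(kernel$density * diff(areas))
}

# Exponential depth weights of the three column layers seen from the flat
# face: fluid on top (injected from the face), air below it to the hole
# bottom, background bone beneath.
column_layer_weights <- function(fill, depth_mm, delta_mm) {
  wf <- 1 - exp(-fill * depth_mm / delta_mm)
  wb <- exp(-depth_mm / delta_mm)
  list(fluid = wf, air = 1 - wf - wb, bone = wb)
}

# Ideal (noise- and gain-free) common-frame 16x16 reading matrix.  Each cell
# reads the composite-weight kernel average of the column refractive index,
# squared back to permittivity.  The smooth baseline is integrated on the
# phantom's field grid; the 2-mm holes are integrated analytically as
# perturbations on a fine sub-grid so their area is not aliased by the
# coarser field raster.
ideal_grid_matrix <- function(phantom, kernel, profile, geometry,
                              lateral = NULL, condition = "pre",
                              hole_subres_mm = 0.05) {
  support <- max(kernel$radii_mm)
  s <- geometry$step_mm
  nd <- geometry$grid_dim
  ax <- phantom$axis_mm
  res <- phantom$field_res_mm
  base_sqrt <- sqrt(phantom$field)
  wfun <- function(r) {
    w <- kernel_density_at(kernel, r)
    if (!is.null(lateral)) w <- w * lateral_weight_at(lateral, r)
    w
  }
  s_base <- matrix(0, nd, nd)
  w_tot <- matrix(1, nd, nd)   # kernel mass seen by each cell (1 interior)
  full_off <- seq(-ceiling(support / res), ceiling(support / res)) * res
  w_full <- sum(wfun(sqrt(outer(full_off^2, full_off^2, `+`))))
  for (i in seq_len(nd)) {
    cy <- (i - 1) * s
    iy <- which(abs(ax - cy) <= support)
    for (j in seq_len(nd)) {
      cx <- (j - 1) * s
      ix <- which(abs(ax - cx) <= support)
      r <- sqrt(outer((ax[iy] - cy)^2, (ax[ix] - cx)^2, `+`))
      w <- wfun(r)
      dim(w) <- dim(r)
      sw <- sum(w)
      s_base[i, j] <- sum(w * base_sqrt[iy, ix]) / sw
      w_tot[i, j] <- sw / w_full  # clipped fraction of the unit-mass kernel
    }
  }
  # hole perturbations: exact annulus/disc lens areas for the bare radial
  # kernel, fine sub-grid quadrature when a lateral profile multiplies it
  pert <- matrix(0, nd, nd)
  holes <- phantom$holes
  if (nrow(holes)) {
    hr <- holes$diameter_mm[1L] / 2
    if (!is.null(lateral)) {
      g <- seq(-hr + hole_subres_mm / 2, hr - hole_subres_mm / 2,
               by = hole_subres_mm)
      sub <- expand.grid(u = g, v = g)
      sub <- sub[sub$u^2 + sub$v^2 <= hr^2, ]
    }
    cellx <- (seq_len(nd) - 1) * s
    for (hidx in seq_len(nrow(holes))) {
      h <- holes[hidx, ]
      lw <- column_layer_weights(
        if (condition == "post") h$fill_fraction else 0, h$depth_mm,
        profile$delta_mm)
      bb <- base_sqrt[which.min(abs(ax - h$y_mm)), which.min(abs(ax - h$x_mm))]
      dcol <- lw$fluid * sqrt(phantom$eps_fluid) + lw$air * 1 +
        lw$bone * bb - bb
      for (i in which(abs(cellx - h$y_mm) <= support + hr)) {
        dy <- cellx[i] - h$y_mm
        for (j in which(abs(cellx - h$x_mm) <= support + hr)) {
          dx <- cellx[j] - h$x_mm
          d <- sqrt(dx^2 + dy^2)
          wq <- if (is.null(lateral)) {
            kernel_disc_weight(kernel, d, hr)
          } else {
            rr <- sqrt((dx - sub$u)^2 + (dy - sub$v)^2)
            sum(wfun(rr)) * hole_subres_mm^2
          }
          pert[i, j] <- pert[i, j] + dcol * wq / w_tot[i, j]
        }
      }
    }
  }
  (s_base + pert)^2
}

#' Per-antenna multiplicative gain profile
#'
#' 16 positive gains with the realized coefficient of variation rescaled to
#' the target exactly (mean 1).
#'
#' @param cv Target inter-antenna CV (default 0.08).
#' @param seed Integer seed.
#' @return Numeric vector of 16 gains, attribute `target_cv`.
#' @export
antenna_gain_profile <- function(cv = 0.08, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  g <- stats::rnorm(16L)
  g <- 1 + (g - mean(g)) / stats::sd(g) * cv
  if (any(g <= 0)) stop("gain draw produced non-positive gains; lower cv")
  attr(g, "target_cv") <- cv
  g
}

#' Forward-simulate coarse grids for the four rotations
#'
#' Each effective antenna reads the kernel-weighted average of the
#' depth-weighted column refractive index over its footprint, squared back to
#' permittivity (the convention under which two-phase mixing superposes
#' linearly), multiplied by its per-antenna gain in the acquisition frame,
#' plus Gaussian noise.
#'
#' @param phantom A [specimen_phantom()].
#' @param kernel [radial_kernel()] sensing footprint.
#' @param profile [depth_profile()].
#' @param gains 16 multiplicative gains from [antenna_gain_profile()].
#' @param geometry [acquisition_geometry()].
#' @param lateral Optional [sigmoid_fit()] lateral profile.
#' @param noise_sd Additive permittivity noise SD (default 0.02).
#' @param coupling_sd SD of the per-rotation multiplicative coupling factor
#'   emulating probe re-landing contact variability (default 0.055,
#'   calibrated so the four-rotation volume CV sits in the study's observed
#'   low-single-digit range).
#' @param condition `"pre"` or `"post"`.
#' @param seed Integer seed.
#' @return List of [coarse_grid()]s, one per rotation, in the array frame.
#' @export
simulate_coarse_grids <- function(phantom, kernel,
                                  profile = default_depth_profile(),
                                  gains = rep(1, 16L),
                                  geometry = acquisition_geometry(),
                                  lateral = NULL, noise_sd = 0.02,
                                  coupling_sd = 0.055,
                                  condition = c("pre", "post"), seed) {
  condition <- match.arg(condition)
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(inherits(phantom, "specimen_phantom"),
            inherits(kernel, "radial_kernel"))
  s <- geometry$step_mm
  nd <- geometry$grid_dim
  ax <- phantom$axis_mm
  if ((nd - 1) * s > max(ax) + 1e-9 || 0 < min(ax) - 1e-9)
    stop("measurement grid exceeds the phantom extent")
  # footprints protruding past the field edge are clipped; normalized
  # weighting keeps each reading a convex average of what is seen
  ideal <- ideal_grid_matrix(phantom, kernel, profile, geometry, lateral,
                             condition)
  amap <- default_antenna_map()
  set.seed(seed)
  lapply(geometry$rotations_deg, function(th) {
    acq <- rotate_from_common(ideal, th)
    coupling <- if (coupling_sd > 0)
      max(stats::rnorm(1L, 1, coupling_sd), 0.5) else 1
    acq <- acq * coupling * matrix(gains[amap], nd, nd) +
      matrix(stats::rnorm(nd * nd, 0, noise_sd), nd, nd)
    coarse_grid(acq, th, condition, phantom$specimen, antenna_map = amap,
                geometry = geometry, frame = "array")
  })
}

#' Expand a coarse grid into raw embedded S11 sweeps plus standards
#'
#' Each cell's permittivity becomes a flat spectrum, passed through the
#' forward Stuchly model and embedded with the supplied error terms; the four
#' calibration standards (open, short, water, glycol) are emitted alongside,
#' embedded the same way.
#'
#' @param grid A [coarse_grid()].
#' @param params [probe_params()].
#' @param terms [error_terms()] to embed with.
#' @param noise_sd Complex-Gaussian noise SD on the embedded coefficients.
#' @param frequencies_hz Sweep grid (default [default_sweep_frequencies()]).
#' @param seed Seed (needed when `noise_sd > 0`).
#' @return List with `sweeps` (16x16 list matrix of [s11_sweep()]s) and
#'   `standards` (list consumable by [solve_error_terms()]).
#' @export
simulate_s11_layer <- function(grid, params, terms, noise_sd = 0,
                               frequencies_hz = default_sweep_frequencies(),
                               seed = NULL) {
  stopifnot(inherits(grid, "coarse_grid"), inherits(params, "probe_params"),
            inherits(terms, "error_terms"))
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0")
    set.seed(seed)
  }
  nf <- length(frequencies_hz)
  embed_eps <- function(eps, label) {
    gam <- forward_gamma(rep(eps, nf), frequencies_hz, params)
    sw <- embed_sweep(s11_sweep(frequencies_hz, gam, label), terms)
    if (noise_sd > 0)
      sw$gamma <- sw$gamma + complex(real = stats::rnorm(nf, 0, noise_sd),
                                     imaginary = stats::rnorm(nf, 0, noise_sd))
    sw
  }
  nd <- nrow(grid$values)
  sweeps <- vector("list", nd * nd)
  dim(sweeps) <- c(nd, nd)
  for (i in seq_len(nd)) for (j in seq_len(nd))
    sweeps[[i, j]] <- embed_eps(grid$values[i, j], sprintf("cell_%02d_%02d", i, j))
  air <- permittivity_spectrum(frequencies_hz, rep(1 + 0i, nf), "air")
  water <- debye_permittivity(water_22c(), frequencies_hz)
  glycol <- debye_permittivity(propylene_glycol_22c(), frequencies_hz)
  short_meas <- embed_sweep(
    s11_sweep(frequencies_hz, rep(-1 + 0i, nf), "short"), terms)
  standards <- list(
    list(measured = embed_eps(1 + 0i, "open"), actual = air),
    list(measured = short_meas, actual = "short"),
    list(measured = {
      gam <- forward_gamma(water$eps_complex, frequencies_hz, params)
      sw <- embed_sweep(s11_sweep(frequencies_hz, gam, "water"), terms)
      sw
    }, actual = water),
    list(measured = {
      gam <- forward_gamma(glycol$eps_complex, frequencies_hz, params)
      embed_sweep(s11_sweep(frequencies_hz, gam, "glycol"), terms)
    }, actual = glycol))
  list(sweeps = sweeps, standards = standards)
}

#' Calibrate and invert raw sweeps back to a permittivity grid
#'
#' The analysis path for raw data: solve error terms from the standards,
#' de-embed every sweep, invert with the Stuchly model and extract the real
#' permittivity at the target frequency.
#'
#' @param sweeps 16x16 list matrix of [s11_sweep()]s.
#' @param standards Standards list for [solve_error_terms()].
#' @param params [probe_params()].
#' @param f_target_hz Extraction frequency (default 2.5 GHz).
#' @return Numeric matrix of real permittivities.
#' @export
invert_sweeps_to_grid <- function(sweeps, standards, params,
                                  f_target_hz = 2.5e9) {
  terms <- solve_error_terms(standards, params)
  nd <- dim(sweeps)
  out <- matrix(NA_real_, nd[1L], nd[2L])
  for (i in seq_len(nd[1L])) for (j in seq_len(nd[2L])) {
    sw <- de_embed(sweeps[[i, j]], terms)
    eps <- invert_permittivity(sw$gamma, sw$frequencies_hz, params)
    spec <- permittivity_spectrum(sw$frequencies_hz, eps, sw$label)
    out[i, j] <- Re(extract_at_frequency(spec, f_target_hz))
  }
  out
}

# Truncated-normal draws via inverse-CDF rejection-free sampling.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate a CT volume of a phantom
#'
#' Bone background plus hole cylinders: empty-hole voxels draw from
#' `N(25, 73^2)` truncated below 132 HU, filled-hole voxels from
#' `N(482, 132^2)` truncated above 388 HU, honoring the non-overlapping
#' group extremes; truncation can be disabled to study threshold failure.
#'
#' @param phantom A [specimen_phantom()].
#' @param condition `"pre"` (all holes empty) or `"post"` (holes filled per
#'   their fill fraction; a voxel is filled when its depth lies within the
#'   filled top segment of the hole).
#' @param spacing_mm Voxel spacing (default `c(0.94, 0.94, 3.0)`).
#' @param hu_params List with `empty_mean`, `empty_sd`, `empty_max`,
#'   `filled_mean`, `filled_sd`, `filled_min`, `background_mean`,
#'   `background_sd`.
#' @param truncate Honor the group extremes (default TRUE)?
#' @param depth_mm Simulated volume depth (default 24 mm, 8 slices).
#' @param seed Integer seed.
#' @return A [ct_volume()] with origin matching the phantom frame.
#' @export
simulate_ct <- function(phantom, condition = c("pre", "post"),
                        spacing_mm = c(0.94, 0.94, 3.0),
                        hu_params = list(empty_mean = 25, empty_sd = 73,
                                         empty_max = 132, filled_mean = 482,
                                         filled_sd = 132, filled_min = 388,
                                         background_mean = 150,
                                         background_sd = 30),
                        truncate = TRUE, depth_mm = 24, seed) {
  condition <- match.arg(condition)
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(inherits(phantom, "specimen_phantom"))
  set.seed(seed)
  origin <- c(min(phantom$axis_mm), min(phantom$axis_mm), 0)
  nx <- ceiling(phantom$extent_mm / spacing_mm[1L])
  ny <- ceiling(phantom$extent_mm / spacing_mm[2L])
  nz <- ceiling(depth_mm / spacing_mm[3L])
  hu <- array(stats::rnorm(nx * ny * nz, hu_params$background_mean,
                           hu_params$background_sd), c(nx, ny, nz))
  xc <- origin[1L] + (seq_len(nx) - 0.5) * spacing_mm[1L]
  yc <- origin[2L] + (seq_len(ny) - 0.5) * spacing_mm[2L]
  zc <- (seq_len(nz) - 0.5) * spacing_mm[3L]
  for (i in seq_len(nrow(phantom$holes))) {
    h <- phantom$holes[i, ]
    f_top <- if (condition == "post") h$fill_fraction else 0
    ix <- which(abs(xc - h$x_mm) <= h$diameter_mm / 2)
    iy <- which(abs(yc - h$y_mm) <= h$diameter_mm / 2)
    iz <- which(zc <= h$depth_mm)
    for (a in ix) for (b in iy) {
      if ((xc[a] - h$x_mm)^2 + (yc[b] - h$y_mm)^2 > (h$diameter_mm / 2)^2)
        next
      filled <- zc[iz] <= f_top * h$depth_mm
      nfil <- sum(filled); nemp <- sum(!filled)
      if (nfil)
        hu[a, b, iz[filled]] <- rtruncnorm(
          nfil, hu_params$filled_mean, hu_params$filled_sd,
          lower = if (truncate) hu_params$filled_min else -Inf)
      if (nemp)
        hu[a, b, iz[!filled]] <- rtruncnorm(
          nemp, hu_params$empty_mean, hu_params$empty_sd,
          upper = if (truncate) hu_params$empty_max else Inf)
    }
  }
  ct_volume(hu, spacing_mm, origin)
}

#' Default study specimen table
#'
#' The seven-specimen design: hole counts (A, B, G: 16; E, F: 20; C, D: 25)
#' and per-specimen baseline permittivity statistics; for `n > 7` the design
#' is recycled with fresh ids.
#'
#' @param n Number of specimens (default 7).
#' @return Data frame with `id`, `n_holes`, `baseline_mean`, `baseline_sd`.
#' @export
default_study_specimens <- function(n = 7L) {
  base <- data.frame(
    id = LETTERS[1:7],
    n_holes = c(16L, 16L, 25L, 25L, 20L, 20L, 16L),
    baseline_mean = c(1.771, 1.789, 1.646, 1.357, 1.386, 1.378, 1.134),
    baseline_sd = c(0.185, 0.162, 0.112, 0.114, 0.127, 0.114, 0.062))
  if (n <= 7L) return(base[seq_len(n), , drop = FALSE])
  out <- base[rep(seq_len(7L), length.out = n), , drop = FALSE]
  out$id <- sprintf("S%02d", seq_len(n))
  rownames(out) <- NULL
  out
}

#' Study configuration
#'
#' @param seed Mandatory master seed; all per-specimen/rotation draws derive
#'   from it deterministically.
#' @param specimens Data frame as from [default_study_specimens()].
#' @param noise_sd Permittivity noise SD (default 0.02).
#' @param coupling_sd Per-rotation coupling-factor SD (default 0.055).
#' @param gain_cv Target inter-antenna CV (default 0.08).
#' @param eps_fluid Gel permittivity (default 62).
#' @param fill_fraction Scalar or per-hole fill (default 1).
#' @param kernel_sigma_mm Gaussian footprint scale of the simulated probes
#'   (default 3).
#' @param pixel_size_mm Upscaled pixel size (default 0.5).
#' @param include_ct Simulate CT volumes too (default TRUE)?
#' @return An object of class `study_config`.
#' @export
study_config <- function(seed, specimens = default_study_specimens(),
                         noise_sd = 0.02, coupling_sd = 0.055,
                         gain_cv = 0.08, eps_fluid = 62,
                         fill_fraction = 1, kernel_sigma_mm = 3,
                         pixel_size_mm = 0.5, include_ct = TRUE) {
  if (missing(seed)) stop("a seed is mandatory")
  structure(list(seed = as.integer(seed), specimens = specimens,
                 noise_sd = noise_sd, coupling_sd = coupling_sd,
                 gain_cv = gain_cv,
                 eps_fluid = eps_fluid, fill_fraction = fill_fraction,
                 kernel_sigma_mm = kernel_sigma_mm,
                 pixel_size_mm = pixel_size_mm, include_ct = include_ct),
            class = "study_config")
}

#' Generate a full synthetic study
#'
#' One phantom per specimen with pre/post coarse grids over four rotations,
#' optional pre/post CT volumes, per-antenna gains, and a ground-truth
#' manifest.
#'
#' @param config A [study_config()].
#' @return An object of class `mwi_study`: list with `specimens` (each
#'   holding `phantom`, `gains`, `pre_grids`, `post_grids`, `ct_pre`,
#'   `ct_post`) and `ground_truth` (data frame with true injected and
#'   depth-scaled volumes).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  kernel <- gaussian_kernel(config$kernel_sigma_mm)
  profile <- default_depth_profile()
  specs <- config$specimens
  out <- vector("list", nrow(specs))
  gt <- data.frame(id = specs$id, n_holes = specs$n_holes,
                   injected_ul = NA_real_, scaled_ul = NA_real_)
  for (i in seq_len(nrow(specs))) {
    s0 <- config$seed + i * 7919L
    ph <- make_phantom(specs$n_holes[i], specs$baseline_mean[i],
                       specs$baseline_sd[i], config$eps_fluid,
                       config$fill_fraction, specimen = specs$id[i],
                       seed = s0)
    gains <- antenna_gain_profile(config$gain_cv, seed = s0 + 1L)
    pre <- simulate_coarse_grids(ph, kernel, profile, gains,
                                 noise_sd = config$noise_sd,
                                 coupling_sd = config$coupling_sd,
                                 condition = "pre", seed = s0 + 2L)
    post <- simulate_coarse_grids(ph, kernel, profile, gains,
                                  noise_sd = config$noise_sd,
                                  coupling_sd = config$coupling_sd,
                                  condition = "post", seed = s0 + 3L)
    sp <- list(id = specs$id[i], phantom = ph, gains = gains,
               pre_grids = pre, post_grids = post)
    if (config$include_ct) {
      sp$ct_pre <- simulate_ct(ph, "pre", seed = s0 + 4L)
      sp$ct_post <- simulate_ct(ph, "post", seed = s0 + 5L)
    }
    out[[i]] <- sp
    gt$injected_ul[i] <- phantom_true_volume(ph)
    gt$scaled_ul[i] <- phantom_true_volume(ph, profile, scaled = TRUE)
  }
  structure(list(specimens = out, ground_truth = gt, config = config,
                 kernel = kernel, profile = profile),
            class = "mwi_study")
}

#' @export
print.mwi_study <- function(x, ...) {
  cat(sprintf("<mwi_study> %d specimens, seed %d, noise_sd %.3g, gain_cv %.3g\n",
              length(x$specimens), x$config$seed, x$config$noise_sd,
              x$config$gain_cv))
  invisible(x)
}

#' Measure the realized inter-antenna CV of a study specimen
#'
#' Table-3 style: the mean baseline (pre-injection) permittivity read by each
#' physical antenna across all positions and rotations, then the CV across
#' the 16 antennas.
#'
#' @param pre_grids List of array-frame pre-injection [coarse_grid()]s.
#' @return CV in percent.
#' @export
interantenna_cv <- function(pre_grids) {
  means <- vapply(1:16, function(a) {
    mean(unlist(lapply(pre_grids, function(g) g$values[g$antenna_map == a])))
  }, 0)
  100 * stats::sd(means) / mean(means)
}
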