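# CT-side reference: cylindrical VOI extraction on HU voxel grids,
# threshold-based hole positivity, nominal-volume assignment, threshold
# derivation from the empty/filled group statistics, and depth rescaling.

#' CT volume container
#'
#' @param hu 3-D numeric array of Hounsfield units (x, y, z order).
#' @param spacing_mm Voxel spacing in mm (default `c(0.94, 0.94, 3.0)`:
#'   in-plane pixels and slice thickness of the study protocol).
#' @param origin_mm Physical position of the corner of voxel `[1,1,1]`.
#' @return An object of class `ct_volume`.  Voxel centers sit at
#'   `origin + (index - 0.5) * spacing`.
#' @export
ct_volume <- function(hu, spacing_mm = c(0.94, 0.94, 3.0),
                      origin_mm = c(0, 0, 0)) {
  if (length(dim(hu)) != 3L) stop("hu must be a 3-D array")
  if (any(spacing_mm <= 0)) stop("spacing must be positive")
  if (any(!is.finite(hu))) stop("HU values must be finite")
  structure(list(hu = hu, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("<ct_volume> %dx%dx%d voxels @ (%.3g, %.3g, %.3g) mm, HU in [%.0f, %.0f]\n",
              d[1L], d[2L], d[3L], x$spacing_mm[1L], x$spacing_mm[2L],
              x$spacing_mm[3L], min(x$hu), max(x$hu)))
  invisible(x)
}

#' Read a NIfTI file into a `ct_volume`
#'
#' @param path Path to a NIfTI image.
#' @return A [ct_volume()] using the image's voxel dimensions.
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  ct_volume(unclass(as.array(img)), spacing_mm = RNifti::pixdim(img)[1:3])
}

#' Write a `ct_volume` to NIfTI
#'
#' @param vol A [ct_volume()].
#' @param path Output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_ct_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$hu)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Cylindrical hole volume of interest
#'
#' A drilled hole on the flat face: axis along z from the surface (z = 0)
#' down to `depth_mm`.  The nominal volume `pi (d/2)^2 depth` of the standard
#' 2 mm x 8 mm hole is 25.13 uL.
#'
#' @param center_mm `(x, y)` of the hole center on the flat face, mm.
#' @param diameter_mm Hole diameter (default 2).
#' @param depth_mm Hole depth (default 8).
#' @return An object of class `hole_voi` with field `nominal_ul`.
#' @export
hole_voi <- function(center_mm, diameter_mm = 2, depth_mm = 8) {
  if (length(center_mm) != 2L) stop("center_mm must be (x, y)")
  if (diameter_mm <= 0 || depth_mm <= 0) stop("diameter and depth must be > 0")
  structure(list(center_mm = as.numeric(center_mm),
                 diameter_mm = diameter_mm, depth_mm = depth_mm,
                 nominal_ul = pi * (diameter_mm / 2)^2 * depth_mm),
            class = "hole_voi")
}

#' Extract HU values inside a cylindrical VOI
#'
#' Voxel-center membership: a voxel belongs to the VOI when its center falls
#' inside the cylinder laterally and within `[0, depth]` axially.
#'
#' @param vol A [ct_volume()].
#' @param hole A [hole_voi()].
#' @return Numeric vector of HU values (length >= 1).
#' @export
extract_voi <- function(vol, hole) {
  stopifnot(inherits(vol, "ct_volume"), inherits(hole, "hole_voi"))
  d <- dim(vol$hu); sp <- vol$spacing_mm; or <- vol$origin_mm
  r <- hole$diameter_mm / 2
  cx <- hole$center_mm[1L]; cy <- hole$center_mm[2L]
  if (cx - r < or[1L] || cx + r > or[1L] + d[1L] * sp[1L] ||
      cy - r < or[2L] || cy + r > or[2L] + d[2L] * sp[2L] ||
      hole$depth_mm > d[3L] * sp[3L])
    stop("cylinder extends beyond the CT volume bounds")
  xc <- or[1L] + (seq_len(d[1L]) - 0.5) * sp[1L]
  yc <- or[2L] + (seq_len(d[2L]) - 0.5) * sp[2L]
  zc <- or[3L] + (seq_len(d[3L]) - 0.5) * sp[3L]
  ix <- which(abs(xc - cx) <= r)
  iy <- which(abs(yc - cy) <= r)
  iz <- which(zc >= 0 & zc <= hole$depth_mm)
  vals <- numeric(0)
  for (i in ix) for (j in iy) {
    if ((xc[i] - cx)^2 + (yc[j] - cy)^2 <= r^2)
      vals <- c(vals, vol$hu[i, j, iz])
  }
  if (!length(vals))
    stop("no voxel centers inside the cylinder (grid too coarse)")
  vals
}

#' Classify a hole as filled from its VOI values
#'
#' Positive iff at least `fraction` of the voxels reach `threshold_hu`
#' (both comparisons inclusive).
#'
#' @param values Nonempty numeric HU vector from [extract_voi()].
#' @param threshold_hu HU cutoff (default 250).
#' @param fraction Required voxel fraction (default 0.5).
#' @return Logical.
#' @export
classify_hole <- function(values, threshold_hu = 250, fraction = 0.5) {
  if (!length(values)) stop("empty VOI value list")
  mean(values >= threshold_hu) >= fraction
}

#' Derive the empty/filled separation threshold
#'
#' From the maximum HU recorded in any empty hole and the minimum in any
#' filled hole: `gap = min_filled - max_empty`,
#' `midpoint = (max_empty + min_filled)/2`.  The study's working cutoff
#' defaults to 250 HU, near the midpoints of both the extreme-value (260)
#' and mean-intensity (253.5) separations.
#'
#' @param empty_max_hu Maximum HU over empty (true-negative) holes.
#' @param filled_min_hu Minimum HU over filled (true-positive) holes; must
#'   exceed `empty_max_hu`.
#' @param chosen_threshold_hu Working threshold (default 250).
#' @return An object of class `threshold_derivation` with fields
#'   `max_empty_hu`, `min_filled_hu`, `gap_hu`, `midpoint_hu`,
#'   `chosen_threshold_hu`.
#' @export
derive_threshold <- function(empty_max_hu, filled_min_hu,
                             chosen_threshold_hu = 250) {
  if (filled_min_hu <= empty_max_hu)
    stop("overlapping groups: no clean threshold exists")
  structure(list(max_empty_hu = empty_max_hu, min_filled_hu = filled_min_hu,
                 gap_hu = filled_min_hu - empty_max_hu,
                 midpoint_hu = (empty_max_hu + filled_min_hu) / 2,
                 chosen_threshold_hu = chosen_threshold_hu),
            class = "threshold_derivation")
}

#' @export
print.threshold_derivation <- function(x, ...) {
  cat(sprintf("<threshold_derivation> gap %g HU (%g..%g), midpoint %g, chosen %g\n",
              x$gap_hu, x$max_empty_hu, x$min_filled_hu, x$midpoint_hu,
              x$chosen_threshold_hu))
  invisible(x)
}

#' CT-derived volume from the positive-hole count
#'
#' Each positive hole contributes the nominal cylinder volume
#' `pi * 1^2 * 8 = 25.133` uL.
#'
#' @param n_positive Non-negative integer count of positive holes.
#' @param diameter_mm,depth_mm Hole geometry (defaults 2 and 8 mm).
#' @return Volume in uL.
#' @export
ct_volume_from_positives <- function(n_positive, diameter_mm = 2,
                                     depth_mm = 8) {
  if (n_positive < 0) stop("n_positive must be >= 0")
  n_positive * pi * (diameter_mm / 2)^2 * depth_mm
}

#' Depth-rescale a reference volume to the probe's sensing slab
#'
#' Multiplies by `rho = d_eff(H)/H` so CT-derived and injected volumes are
#' expressed over the same interrogated equivalent slab as the microwave
#' estimates.
#'
#' @param volume_ul Volume in uL, >= 0.
#' @param profile A [depth_profile()].
#' @param hole_depth_mm Hole depth (default 8).
#' @return Rescaled volume in uL.
#' @export
depth_rescale <- function(volume_ul, profile, hole_depth_mm = 8) {
  if (any(volume_ul < 0)) stop("volume must be >= 0")
  volume_ul * depth_factor(profile, hole_depth_mm)
}

#' Count positive holes across a layout
#'
#' @param vol A [ct_volume()].
#' @param layout Data frame with columns `x_mm`, `y_mm` (hole centers).
#' @param threshold_hu,fraction Passed to [classify_hole()].
#' @param diameter_mm,depth_mm Hole geometry.
#' @return Integer count of positive holes.
#' @export
count_positive_holes <- function(vol, layout, threshold_hu = 250,
                                 fraction = 0.5, diameter_mm = 2,
                                 depth_mm = 8) {
  sum(vapply(seq_len(nrow(layout)), function(i) {
    vals <- extract_voi(vol, hole_voi(c(layout$x_mm[i], layout$y_mm[i]),
                                      diameter_mm, depth_mm))
    classify_hole(vals, threshold_hu, fraction)
  }, logical(1L)))
}
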