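# Assembly of stepped 4x4 array readings into 16x16 effective matrices,
# de-rotation to a common specimen frame, and sensitivity-weighted upscaling
# to high-resolution permittivity maps.
#
# Frame convention: matrix row i maps to y = (i-1)*spacing, column j to
# x = (j-1)*spacing (mm, specimen frame), origin at cell (1,1).

#' Acquisition geometry of the stepped probe array
#'
#' A 4x4 antenna array at `antenna_pitch_mm` is stepped through a 4x4 offset
#' pattern at `antenna_pitch_mm / 4`, interleaving to a 16x16 effective
#' measurement grid with uniform spacing pitch/4; four 90-degree rotations
#' serve as replicates.
#'
#' @param antenna_pitch_mm Physical antenna pitch in mm (default 16).
#' @param rotations_deg Rotation replicates, multiples of 90.
#' @return An object of class `acquisition_geometry` with derived fields
#'   `step_mm` (= pitch/4) and `grid_dim` (16).
#' @export
acquisition_geometry <- function(antenna_pitch_mm = 16,
                                 rotations_deg = c(0, 90, 180, 270)) {
  if (antenna_pitch_mm <= 0) stop("antenna pitch must be > 0")
  if (any(rotations_deg %% 90 != 0))
    stop("rotations must be multiples of 90 degrees")
  structure(list(array_shape = c(4L, 4L), antenna_pitch_mm = antenna_pitch_mm,
                 step_mm = antenna_pitch_mm / 4, grid_dim = 16L,
                 rotations_deg = rotations_deg %% 360),
            class = "acquisition_geometry")
}

#' Coarse 16x16 permittivity grid
#'
#' @param values 16x16 numeric matrix of real permittivities at the working
#'   frequency.
#' @param rotation_deg Acquisition rotation (0/90/180/270).
#' @param condition `"pre"` or `"post"` injection.
#' @param specimen Specimen id.
#' @param antenna_map Integer 16x16 matrix tracing each cell to the physical
#'   antenna (1-16) that produced it.
#' @param geometry The [acquisition_geometry()].
#' @param frame `"array"` (as acquired) or `"common"` (de-rotated).
#' @return An object of class `coarse_grid`.
#' @export
coarse_grid <- function(values, rotation_deg = 0,
                        condition = c("pre", "post"), specimen = "",
                        antenna_map = NULL,
                        geometry = acquisition_geometry(),
                        frame = c("array", "common")) {
  condition <- match.arg(condition)
  frame <- match.arg(frame)
  values <- as.matrix(values)
  if (!all(dim(values) == c(16L, 16L))) stop("grid must be exactly 16x16")
  if (any(!is.finite(values))) stop("grid values must be finite")
  if (is.null(antenna_map)) antenna_map <- default_antenna_map()
  structure(list(values = values, rotation_deg = rotation_deg %% 360,
                 condition = condition, specimen = specimen,
                 antenna_map = antenna_map, geometry = geometry,
                 frame = frame),
            class = "coarse_grid")
}

#' @export
print.coarse_grid <- function(x, ...) {
  cat(sprintf("<coarse_grid> specimen %s, %s, rot %d (%s frame), eps in [%.3g, %.3g]\n",
              if (nzchar(x$specimen)) x$specimen else "?", x$condition,
              x$rotation_deg, x$frame, min(x$values), max(x$values)))
  invisible(x)
}

# Effective cell (i,j) <- (antenna row ai, step row si): i = (ai-1)*4 + si.
default_antenna_map <- function() {
  m <- matrix(0L, 16L, 16L)
  for (ai in 1:4) for (aj in 1:4)
    m[(ai - 1L) * 4L + 1:4, (aj - 1L) * 4L + 1:4] <- (ai - 1L) * 4L + aj
  m
}

#' Assemble stepped readings into a 16x16 effective grid
#'
#' @param readings List of 16 entries, each a list with `step = c(si, sj)`
#'   (1-4 step-pattern indices) and `values` (4x4 matrix of readings from the
#'   physical array at that position).
#' @param geometry [acquisition_geometry()].
#' @param rotation_deg Acquisition rotation of this pass.
#' @param condition,specimen Metadata passed to [coarse_grid()].
#' @return A [coarse_grid()] in the array frame.
#' @export
assemble_grid <- function(readings, geometry = acquisition_geometry(),
                          rotation_deg = 0, condition = "pre",
                          specimen = "") {
  seen <- matrix(FALSE, 4L, 4L)
  values <- matrix(NA_real_, 16L, 16L)
  for (rd in readings) {
    si <- rd$step[1L]; sj <- rd$step[2L]
    if (si < 1L || si > 4L || sj < 1L || sj > 4L)
      stop("step indices must be in 1..4")
    v <- as.matrix(rd$values)
    if (!all(dim(v) == c(4L, 4L))) stop("each position must carry a 4x4 block")
    seen[si, sj] <- TRUE
    for (ai in 1:4) for (aj in 1:4)
      values[(ai - 1L) * 4L + si, (aj - 1L) * 4L + sj] <- v[ai, aj]
  }
  if (!all(seen)) {
    gaps <- which(!seen, arr.ind = TRUE)
    stop("missing step positions: ",
         paste(sprintf("(%d,%d)", gaps[, 1L], gaps[, 2L]), collapse = " "))
  }
  coarse_grid(values, rotation_deg, condition, specimen,
              geometry = geometry, frame = "array")
}

# Quarter-turn rotations (k counterclockwise quarter turns) of a matrix.
rot90_mat <- function(m, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

#' De-rotate an acquired grid into the common specimen frame
#'
#' Exact (interpolation-free) for the 90-degree multiples used by the
#' acquisition protocol.  The antenna trace map is rotated alongside the
#' values so per-antenna provenance survives.
#'
#' @param grid A [coarse_grid()] in the array frame.
#' @return The grid in the common frame (`frame = "common"`).
#' @export
rotate_to_common <- function(grid) {
  stopifnot(inherits(grid, "coarse_grid"))
  if (grid$frame == "common") return(grid)
  if (!grid$rotation_deg %in% c(0, 90, 180, 270))
    stop("only 90-degree rotation multiples are supported")
  k <- grid$rotation_deg / 90
  out <- grid
  out$values <- rot90_mat(grid$values, -k)
  out$antenna_map <- rot90_mat(grid$antenna_map, -k)
  out$frame <- "common"
  out
}

# Rotate a common-frame matrix into the acquisition frame of `rotation_deg`
# (simulator-side counterpart of rotate_to_common).
rotate_from_common <- function(values, rotation_deg) {
  rot90_mat(values, rotation_deg / 90)
}

#' High-resolution permittivity map
#'
#' @param pixels 2-D numeric matrix.
#' @param pixel_size_mm Pixel size in mm.
#' @param origin_mm `(x, y)` of the center of pixel `[1, 1]`, mm.
#' @param metadata Free-form list (specimen, condition, rotation set).
#' @return An object of class `permittivity_map`.
#' @export
permittivity_map <- function(pixels, pixel_size_mm, origin_mm = c(0, 0),
                             metadata = list()) {
  pixels <- as.matrix(pixels)
  if (pixel_size_mm <= 0) stop("pixel size must be > 0")
  structure(list(pixels = pixels, pixel_size_mm = pixel_size_mm,
                 origin_mm = as.numeric(origin_mm), metadata = metadata),
            class = "permittivity_map")
}

#' @export
print.permittivity_map <- function(x, ...) {
  cat(sprintf("<permittivity_map> %dx%d px @ %.3g mm, eps in [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_mm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Upscale a coarse grid to a high-resolution permittivity map
#'
#' Normalized sensitivity-weighted interpolation:
#' `eps(x) = sum_ij W(|x - p_ij|) eps_ij / sum_ij W`, where the composite
#' weight `W(r)` is the radial kernel density optionally multiplied by the
#' lateral profile derived from the side-to-side sigmoid fit.  Weights at
#' each pixel are normalized to sum to one (partition of unity), so every
#' map value is a convex combination of coarse values.  The map covers the
#' grid bounding box plus an `r_eq` margin.
#'
#' @param grid A common-frame [coarse_grid()].
#' @param kernel A [radial_kernel()].
#' @param lateral Optional [sigmoid_fit()] of the side-to-side curve.
#' @param pixel_size_mm Output pixel size, must be smaller than the effective
#'   grid spacing.
#' @return A [permittivity_map()].
#' @export
upscale <- function(grid, kernel, lateral = NULL, pixel_size_mm = 0.5) {
  stopifnot(inherits(grid, "coarse_grid"), inherits(kernel, "radial_kernel"))
  s <- grid$geometry$step_mm
  if (pixel_size_mm >= s)
    stop("pixel size must be smaller than the effective grid spacing")
  support <- max(kernel$radii_mm)
  if (support <= 0) stop("kernel support must be > 0")
  margin <- kernel$r_eq_mm
  n <- grid$geometry$grid_dim
  # pixel centers
  x0 <- -margin; x1 <- (n - 1) * s + margin
  px <- seq(x0, x1, by = pixel_size_mm)
  py <- seq(x0, x1, by = pixel_size_mm)
  num <- matrix(0, length(py), length(px))
  den <- matrix(0, length(py), length(px))
  for (i in seq_len(n)) {
    cy <- (i - 1) * s
    ry <- which(abs(py - cy) <= support)
    if (!length(ry)) next
    dy2 <- (py[ry] - cy)^2
    for (j in seq_len(n)) {
      cx <- (j - 1) * s
      rx <- which(abs(px - cx) <= support)
      if (!length(rx)) next
      r <- sqrt(outer(dy2, (px[rx] - cx)^2, `+`))
      w <- kernel_density_at(kernel, r)
      if (!is.null(lateral)) w <- w * lateral_weight_at(lateral, r)
      dim(w) <- dim(r)
      num[ry, rx] <- num[ry, rx] + w * grid$values[i, j]
      den[ry, rx] <- den[ry, rx] + w
    }
  }
  if (any(den == 0))
    stop("pixels with all-zero interpolation weight: kernel support too small")
  permittivity_map(num / den, pixel_size_mm, origin_mm = c(x0, x0),
                   metadata = list(specimen = grid$specimen,
                                   condition = grid$condition,
                                   rotation_deg = grid$rotation_deg))
}

#' Pixel-wise mean of maps from the four rotations
#'
#' @param maps List of [permittivity_map()]s on identical rasters.
#' @return A [permittivity_map()] with metadata recording the rotation set.
#' @export
average_rotations <- function(maps) {
  if (!length(maps)) stop("no maps supplied")
  ref <- maps[[1L]]
  for (m in maps) {
    stopifnot(inherits(m, "permittivity_map"))
    if (!identical(dim(m$pixels), dim(ref$pixels)) ||
        m$pixel_size_mm != ref$pixel_size_mm ||
        any(m$origin_mm != ref$origin_mm))
      stop("maps must share shape, pixel size and origin")
  }
  acc <- Reduce(`+`, lapply(maps, `[[`, "pixels")) / length(maps)
  permittivity_map(acc, ref$pixel_size_mm, ref$origin_mm,
                   metadata = list(
                     specimen = ref$metadata$specimen,
                     condition = ref$metadata$condition,
                     rotations_deg = vapply(maps, function(m)
                       as.numeric(m$metadata$rotation_deg %||% NA_real_), 0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
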