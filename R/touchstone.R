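# Touchstone .s1p I/O for one-port sweeps.  Only the 1-port subset of the
# format is handled: option line "# <unit> S <format> R <z0>", comment lines
# starting with "!", one "f a b" triple per line.

.ts_units <- c(hz = 1, khz = 1e3, mhz = 1e6, ghz = 1e9)

#' Read a one-port Touchstone (.s1p) file
#'
#' Supports RI (real/imaginary), MA (magnitude/angle in degrees) and DB
#' (dB magnitude/angle) data formats and Hz/kHz/MHz/GHz frequency units,
#' auto-detected from the option line.
#'
#' @param path Path to a `.s1p` file.
#' @param label Label for the resulting sweep (default: file name).
#' @return An [s11_sweep()].
#' @export
read_touchstone <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("!.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  opt <- grep("^#", lines, value = TRUE)
  unit_mult <- 1e9; fmt <- "ma"  # Touchstone defaults: GHz, MA
  if (length(opt)) {
    toks <- tolower(strsplit(sub("^#\\s*", "", opt[1L]), "\\s+")[[1L]])
    u <- intersect(toks, names(.ts_units))
    if (length(u)) unit_mult <- .ts_units[[u[1L]]]
    f <- intersect(toks, c("ri", "ma", "db"))
    if (length(f)) fmt <- f[1L]
  }
  dat <- lines[!grepl("^#", lines)]
  if (!length(dat)) stop("no data lines in ", path)
  m <- do.call(rbind, lapply(strsplit(dat, "\\s+"), function(x) {
    v <- as.numeric(x)
    if (length(v) < 3L || any(is.na(v[1:3])))
      stop("malformed Touchstone data line in ", path)
    v[1:3]
  }))
  gamma <- switch(fmt,
    ri = complex(real = m[, 2L], imaginary = m[, 3L]),
    ma = m[, 2L] * exp(1i * m[, 3L] * pi / 180),
    db = 10^(m[, 2L] / 20) * exp(1i * m[, 3L] * pi / 180))
  s11_sweep(m[, 1L] * unit_mult, gamma, label)
}

#' Write a one-port sweep as Touchstone (.s1p)
#'
#' @param sweep An [s11_sweep()].
#' @param path Output path.
#' @param format One of `"RI"`, `"MA"`, `"DB"`.
#' @param unit One of `"Hz"`, `"kHz"`, `"MHz"`, `"GHz"`.
#' @param z0 Reference impedance recorded on the option line.
#' @return `path`, invisibly.
#' @export
write_touchstone <- function(sweep, path, format = c("RI", "MA", "DB"),
                             unit = c("GHz", "MHz", "kHz", "Hz"), z0 = 50) {
  stopifnot(inherits(sweep, "s11_sweep"))
  format <- match.arg(format)
  unit <- match.arg(unit)
  mult <- .ts_units[[tolower(unit)]]
  f <- sweep$frequencies_hz / mult
  g <- sweep$gamma
  ab <- switch(format,
    RI = cbind(Re(g), Im(g)),
    MA = cbind(Mod(g), Arg(g) * 180 / pi),
    DB = cbind(20 * log10(Mod(g)), Arg(g) * 180 / pi))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("! %s", sweep$label), con)
  writeLines(sprintf("# %s S %s R %g", unit, format, z0), con)
  writeLines(sprintf("%.12g %.12g %.12g", f, ab[, 1L], ab[, 2L]), con)
  invisible(path)
}

#' Read a calibration-standards directory
#'
#' Expects `open.s1p`, `short.s1p`, `water.s1p`, `glycol.s1p` under `dir` and
#' returns the standards list consumed by [solve_error_terms()].
#'
#' @param dir Directory containing the four standard sweeps.
#' @param params [probe_params()] for the open (air) standard's forward model.
#' @param water,glycol [debye_liquid()] models for the liquid standards.
#' @return A list of standards (`measured` + `actual` entries).
#' @export
read_calibration_dir <- function(dir, params,
                                 water = water_22c(),
                                 glycol = propylene_glycol_22c()) {
  need <- c("open", "short", "water", "glycol")
  paths <- file.path(dir, paste0(need, ".s1p"))
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop("missing calibration standards: ", paste(missing, collapse = ", "))
  sw <- lapply(paths, read_touchstone)
  f <- sw[[1L]]$frequencies_hz
  air <- permittivity_spectrum(f, rep(1 + 0i, length(f)), "air")
  list(
    list(measured = sw[[1L]], actual = air),
    list(measured = sw[[2L]], actual = "short"),
    list(measured = sw[[3L]], actual = debye_permittivity(water, f)),
    list(measured = sw[[4L]], actual = debye_permittivity(glycol, f)))
}
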