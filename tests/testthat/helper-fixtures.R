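# Shared builders for the test suite.

default_params <- function() probe_params(25e-15, 20e-15)

identity_terms <- function(f = default_sweep_frequencies()) {
  error_terms(f, 0 + 0i, 1 + 0i, 0 + 0i)
}

# Standards list (open/short/water/glycol) with measured == actual, or
# embedded through `terms` when given.
make_standards <- function(params = default_params(),
                           f = default_sweep_frequencies(), terms = NULL) {
  air <- permittivity_spectrum(f, rep(1 + 0i, length(f)), "air")
  water <- debye_permittivity(water_22c(), f)
  glycol <- debye_permittivity(propylene_glycol_22c(), f)
  mk <- function(spec, label) {
    gam <- forward_gamma(spec$eps_complex, f, params)
    sw <- s11_sweep(f, gam, label)
    if (!is.null(terms)) sw <- embed_sweep(sw, terms)
    sw
  }
  short <- s11_sweep(f, rep(-1 + 0i, length(f)), "short")
  if (!is.null(terms)) short <- embed_sweep(short, terms)
  list(list(measured = mk(air, "open"), actual = air),
       list(measured = short, actual = "short"),
       list(measured = mk(water, "water"), actual = water),
       list(measured = mk(glycol, "glycol"), actual = glycol))
}

# Cumulative center-to-edge response implied by a radial density function:
# R(D) = integral of dens(r) over the disc of radius D/2 (fine quadrature).
forward_cumulative <- function(dens_fun, diameters_mm) {
  ann <- function(r) dens_fun(r) * 2 * pi * r
  tot <- stats::integrate(ann, 0, max(diameters_mm) / 2)$value
  vapply(diameters_mm / 2, function(rr)
    stats::integrate(ann, 0, rr)$value / tot, 0)
}

# Independent 4/8-connected flood fill used as the ROI component oracle.
flood_components <- function(mask, eight = TRUE) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nextlab <- 0L
  offs <- if (eight)
    rbind(c(-1,-1),c(-1,0),c(-1,1),c(0,-1),c(0,1),c(1,-1),c(1,0),c(1,1))
  else rbind(c(-1,0),c(1,0),c(0,-1),c(0,1))
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      ci <- (cur - 1L) %% nrow(mask) + 1L
      cj <- (cur - 1L) %/% nrow(mask) + 1L
      for (k in seq_len(nrow(offs))) {
        ni <- ci + offs[k, 1L]; nj <- cj + offs[k, 2L]
        if (ni < 1L || ni > nrow(mask) || nj < 1L || nj > ncol(mask)) next
        idx <- (nj - 1L) * nrow(mask) + ni
        if (mask[idx] && lab[idx] == 0L) {
          lab[idx] <- nextlab
          queue <- c(queue, idx)
        }
      }
    }
  }
  lab
}
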