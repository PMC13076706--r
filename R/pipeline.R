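# Orchestration and the packaged-results reproduction entry point: the
# study's per-specimen volume tables ship as plain-CSV fixtures, and
# reproduce_results() recomputes the full agreement and repeatability panels
# from them; run_pipeline() drives the synthetic study end-to-end.

#' Packaged per-specimen volume fixture
#'
#' Seven rows (specimens A-G): measured injected volume and uncertainty,
#' depth-scaled injected volume, CT-estimated and CT-scaled volumes, and the
#' microwave-measured volume, all in uL.
#'
#' @return Data frame with 7 rows.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_volumes.csv", package = "mwivol",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "injected_ul", "injected_uncertainty_ul",
            "scaled_injected_ul", "ct_ul", "ct_scaled_ul", "mwi_ul")
  if (!identical(names(df), need) || nrow(df) != 7L ||
      !identical(df$specimen, LETTERS[1:7]))
    stop("packaged volume fixture is corrupt")
  df
}

#' Packaged repeatability fixture
#'
#' Per-specimen mean, SD, CV and 95% CI of the four-rotation microwave
#' volume estimates, in uL and percent.
#'
#' @return Data frame with 7 rows.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_repeatability.csv",
                      package = "mwivol", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) != 7L || !identical(df$specimen, LETTERS[1:7]))
    stop("packaged repeatability fixture is corrupt")
  df
}

#' Packaged baseline permittivity fixture
#'
#' Per-specimen mean, SD and inter-antenna CV of the baseline dielectric
#' permittivity across the 16-probe array.
#'
#' @return Data frame with 7 rows.
#' @export
table3_fixture <- function() {
  path <- system.file("extdata", "table3_baseline.csv", package = "mwivol",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute the full results panel from the packaged fixtures
#'
#' From the per-specimen volume table: the agreement battery of the
#' microwave estimates against the depth-scaled injected volumes and against
#' the depth-scaled CT volumes, plus the CT-versus-injected deficit; from the
#' repeatability table: recomputed CVs and t-based CIs.
#'
#' @param volumes Data frame as [table2_fixture()].
#' @param repeats Data frame as [table1_fixture()].
#' @param boot_B Bootstrap resamples for CIs (0 disables).
#' @param seed Bootstrap seed.
#' @return List with elements `injected` and `ct`
#'   ([agreement_report()]s), `ct_deficit` (list with `bias`, `sd`),
#'   and `repeatability` (data frame with recomputed `cv_percent`,
#'   `ci_lo_ul`, `ci_hi_ul`, plus `mean_cv_percent` attribute).
#' @export
reproduce_results <- function(volumes = table2_fixture(),
                              repeats = table1_fixture(),
                              boot_B = 0L, seed = NULL) {
  inj <- agreement_report(volumes$scaled_injected_ul, volumes$mwi_ul,
                          boot_B = boot_B, seed = seed)
  ct <- agreement_report(volumes$ct_scaled_ul, volumes$mwi_ul,
                         boot_B = if (boot_B > 0L) boot_B else 0L,
                         seed = if (is.null(seed)) NULL else seed + 10L)
  def <- bland_altman_percent(volumes$scaled_injected_ul,
                              volumes$ct_scaled_ul)
  n <- nrow(repeats)
  rp <- data.frame(
    specimen = repeats$specimen,
    cv_percent = 100 * repeats$sd_ul / repeats$mean_ul,
    ci_lo_ul = repeats$mean_ul -
      stats::qt(0.975, 3) * repeats$sd_ul / sqrt(4),
    ci_hi_ul = repeats$mean_ul +
      stats::qt(0.975, 3) * repeats$sd_ul / sqrt(4))
  attr(rp, "mean_cv_percent") <- mean(rp$cv_percent)
  list(injected = inj, ct = ct,
       ct_deficit = list(bias = def$bias, sd = def$sd),
       repeatability = rp)
}

#' Run the full pipeline on a synthetic study
#'
#' Generates (or accepts) a synthetic study, estimates every specimen's
#' fluid volume from its pre/post grids, derives the CT reference volumes,
#' depth-rescales references, and assembles the repeatability and agreement
#' panels -- the synthetic analogue of the study's Tables 1 and 2.
#'
#' @param config A [study_config()]; ignored when `study` is supplied.
#' @param study Optionally a pre-generated [generate_study()] result.
#' @param use_ct Derive CT reference volumes (requires CT in the study)?
#' @return List with `volumes` (per-specimen table: truth, CT, microwave),
#'   `estimates` (list of [volume_estimate()]s), `agreement_injected`,
#'   `agreement_ct` (when CT present), and `manifest` (config echo, seeds,
#'   thresholds, per-stage timings).
#' @export
run_pipeline <- function(config = NULL, study = NULL, use_ct = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(study)) {
    if (is.null(config)) stop("supply a study_config or a generated study")
    study <- generate_study(config)
  }
  config <- study$config
  kernel <- study$kernel
  profile <- study$profile
  t_sim <- proc.time()[["elapsed"]]
  ests <- lapply(study$specimens, function(sp)
    estimate_specimen_volume(sp$pre_grids, sp$post_grids, kernel,
                             profile = profile,
                             eps_fluid = config$eps_fluid,
                             pixel_size_mm = config$pixel_size_mm))
  t_vol <- proc.time()[["elapsed"]]
  gt <- study$ground_truth
  vols <- data.frame(
    id = gt$id, n_holes = gt$n_holes, injected_ul = gt$injected_ul,
    scaled_injected_ul = gt$scaled_ul,
    mwi_ul = vapply(ests, `[[`, 0, "mean_ul"),
    mwi_cv_percent = vapply(ests, `[[`, 0, "cv_percent"))
  has_ct <- use_ct && !is.null(study$specimens[[1L]]$ct_post)
  if (has_ct) {
    vols$ct_ul <- vapply(study$specimens, function(sp) {
      layout <- sp$phantom$holes[, c("x_mm", "y_mm")]
      ct_volume_from_positives(count_positive_holes(sp$ct_post, layout))
    }, 0)
    vols$ct_scaled_ul <- depth_rescale(vols$ct_ul, profile)
  }
  t_ct <- proc.time()[["elapsed"]]
  out <- list(volumes = vols, estimates = ests)
  if (nrow(vols) >= 4L) {  # the agreement battery needs n >= 4 pairs
    out$agreement_injected <- agreement_report(vols$scaled_injected_ul,
                                               vols$mwi_ul)
    if (has_ct)
      out$agreement_ct <- agreement_report(vols$ct_scaled_ul, vols$mwi_ul)
  }
  out$manifest <- list(
    seed = config$seed, n_specimens = nrow(vols),
    noise_sd = config$noise_sd, gain_cv = config$gain_cv,
    eps_fluid = config$eps_fluid, pixel_size_mm = config$pixel_size_mm,
    kernel_sigma_mm = config$kernel_sigma_mm,
    depth_delta_mm = profile$delta_mm,
    roi_k = 3, roi_min_pixels = 4,
    timings_s = c(simulate = t_sim - t0, volumetry = t_vol - t_sim,
                  ct = t_ct - t_vol))
  out
}

#' Write a generated study to a directory tree
#'
#' `study/<id>/{pre|post}/rot<deg>/grid.csv` for the coarse grids, NIfTI CT
#' volumes when present, plus `metadata.csv` and `ground_truth.csv`.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created; must not already contain a study).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mwi_study"))
  if (dir.exists(file.path(dir, "ground_truth.csv")))
    stop("target directory already holds a study")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(dir, recursive = TRUE))
  for (sp in study$specimens) {
    for (cond in c("pre", "post")) {
      grids <- sp[[paste0(cond, "_grids")]]
      for (g in grids) {
        d <- file.path(dir, sp$id, cond, sprintf("rot%03d", g$rotation_deg))
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        utils::write.table(g$values, file.path(d, "grid.csv"), sep = ",",
                           row.names = FALSE, col.names = FALSE)
      }
      ct <- sp[[paste0("ct_", cond)]]
      if (!is.null(ct))
        write_ct_nifti(ct, file.path(dir, sp$id,
                                     sprintf("ct_%s.nii.gz", cond)))
    }
  }
  meta <- do.call(rbind, lapply(study$specimens, function(sp)
    cbind(specimen = sp$id, sp$phantom$holes)))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(study$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  ok <- TRUE
  invisible(dir)
}
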