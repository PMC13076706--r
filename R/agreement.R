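# Method-comparison battery: Pearson with Fisher/bootstrap CIs, Lin's CCC
# with bias-correction factor, Bland-Altman on percent differences, Deming
# regression, paired t and exact Wilcoxon, MAPE, and ICC(2,1).
#
# Conventions that matter for reproducing the study panel: all second
# moments are SAMPLE (n-1) moments, and percent differences use the
# REFERENCE as denominator (not the pair mean).

#' Pearson correlation with Fisher confidence interval
#'
#' `CI = tanh(atanh(r) +/- 1.96 / sqrt(n - 3))`; two-sided p from
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` df.
#'
#' @param x,y Numeric vectors, n >= 4, non-degenerate.
#' @return List with `r`, `ci` (length 2), `p`.
#' @export
pearson_fisher <- function(x, y) {
  n <- length(x)
  if (n < 4L || length(y) != n) stop("need aligned vectors with n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- stats::cor(x, y)
  ci <- tanh(atanh(r) + c(-1, 1) * 1.96 / sqrt(n - 3))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, ci = ci, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with sample
#' (n-1) moments; the bias-correction (accuracy) factor is `Cb = CCC / r`.
#'
#' @param x,y Numeric vectors, n >= 3.
#' @return List with `ccc`, `cb`.
#' @export
lins_ccc <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need aligned vectors with n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ccc <- 2 * stats::cov(x, y) /
    (stats::var(x) + stats::var(y) + (mean(x) - mean(y))^2)
  list(ccc = ccc, cb = ccc / stats::cor(x, y))
}

#' Bland-Altman analysis on percent differences
#'
#' Differences `d_i = 100 (est_i - ref_i) / ref_i` (reference denominator);
#' `LoA = bias +/- 1.96 SD`.
#'
#' @param reference Positive reference values.
#' @param estimate Estimates, same length.
#' @return List with `bias`, `sd`, `loa` (length 2), `d` (the percent
#'   differences).
#' @export
bland_altman_percent <- function(reference, estimate) {
  if (any(reference <= 0)) stop("reference values must be > 0")
  if (length(reference) != length(estimate)) stop("length mismatch")
  d <- 100 * (estimate - reference) / reference
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, sd = s, loa = bias + c(-1, 1) * 1.96 * s, d = d)
}

#' Deming regression
#'
#' Errors-in-both-variables fit with error-variance ratio `lambda`
#' (`lambda = 1` is orthogonal regression):
#' `slope = (s_y^2 - lambda s_x^2 + sqrt((s_y^2 - lambda s_x^2)^2 +
#' 4 lambda s_xy^2)) / (2 s_xy)`, sample moments;
#' `intercept = mean(y) - slope mean(x)`.
#'
#' @param x,y Numeric vectors, n >= 3.
#' @param lambda_ratio Error-variance ratio (default 1).
#' @return List with `slope`, `intercept`.
#' @export
deming <- function(x, y, lambda_ratio = 1) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need aligned vectors with n >= 3")
  sxy <- stats::cov(x, y)
  if (sxy == 0) stop("zero covariance: Deming slope undefined")
  sx2 <- stats::var(x); sy2 <- stats::var(y)
  slope <- (sy2 - lambda_ratio * sx2 +
              sqrt((sy2 - lambda_ratio * sx2)^2 + 4 * lambda_ratio * sxy^2)) /
    (2 * sxy)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Exact null distribution of the Wilcoxon signed-rank statistic by full
# enumeration of the 2^n sign assignments; beyond n = 16 the exact
# signed-rank distribution (untied) or the normal approximation is used.
signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (!n) stop("all-zero differences: Wilcoxon undefined")
  if (n > 16L) {
    rk <- rank(abs(d))
    if (!anyDuplicated(abs(d))) {
      v <- sum(rk[d > 0])
      return(min(1, 2 * min(stats::psignrank(v, n),
                            1 - stats::psignrank(v - 1, n))))
    }
    return(stats::wilcox.test(d, exact = FALSE)$p.value)
  }
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_null <- as.numeric(signs %*% rk)
  p_le <- mean(w_null <= w_obs + 1e-9)
  p_ge <- mean(w_null >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

#' Paired-difference tests
#'
#' Paired Student t-test and exact two-sided Wilcoxon signed-rank test
#' (full enumeration of sign assignments) on `d = y - x`.
#'
#' @param x,y Numeric vectors, n >= 3.
#' @return List with `t`, `df`, `p_t`, `p_wilcoxon`, `mean_diff`.
#' @export
paired_tests <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need aligned vectors with n >= 3")
  d <- y - x
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_t = tt$p.value, p_wilcoxon = signed_rank_exact_p(d),
       mean_diff = mean(d))
}

#' Mean absolute percent error
#'
#' @param reference Positive reference values.
#' @param estimate Estimates, same length.
#' @return MAPE in percent.
#' @export
mape <- function(reference, estimate) {
  if (any(reference <= 0)) stop("reference values must be > 0")
  mean(100 * abs(estimate - reference) / reference)
}

#' Percentile bootstrap confidence interval for a paired statistic
#'
#' Resamples specimens (pairs) with replacement and returns the 2.5/97.5
#' percentiles of the statistic over `B` resamples.
#'
#' @param statistic Function of `(x, y)` returning a scalar.
#' @param x,y Paired numeric vectors.
#' @param B Number of resamples (default 10000).
#' @param seed Mandatory integer seed.
#' @return List with `ci` (length 2) and `n_failed`.
#' @export
bootstrap_ci <- function(statistic, x, y, B = 10000L, seed) {
  if (missing(seed)) stop("a seed is mandatory for bootstrap resampling")
  n <- length(x)
  set.seed(seed)
  vals <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    vals[b] <- tryCatch(suppressWarnings(statistic(x[idx], y[idx])),
                        error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(vals))
  if (n_failed > B / 2)
    stop("statistic failed on more than half of the bootstrap resamples")
  list(ci = unname(stats::quantile(vals, c(0.025, 0.975), na.rm = TRUE)),
       n_failed = n_failed)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measurement
#'
#' `ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n)` from the
#' two-way ANOVA of a complete specimens-by-raters (rotations) matrix.
#'
#' @param m Numeric matrix, rows = specimens (n >= 2), columns = repeated
#'   measurements (k >= 2), complete.
#' @return ICC(2,1) value.
#' @export
icc_2_1 <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need >= 2 rows and >= 2 columns")
  if (any(!is.finite(m))) stop("matrix must be complete")
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m); col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n
  if (denom <= 0) stop("no between-specimen variance: ICC undefined")
  (ms_r - ms_e) / denom
}

#' Full agreement panel between a reference and an estimate
#'
#' Assembles the complete method-comparison battery used for the study
#' tables; bootstrap CIs are included when `boot_B > 0`.
#'
#' @param reference,estimate Paired positive volume vectors (uL).
#' @param boot_B Bootstrap resamples for CIs (0 disables).
#' @param seed Seed for the bootstrap (required when `boot_B > 0`).
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(reference, estimate, boot_B = 0L, seed = NULL) {
  pf <- pearson_fisher(reference, estimate)
  cc <- lins_ccc(reference, estimate)
  ba <- bland_altman_percent(reference, estimate)
  dm <- deming(reference, estimate)
  pt <- tryCatch(paired_tests(reference, estimate),
                 error = function(e) list(t = NA_real_, df = NA_real_,
                                          p_t = NA_real_,
                                          p_wilcoxon = NA_real_,
                                          mean_diff = mean(estimate -
                                                             reference)))
  rep <- list(r = pf$r, r_fisher_ci = pf$ci, r_p = pf$p,
              ccc = cc$ccc, cb = cc$cb,
              bias_percent = ba$bias, sd_percent = ba$sd, loa_percent = ba$loa,
              mean_diff_ul = pt$mean_diff, t_stat = pt$t, t_df = pt$df,
              t_p = pt$p_t, wilcoxon_p = pt$p_wilcoxon,
              mape_percent = mape(reference, estimate),
              deming_slope = dm$slope, deming_intercept = dm$intercept)
  if (boot_B > 0L) {
    if (is.null(seed)) stop("seed required for bootstrap CIs")
    rep$r_boot_ci <- bootstrap_ci(function(a, b) stats::cor(a, b),
                                  reference, estimate, boot_B, seed)$ci
    rep$bias_boot_ci <- bootstrap_ci(
      function(a, b) mean(100 * (b - a) / a),
      reference, estimate, boot_B, seed + 1L)$ci
    rep$mean_diff_boot_ci <- bootstrap_ci(function(a, b) mean(b - a),
                                          reference, estimate, boot_B,
                                          seed + 2L)$ci
  }
  structure(rep, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report>\n  r = %.3f (Fisher CI %.2f..%.2f, p = %.3f)\n",
              x$r, x$r_fisher_ci[1L], x$r_fisher_ci[2L], x$r_p))
  cat(sprintf("  CCC = %.2f (Cb = %.2f)\n", x$ccc, x$cb))
  cat(sprintf("  Bland-Altman bias %+.1f%% (SD %.1f%%, LoA %.1f%%..%.1f%%)\n",
              x$bias_percent, x$sd_percent, x$loa_percent[1L],
              x$loa_percent[2L]))
  cat(sprintf("  mean diff %+.2f uL (t(%d) = %.2f, p = %.3f; Wilcoxon p = %.3f)\n",
              x$mean_diff_ul, x$t_df, x$t_stat, x$t_p, x$wilcoxon_p))
  cat(sprintf("  MAPE %.1f%%; Deming slope %.2f, intercept %.2f\n",
              x$mape_percent, x$deming_slope, x$deming_intercept))
  invisible(x)
}
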