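#' Intraclass correlation: two-way model, single measures, absolute agreement
#'
#' Decomposes a complete subjects-by-occasions matrix into row (subject),
#' column (occasion) and residual mean squares and returns the
#' single-measures absolute-agreement intraclass correlation
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' together with the F-test of H0: ICC = 0 (F = MS_R/MS_E on n-1 and
#' (n-1)(k-1) degrees of freedom, one-sided p) and an F-based confidence
#' interval (McGraw-Wong construction). The absolute-agreement form penalises
#' systematic occasion differences, not just inconsistency; the point
#' estimate is identical under the two-way mixed and two-way random readings
#' of the model. Estimates are not truncated: values below 0 are reported as
#' computed.
#'
#' @param m complete numeric matrix, subjects in rows (n >= 2), occasions in
#'   columns (k >= 2).
#' @param conf.level confidence level for the interval (default 0.95).
#' @return object of class `"icc_estimate"`: list with `icc`, `ci_low`,
#'   `ci_high`, `f_stat`, `df1`, `df2`, `p_value` (one-sided), the mean
#'   squares, `n_subjects`, `n_occasions` and `model_label`.
#' @seealso [within_subject_cv()], [reliability()]
#' @export
icc_absolute_agreement <- function(m, conf.level = 0.95) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("matrix must be complete (no missing cells)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L) stop("need at least 2 subjects")
  if (k < 2L) stop("need at least 2 occasions")
  grand <- mean(m)
  if (sum((m - grand)^2) == 0)
    stop("degenerate input: zero total variance")
  row_means <- rowMeans(m); col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- sum((m - outer(row_means, col_means, "+") + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  df1 <- n - 1L
  df2 <- (n - 1L) * (k - 1L)
  if (mse > 0) {
    f <- msr / mse
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    alpha <- 1 - conf.level
    fj <- msc / mse
    a <- k * icc * fj + n * (1 + (k - 1) * icc) - k * icc
    v <- ((k - 1) * (n - 1) * a^2) /
      ((n - 1) * k^2 * icc^2 * fj^2 + (n * (1 + (k - 1) * icc) - k * icc)^2)
    f_u <- stats::qf(1 - alpha / 2, n - 1, v)
    f_l <- stats::qf(1 - alpha / 2, v, n - 1)
    ci_low  <- n * (msr - f_u * mse) /
      (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci_high <- n * (f_l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_l * msr)
  } else {
    # perfect within-subject agreement: F degenerates
    f <- Inf; p <- 0; ci_low <- icc; ci_high <- icc
    warning("zero residual mean square; confidence interval collapsed to ",
            "the point estimate")
  }
  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 conf.level = conf.level,
                 f_stat = f, df1 = df1, df2 = df2, p_value = p,
                 ms = c(MSR = msr, MSC = msc, MSE = mse),
                 n_subjects = n, n_occasions = k,
                 model_label =
                   "two-way mixed, single measures, absolute agreement"),
            class = "icc_estimate")
}

#' Intraclass correlation: consistency form
#'
#' The companion single-measures consistency coefficient
#' (MS_R - MS_E) / (MS_R + (k-1) MS_E), insensitive to systematic occasion
#' shifts. Provided for comparison with the absolute-agreement form.
#'
#' @inheritParams icc_absolute_agreement
#' @return numeric scalar.
#' @export
icc_consistency <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 2L, k >= 2L, !anyNA(m))
  grand <- mean(m)
  row_means <- rowMeans(m); col_means <- colMeans(m)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  mse <- sum((m - outer(row_means, col_means, "+") + grand)^2) /
    ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

#' @export
print.icc_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("ICC (%s)\n", x$model_label))
  cat(sprintf("  ICC = %.*f, %d%% CI [%.*f, %.*f]\n", digits, x$icc,
              round(100 * x$conf.level), digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  F(%d, %d) = %.*f, one-sided p = %.3g (H0: ICC = 0)\n",
              x$df1, x$df2, digits, x$f_stat, x$p_value))
  cat(sprintf("  n = %d subjects, k = %d occasions\n",
              x$n_subjects, x$n_occasions))
  invisible(x)
}

#' Within-subject coefficient of variation
#'
#' Absolute reliability of repeated measurements: per subject,
#' CV_i = 100 sd(x_i)/mean(x_i) (sample sd), summarised as the mean and sd of
#' the per-subject CVs. Must be computed on raw (not log) concentrations so
#' that percentages are meaningful.
#'
#' @param m complete positive matrix, subjects in rows, repeated measures in
#'   columns (raw scale).
#' @param pooled if `TRUE`, additionally return the pooled root-mean-square
#'   CV, `sqrt(mean(CV_i^2))`.
#' @return list with `cv_mean`, `cv_sd` (percent) and `per_subject`.
#' @export
within_subject_cv <- function(m, pooled = FALSE) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 1L, ncol(m) >= 2L, !anyNA(m))
  if (identical(attr(m, "scale"), "log"))
    stop("CV must be computed on the raw concentration scale")
  if (any(m <= 0)) stop("CV requires strictly positive values")
  per_subject <- 100 * apply(m, 1L, stats::sd) / rowMeans(m)
  out <- list(cv_mean = mean(per_subject),
              cv_sd = stats::sd(per_subject),
              per_subject = per_subject)
  if (pooled) out$cv_rms <- sqrt(mean(per_subject^2))
  out
}
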