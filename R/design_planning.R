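#' Measurements needed for a target reliability (Spearman-Brown)
#'
#' Inverts the Spearman-Brown prophecy formula: given the reliability of a
#' single measurement, how many parallel measurements must be averaged for
#' the mean to reach a target reliability?
#' \deqn{m = \frac{X(1 - ICC)}{ICC(1 - X)}}
#' The result is left fractional; whether to round up is the consumer's
#' decision.
#'
#' @param icc_observed single-measurement reliability, strictly in (0, 1).
#' @param icc_target target reliability of the averaged measure, strictly in
#'   (0, 1); may be a vector.
#' @return numeric vector of (possibly fractional) numbers of measurements.
#' @examples
#' samples_needed(0.23, c(0.80, 0.70, 0.50))
#' @export
samples_needed <- function(icc_observed, icc_target) {
  if (any(icc_observed <= 0 | icc_observed >= 1))
    stop("icc_observed must be strictly inside (0, 1)")
  if (any(icc_target <= 0 | icc_target >= 1))
    stop("icc_target must be strictly inside (0, 1)")
  icc_target * (1 - icc_observed) / (icc_observed * (1 - icc_target))
}

#' Reliability of an average of m measurements (Spearman-Brown)
#'
#' Forward form of the prophecy formula: the reliability of the mean of `m`
#' parallel measurements each with single-measure reliability `icc_single` is
#' m ICC / (1 + (m-1) ICC). Exact inverse of [samples_needed()].
#'
#' @param icc_single single-measurement reliability in (0, 1).
#' @param m number of averaged measurements, > 0 (fractional allowed;
#'   values below 1 project the reliability of a notional fraction of a
#'   measurement, making the function the exact inverse of
#'   [samples_needed()] on its whole domain).
#' @return reliability of the averaged measure.
#' @export
spearman_brown_average <- function(icc_single, m) {
  if (any(icc_single <= 0 | icc_single >= 1))
    stop("icc_single must be strictly inside (0, 1)")
  if (any(m <= 0)) stop("m must be positive")
  m * icc_single / (1 + (m - 1) * icc_single)
}

#' Spearman-Brown projection table
#'
#' Tabulates [samples_needed()] over a set of target reliabilities. The
#' default targets are the conventional fair (0.50), moderate (0.70) and good
#' (0.80) cut-offs.
#'
#' @param icc_observed single-measurement reliability in (0, 1).
#' @param targets target reliabilities.
#' @return data.frame of class `"sb_projection"` with columns `icc_observed`,
#'   `icc_target`, `samples_needed`.
#' @export
project_reliability <- function(icc_observed,
                                targets = c(0.80, 0.70, 0.50)) {
  out <- data.frame(icc_observed = icc_observed, icc_target = targets,
                    samples_needed = samples_needed(icc_observed, targets))
  class(out) <- c("sb_projection", "data.frame")
  out
}

#' @export
print.sb_projection <- function(x, ...) {
  cat(sprintf("Spearman-Brown projection from single-measure ICC = %.2f:\n",
              x$icc_observed[1L]))
  cat(sprintf("  target ICC %.2f: %6.2f samples per individual\n",
              x$icc_target, x$samples_needed), sep = "")
  invisible(x)
}

#' Attenuate a correlation for measurement unreliability
#'
#' The classical attenuation relation: a true correlation `r_true` between
#' two constructs is observed as
#' \deqn{r_{obs} = r_{true} \sqrt{ICC_x \, ICC_y}}
#' when the measurements of x and y have reliabilities `icc_x` and `icc_y`.
#'
#' @param r_true true correlation in \[-1, 1\].
#' @param icc_x reliability of the predictor measurement in \[0, 1\].
#' @param icc_y reliability of the outcome measurement in \[0, 1\]
#'   (default 1, a perfectly reliable outcome).
#' @return attenuated (observable) correlation.
#' @export
attenuate_correlation <- function(r_true, icc_x, icc_y = 1) {
  stopifnot(all(abs(r_true) <= 1), all(icc_x >= 0 & icc_x <= 1),
            all(icc_y >= 0 & icc_y <= 1))
  r_true * sqrt(icc_x * icc_y)
}

# Power of the two-tailed test of H0: rho = 0 at observed correlation r and
# sample size n, by the Fisher-z approximation. The small-sample bias term
# r/(2(n-1)) and the t-based critical correlation make the function agree
# with the standard correlation power calculator.
power_correlation <- function(n, r, alpha = 0.05, bias_correction = TRUE) {
  stopifnot(n >= 4)
  t_crit <- stats::qt(alpha / 2, df = n - 2, lower.tail = FALSE)
  r_crit <- sqrt(t_crit^2 / (t_crit^2 + n - 2))
  z_r <- atanh(r) + if (bias_correction) r / (2 * (n - 1)) else 0
  stats::pnorm((z_r - atanh(r_crit)) * sqrt(n - 3))
}

#' Sample size required to detect a correlation
#'
#' Smallest integer n (>= 4) whose achieved power reaches the target for a
#' two-tailed test of zero correlation at the given alpha, under the Fisher-z
#' power approximation with the r/(2(n-1)) small-sample bias term and a
#' critical correlation taken from the t distribution on n-2 df. The integer
#' is found by upward scan (power is monotone in n), avoiding the rounding
#' ambiguity of inverting the formula.
#'
#' @param r observable correlation, strictly in (0, 1); attenuate first via
#'   [attenuate_correlation()] if the measurements are unreliable.
#' @param alpha two-tailed significance level.
#' @param power target power.
#' @param bias_correction include the r/(2(n-1)) bias term (default `TRUE`);
#'   `FALSE` gives the plain Fisher-z variant.
#' @return integer sample size.
#' @examples
#' required_n_correlation(attenuate_correlation(0.5, icc_x = 0.30))
#' @export
required_n_correlation <- function(r, alpha = 0.05, power = 0.80,
                                   bias_correction = TRUE) {
  stopifnot(r > 0, r < 1, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- 4L
  while (power_correlation(n, r, alpha, bias_correction) < power) {
    n <- n + 1L
    if (n > 1e7L) stop("sample size search exceeded 1e7")
  }
  n
}

#' Required sample size over a reliability-by-effect-size grid
#'
#' Composes [attenuate_correlation()] and [required_n_correlation()] over a
#' grid of predictor reliabilities and true correlations, quantifying how
#' measurement unreliability inflates the sample needed to detect an
#' association. The outcome is assumed perfectly reliable unless `icc_y` is
#' lowered.
#'
#' @param icc_x vector of predictor reliabilities in (0, 1\].
#' @param r_true vector of true correlations in (0, 1).
#' @param alpha two-tailed significance level.
#' @param power target power.
#' @param icc_y outcome reliability (scalar, default 1).
#' @return data.frame of class `"power_plan"` with columns `icc_x`, `icc_y`,
#'   `r_true`, `r_observed`, `alpha`, `power`, `n_required`.
#' @examples
#' plan <- power_surface(icc_x = c(0.3, 0.6, 1), r_true = c(0.2, 0.35, 0.5))
#' plan
#' @export
power_surface <- function(icc_x, r_true, alpha = 0.05, power = 0.80,
                          icc_y = 1) {
  stopifnot(length(icc_x) >= 1L, length(r_true) >= 1L, length(icc_y) == 1L)
  grid <- expand.grid(icc_x = icc_x, r_true = r_true,
                      KEEP.OUT.ATTRS = FALSE)
  grid$icc_y <- icc_y
  grid$r_observed <- attenuate_correlation(grid$r_true, grid$icc_x, icc_y)
  grid$alpha <- alpha
  grid$power <- power
  grid$n_required <- vapply(grid$r_observed, required_n_correlation,
                            integer(1L), alpha = alpha, power = power)
  grid <- grid[c("icc_x", "icc_y", "r_true", "r_observed", "alpha", "power",
                 "n_required")]
  class(grid) <- c("power_plan", "data.frame")
  grid
}

#' @export
print.power_plan <- function(x, ...) {
  cat(sprintf("Correlation power plan (alpha = %.2g two-tailed, power = %.2g, outcome reliability %.2g):\n",
              x$alpha[1L], x$power[1L], x$icc_y[1L]))
  print(as.data.frame(x)[c("icc_x", "r_true", "r_observed", "n_required")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.power_plan <- function(x, log_n = TRUE, ...) {
  iccs <- sort(unique(x$icc_x))
  rs <- sort(unique(x$r_true))
  z <- matrix(NA_real_, length(iccs), length(rs))
  for (j in seq_along(rs))
    z[, j] <- x$n_required[order(x$icc_x)][x$r_true[order(x$icc_x)] == rs[j]]
  graphics::matplot(iccs, z, type = "b", pch = 19, lty = 1,
                    log = if (log_n) "y" else "",
                    xlab = "predictor reliability (ICC)",
                    ylab = "required sample size",
                    main = "Sample size vs measurement reliability", ...)
  graphics::legend("topright", legend = sprintf("r_true = %.2f", rs),
                   col = seq_along(rs), lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Write a planning report CSV
#'
#' Serialises a Spearman-Brown projection and/or a power plan to a single
#' long CSV (columns: section, icc_observed, icc_target, samples_needed,
#' icc_x, r_true, r_observed, n_required).
#'
#' @param projection an `sb_projection` (or `NULL`).
#' @param plan a `power_plan` (or `NULL`).
#' @param path output CSV path.
#' @return the combined data.frame, invisibly.
#' @export
planning_report <- function(projection = NULL, plan = NULL, path = NULL) {
  parts <- list()
  if (!is.null(projection))
    parts$projection <- data.frame(section = "spearman_brown",
                                   as.data.frame(projection),
                                   icc_x = NA, r_true = NA, r_observed = NA,
                                   n_required = NA)
  if (!is.null(plan))
    parts$plan <- data.frame(section = "power",
                             icc_observed = NA, icc_target = NA,
                             samples_needed = NA,
                             as.data.frame(plan)[c("icc_x", "r_true",
                                                   "r_observed",
                                                   "n_required")])
  df <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
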