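# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

cor_result <- function(method, estimate, ci_low = NA_real_,
                       ci_high = NA_real_, p_value = NA_real_,
                       bf01 = NA_real_, bf10 = NA_real_, label = NA_character_,
                       n, n_boot = NA_integer_, seed = NA_integer_) {
  structure(list(method = method, estimate = estimate, ci_low = ci_low,
                 ci_high = ci_high, p_value = p_value, bf01 = bf01,
                 bf10 = bf10, label = label, n = n, n_boot = n_boot,
                 seed = seed),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, digits = 3, ...) {
  cat(sprintf("Correlation (%s): r = %.*f, N = %d\n", x$method, digits,
              x$estimate, x$n))
  if (!is.na(x$ci_low))
    cat(sprintf("  bootstrap 95%% CI [%.*f, %.*f] (%d resamples, seed %d)\n",
                digits, x$ci_low, digits, x$ci_high, x$n_boot, x$seed))
  if (!is.na(x$p_value)) cat(sprintf("  p = %.3g (two-tailed)\n", x$p_value))
  if (!is.na(x$bf01))
    cat(sprintf("  BF01 = %.3g (BF10 = %.3g): %s\n", x$bf01, x$bf10, x$label))
  invisible(x)
}

#' Pearson correlation with percentile bootstrap interval
#'
#' Point estimate on the full sample, 95% percentile interval over paired
#' resamples, and the two-tailed parametric p-value from the t distribution
#' on n - 2 df. The bootstrap seed is fixed and recorded so results are
#' reproducible.
#'
#' @param x,y equal-length numeric vectors (n >= 4).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed RNG seed for the resampling (recorded in the result).
#' @param conf.level bootstrap interval level.
#' @return a `cor_result`.
#' @export
pearson_bootstrap <- function(x, y, n_boot = 1000L, seed = 1L,
                              conf.level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 4L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  n <- length(x)
  r <- stats::cor(x, y)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(t_stat), n - 2, lower.tail = FALSE)
  boot_r <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) NA_real_
      else stats::cor(x[idx], y[idx])
    }, numeric(1L))
  })
  alpha <- 1 - conf.level
  ci <- stats::quantile(boot_r, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                        names = FALSE)
  cor_result("pearson_bootstrap", estimate = r, ci_low = ci[1L],
             ci_high = ci[2L], p_value = p, n = n,
             n_boot = as.integer(n_boot), seed = as.integer(seed))
}

#' Multilevel (repeated-measures) correlation
#'
#' The common within-subject association across repeated observations,
#' treating participant as a random (intercept) effect: both variables are
#' centred on their subject means and the residuals are correlated, with
#' error df = N - n_subjects - 1. This removes between-subject variation, so
#' the estimate is invariant to adding arbitrary per-subject constants.
#' Subjects with fewer than 2 observations carry no within-subject
#' information and are dropped.
#'
#' @param x,y equal-length numeric vectors.
#' @param subject subject labels aligned with `x` and `y`.
#' @return a `cor_result` (method `"multilevel"`).
#' @export
multilevel_correlation <- function(x, y, subject) {
  stopifnot(length(x) == length(y), length(x) == length(subject))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]; subject <- as.character(subject)[keep]
  counts <- table(subject)
  retained <- names(counts)[counts >= 2L]
  if (length(retained) < 2L)
    stop("need at least 2 subjects with >= 2 observations each")
  keep <- subject %in% retained
  x <- x[keep]; y <- y[keep]; subject <- subject[keep]
  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  if (stats::sd(xc) == 0 || stats::sd(yc) == 0)
    stop("undefined within-subject correlation: no within-subject variance")
  r <- stats::cor(xc, yc)
  df <- length(x) - length(retained) - 1L
  t_stat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  cor_result("multilevel", estimate = r, p_value = p, n = length(x))
}

# Gauss hypergeometric 2F1(a, b; c; z) by its power series (|z| < 1; the
# correlation likelihood only needs z = (1 + rho*r)/2 with c ~ n, where the
# series converges quickly).
hyp2f1 <- function(a, b, cc, z) {
  term <- 1; s <- 1
  for (k in 0:5000) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * z
    s <- s + term
    if (abs(term) < 1e-14 * abs(s)) return(s)
  }
  stop("hypergeometric series failed to converge (z = ", z, ")")
}

# Log integrated likelihood of rho given a sample correlation r at size n
# (Jeffreys' exact form; nuisance means/variances integrated out), up to a
# rho-free constant.
log_cor_likelihood <- function(rho, r, n) {
  (n - 1) / 2 * log1p(-rho^2) - (2 * n - 3) / 2 * log1p(-rho * r) +
    log(hyp2f1(0.5, 0.5, (2 * n - 1) / 2, (1 + rho * r) / 2))
}

#' Bayes factor for a Pearson correlation
#'
#' Evidence for H0: rho = 0 against H1: rho distributed as a stretched beta
#' on (-1, 1) centred at zero with width parameter `prior_width` (width 1 is
#' the uniform prior). The marginal likelihood under H1 is obtained by
#' numerical integration of the exact integrated correlation likelihood over
#' the prior; `bf01` is reported as evidence favouring the null (the
#' reciprocal `bf10` is also returned), with a verbal label from
#' [interpret_bf()].
#'
#' @param x,y equal-length numeric vectors (n >= 4).
#' @param prior_width width of the stretched beta prior (shape
#'   `1/prior_width` on both sides); larger widths concentrate mass near
#'   |rho| = 1.
#' @return a `cor_result` with `bf01`, `bf10` and `label` filled in.
#' @export
bayes_correlation <- function(x, y, prior_width = 1) {
  stopifnot(length(x) == length(y), length(x) >= 4L, prior_width > 0)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  n <- length(x)
  r <- stats::cor(x, y)
  shape <- 1 / prior_width
  log_f <- function(rho)
    vapply(rho, function(p)
      log_cor_likelihood(p, r, n) - log_cor_likelihood(0, r, n) +
        stats::dbeta((p + 1) / 2, shape, shape, log = TRUE) + log(0.5),
      numeric(1L))
  # factor out the integrand's peak so near-degenerate data (|r| close to 1,
  # a spike at the boundary) stay within floating-point range
  log_peak <- max(log_f(seq(-1 + 1e-9, 1 - 1e-9, length.out = 201L)))
  scaled <- function(rho) exp(log_f(rho) - log_peak)
  int <- tryCatch(
    stats::integrate(scaled, -1, 1, rel.tol = 1e-9,
                     subdivisions = 500L)$value,
    error = function(e) {
      # trapezoidal fallback on a fine grid
      grid <- seq(-1 + 1e-9, 1 - 1e-9, length.out = 20001L)
      v <- scaled(grid)
      if (any(!is.finite(v)))
        stop("Bayes factor integration failed (r = ", signif(r, 3),
             ", n = ", n, "): non-finite integrand", call. = FALSE)
      sum((v[-1L] + v[-length(v)]) / 2 * diff(grid))
    })
  bf10 <- exp(log_peak + log(int))
  bf01 <- 1 / bf10
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  cor_result("bayes", estimate = r,
             p_value = 2 * stats::pt(abs(t_stat), n - 2, lower.tail = FALSE),
             bf01 = bf01, bf10 = bf10, label = interpret_bf(bf01), n = n)
}

#' Verbal interpretation of a null-favouring Bayes factor
#'
#' Maps `bf01` (evidence for the null over the alternative) onto the
#' conventional evidence categories: < 1/10 strong and \[1/10, 1/3) moderate
#' evidence for the alternative, \[1/3, 1\] anecdotal alternative, (1, 3\]
#' anecdotal null, (3, 10\] moderate null, > 10 strong null. Exact boundary
#' values take the milder adjacent label (so bf01 = 3 is "anecdotal", 10 is
#' "moderate").
#'
#' @param bf01 positive Bayes factor favouring the null.
#' @return character label.
#' @examples
#' interpret_bf(3.02)
#' @export
interpret_bf <- function(bf01) {
  stopifnot(length(bf01) == 1L, is.finite(bf01) || bf01 == Inf)
  if (bf01 <= 0) stop("bf01 must be positive")
  if (bf01 < 1 / 10) "strong evidence for alternative hypothesis"
  else if (bf01 < 1 / 3) "moderate evidence for alternative hypothesis"
  else if (bf01 <= 1) "anecdotal evidence for alternative hypothesis"
  else if (bf01 <= 3) "anecdotal evidence for the null hypothesis"
  else if (bf01 <= 10) "moderate evidence for the null hypothesis"
  else "strong evidence for the null hypothesis"
}

#' Write an association report CSV
#'
#' One row per correlation analysis: method, n, estimate, bootstrap CI,
#' p-value, Bayes factors, label, seed and resample count.
#'
#' @param results list of `cor_result` objects (possibly named).
#' @param path output CSV path.
#' @return the report data.frame, invisibly.
#' @export
association_report <- function(results, path = NULL) {
  if (inherits(results, "cor_result")) results <- list(results)
  df <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(analysis = names(results)[i] %||% as.character(i),
               method = r$method, n = r$n, estimate = r$estimate,
               ci_low = r$ci_low, ci_high = r$ci_high, p = r$p_value,
               bf01 = r$bf01, bf10 = r$bf10, label = r$label,
               seed = r$seed, n_boot = r$n_boot)
  }))
  rownames(df) <- NULL
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
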