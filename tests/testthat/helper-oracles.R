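# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: sums of squares by explicit loops, power by
# Monte-Carlo simulation, Bayes factors by Monte-Carlo prior integration.

# Single-measures absolute-agreement ICC from first principles: cell-level
# sums of squares accumulated by explicit loops over the two-way layout.
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ssr <- 0; ssc <- 0; sse <- 0
  row_means <- numeric(n); col_means <- numeric(k)
  for (i in 1:n) row_means[i] <- mean(m[i, ])
  for (j in 1:k) col_means[j] <- mean(m[, j])
  for (i in 1:n) ssr <- ssr + k * (row_means[i] - grand)^2
  for (j in 1:k) ssc <- ssc + n * (col_means[j] - grand)^2
  for (i in 1:n) for (j in 1:k)
    sse <- sse + (m[i, j] - row_means[i] - col_means[j] + grand)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# One-way repeated-measures F from an explicit SS decomposition.
rm_anova_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- 0; ss_err <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (mean(m[, j]) - grand)^2
  for (i in 1:n) for (j in 1:k)
    ss_err <- ss_err + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
  (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
}

# Monte-Carlo power of the two-tailed correlation test at sample size n,
# chunked to bound memory.
mc_power_correlation <- function(n, rho, alpha = 0.05, n_rep = 50000L,
                                 chunk = 5000L) {
  r_crit <- {
    t_crit <- qt(alpha / 2, n - 2, lower.tail = FALSE)
    sqrt(t_crit^2 / (t_crit^2 + n - 2))
  }
  hits <- 0L; done <- 0L
  while (done < n_rep) {
    b <- min(chunk, n_rep - done)
    x <- matrix(rnorm(n * b), n, b)
    y <- rho * x + sqrt(1 - rho^2) * matrix(rnorm(n * b), n, b)
    xc <- sweep(x, 2L, colMeans(x)); yc <- sweep(y, 2L, colMeans(y))
    r <- colSums(xc * yc) / sqrt(colSums(xc^2) * colSums(yc^2))
    hits <- hits + sum(abs(r) > r_crit)
    done <- done + b
  }
  hits / n_rep
}

# Monte-Carlo marginal-likelihood ratio for the correlation Bayes factor:
# average the likelihood ratio over draws from the stretched beta prior.
mc_bf10 <- function(r, n, width = 1, n_draw = 200000L) {
  rho <- 2 * rbeta(n_draw, 1 / width, 1 / width) - 1
  loglr <- (n - 1) / 2 * log1p(-rho^2) - (2 * n - 3) / 2 * log1p(-rho * r) +
    vapply(rho, function(p)
      log(hormrel:::hyp2f1(0.5, 0.5, (2 * n - 1) / 2, (1 + p * r) / 2)),
      numeric(1)) -
    log(hormrel:::hyp2f1(0.5, 0.5, (2 * n - 1) / 2, 0.5))
  mean(exp(loglr))
}

# Small dataset-shaped table used by data-model tests.
make_test_table <- function() {
  grid <- expand.grid(subject_id = sprintf("S%d", 1:6), visit = 1:4,
                      stringsAsFactors = FALSE)
  set.seed(42)
  grid$fluid <- "plasma"
  grid$time_point <- "baseline"
  grid$treatment <- "none"
  grid$concentration_pg_ml <- round(rlnorm(nrow(grid), log(4), 0.5), 3)
  grid$visit_date_offset_days <- (grid$visit - 1L) * 7
  sample_table(grid, dataset = "unit-test")
}
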