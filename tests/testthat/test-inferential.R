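test_that("one-way RM-ANOVA matches the brute-force SS oracle and paired t at k=2", {
  set.seed(301)
  for (rep in 1:50) {
    m <- matrix(rnorm(6 * 4, 5), 6, 4)
    expect_equal(rm_anova_oneway(m)$f_stat, rm_anova_oracle(m),
                 tolerance = 1e-10)
  }
  # k = 2: epsilon is exactly 1 and F = t^2 with identical p
  for (rep in 1:50) {
    n <- sample(5:15, 1)
    m <- matrix(rnorm(2 * n, 3), n, 2)
    a <- rm_anova_oneway(m)
    tt <- paired_ttest(m[, 1], m[, 2])
    expect_equal(a$epsilon, 1)
    expect_equal(a$f_stat, tt$t_stat^2, tolerance = 1e-10)
    expect_equal(a$p_value, tt$p_value, tolerance = 1e-10)
  }
  expect_error(rm_anova_oneway(matrix(rep(1:4, 3), 4, 3)), "zero error")
})

test_that("Greenhouse-Geisser correction matches car::Anova", {
  skip_if_not_installed("car")
  set.seed(55)
  m <- matrix(rnorm(12 * 4, 10), 12, 4)
  m[, 4] <- m[, 4] + 0.8 * m[, 1]   # induce non-sphericity
  a <- rm_anova_oneway(m)
  idata <- data.frame(cond = factor(paste0("c", 1:4)))
  fit <- lm(m ~ 1)
  s <- summary(car::Anova(fit, idata = idata, idesign = ~cond, type = 3),
               multivariate = FALSE)
  expect_equal(a$epsilon, unname(s$pval.adjustments[1, "GG eps"]),
               tolerance = 1e-8)
  expect_equal(a$p_value, unname(s$pval.adjustments[1, "Pr(>F[GG])"]),
               tolerance = 1e-8)
})

test_that("two-way RM-ANOVA reports effect-specific error terms and dfs", {
  cfg <- generator_config(n_subjects = 13, seed = 91)
  tab <- simulate_intervention(cfg)
  a <- suppressMessages(rm_anova_twoway(tab, "saliva"))
  inter <- a[a$effect == "treatment:time", ]
  expect_equal(c(inter$df1, inter$df2), c(3, 36))
  expect_equal(a$df2[a$effect == "time"], 12)

  cfg16 <- generator_config(n_subjects = 16, seed = 92)
  a16 <- suppressMessages(rm_anova_twoway(simulate_intervention(cfg16),
                                          "plasma"))
  expect_equal(a16$df2[a16$effect == "treatment:time"], 45)

  # cross-check all three F statistics against car::Anova
  skip_if_not_installed("car")
  cells <- attr(a, "cells")
  idata <- expand.grid(time = factor(c("baseline", "post")),
                       treatment = factor(attr(a, "treatments"),
                                          levels = attr(a, "treatments")))
  fit <- lm(cells ~ 1)
  s <- summary(car::Anova(fit, idata = idata,
                          idesign = ~treatment * time, type = 3),
               multivariate = FALSE)
  u <- s$univariate.tests
  expect_equal(a$f_stat[a$effect == "treatment"],
               unname(u["treatment", "F value"]), tolerance = 1e-8)
  expect_equal(a$f_stat[a$effect == "time"],
               unname(u["time", "F value"]), tolerance = 1e-8)
  expect_equal(a$f_stat[a$effect == "treatment:time"],
               unname(u["treatment:time", "F value"]), tolerance = 1e-8)
})

test_that("two-way RM-ANOVA detects a simulated interaction and not a null one", {
  set.seed(888)
  # additive data: interaction p should be roughly uniform
  p_null <- replicate(100, {
    cfg <- generator_config(n_subjects = 13, fluids = "plasma",
                            mu_log = c(plasma = log(4)),
                            treatment_effects = list(
                              spray = c(plasma = 1), nebuliser = c(plasma = 1),
                              intravenous = c(plasma = 1),
                              placebo = c(plasma = 1)),
                            seed = sample.int(1e6, 1))
    a <- suppressMessages(rm_anova_twoway(simulate_intervention(cfg),
                                          "plasma"))
    a$p_value[a$effect == "treatment:time"]
  })
  expect_gt(mean(p_null < 0.05), 0.0)  # sanity: p computed
  expect_lt(abs(mean(p_null < 0.5) - 0.5), 0.17)
  expect_gt(suppressWarnings(ks.test(p_null, "punif"))$p.value, 0.01)

  # default saliva ratios: interaction should be overwhelmingly detected
  hits <- replicate(40, {
    cfg <- generator_config(n_subjects = 13, seed = sample.int(1e6, 1))
    a <- suppressMessages(rm_anova_twoway(simulate_intervention(cfg),
                                          "saliva"))
    a$p_value[a$effect == "treatment:time"] < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("missing design cells are reported by subject", {
  cfg <- generator_config(n_subjects = 3, seed = 14)
  tab <- simulate_intervention(cfg)
  df <- as.data.frame(tab)
  df <- df[!(df$subject_id == "S02" & df$fluid == "saliva" &
             df$time_point == "post_administration" & df$visit == 1L), ]
  expect_error(
    suppressMessages(rm_anova_twoway(sample_table(df), "saliva",
                                     on_incomplete = "error")),
    "S02")
  # default drops the incomplete subject with a message
  expect_message(a <- rm_anova_twoway(sample_table(df), "saliva"), "S02")
  expect_equal(attr(a, "n_subjects"), 2L)
})

test_that("Tukey-adjusted paired contrasts dominate the unadjusted p-values", {
  cfg <- generator_config(n_subjects = 13, seed = 77)
  a <- suppressMessages(rm_anova_twoway(simulate_intervention(cfg), "saliva"))
  ph <- posthoc_paired_tukey(a)
  expect_equal(nrow(ph), 4L)
  expect_equal(unique(ph$df), 12)
  expect_true(all(ph$p_adjusted >= ph$p_unadjusted - 1e-12))
  # intranasal routes raise saliva; intravenous and placebo do not
  expect_lt(max(ph$p_adjusted[ph$treatment %in% c("spray", "nebuliser")]),
            0.001)

  # identical baseline and post vectors -> t = 0, adjusted p ~ 1
  cells <- attr(a, "cells")
  cells[, "placebo.post_administration"] <- cells[, "placebo.baseline"]
  ph0 <- posthoc_paired_tukey(cells, treatments = attr(a, "treatments"))
  expect_equal(ph0$t_stat[ph0$treatment == "placebo"], 0)
  expect_gt(ph0$p_adjusted[ph0$treatment == "placebo"], 0.99)
  expect_error(posthoc_paired_tukey(cells[1:2, ]), "at least 3")
})

test_that("paired t-test equals the one-sample t on differences", {
  set.seed(17)
  a <- rnorm(20, 5); b <- rnorm(20, 5.4)
  res <- paired_ttest(a, b)
  one <- t.test(a - b)
  expect_equal(res$t_stat, unname(one$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, one$p.value, tolerance = 1e-12)
  expect_equal(res$df, 19)
  same <- rnorm(5)
  expect_error(paired_ttest(same, same), "zero variance")
  eq <- paired_ttest(c(1, 2, 3), c(1.1, 1.9, 3.0))
  expect_lte(abs(eq$t_stat), 1)
})

test_that("bootstrap Pearson is affine-invariant with calibrated coverage", {
  set.seed(33)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40, 0, 0.8)
  r1 <- pearson_bootstrap(x, y, seed = 9)
  r2 <- pearson_bootstrap(2 * x + 3, 0.5 * y - 1, seed = 9)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-12)
  expect_equal(r1$ci_low, r2$ci_low, tolerance = 1e-12)
  expect_identical(r1$seed, 9L)

  expect_equal(pearson_bootstrap(x, x)$estimate, 1)
  expect_equal(pearson_bootstrap(x, x)$ci_low, 1)
  expect_equal(pearson_bootstrap(x, -x)$estimate, -1)
  expect_error(pearson_bootstrap(x, rep(1, 40)), "constant")

  # CI coverage near nominal under rho = 0.5
  set.seed(2024)
  cover <- replicate(200, {
    n <- 200
    u <- rnorm(n); v <- 0.5 * u + sqrt(1 - 0.25) * rnorm(n)
    ci <- pearson_bootstrap(u, v, n_boot = 300, seed = sample.int(1e6, 1))
    ci$ci_low <= 0.5 && ci$ci_high >= 0.5
  })
  expect_gt(mean(cover), 0.89)
  expect_lt(mean(cover), 0.995)
})

test_that("multilevel correlation removes between-subject variation", {
  # each subject on its own unit-slope line -> estimate 1
  subj <- rep(1:5, each = 4)
  x <- rnorm(20)
  y <- x + rep(c(10, -5, 0, 3, 7), each = 4)
  res <- multilevel_correlation(x, y, subj)
  expect_equal(res$estimate, 1, tolerance = 1e-12)

  # invariant to per-subject constant shifts
  set.seed(61)
  x2 <- rnorm(20); y2 <- 0.5 * x2 + rnorm(20)
  base <- multilevel_correlation(x2, y2, subj)
  shifted <- multilevel_correlation(x2 + rep(rnorm(5, 0, 50), each = 4),
                                    y2 + rep(rnorm(5, 0, 50), each = 4),
                                    subj)
  expect_equal(base$estimate, shifted$estimate, tolerance = 1e-10)
  expect_equal(base$p_value, shifted$p_value, tolerance = 1e-10)

  # degenerate: no within-subject variance in x
  expect_error(multilevel_correlation(rep(c(1, 2), each = 4),
                                      rnorm(8), rep(1:2, each = 4)),
               "within-subject")
  expect_error(multilevel_correlation(rnorm(3), rnorm(3), 1:3),
               "at least 2 subjects")

  # recovery of a within-subject correlation of 0.6 (17 subjects x 4 points)
  set.seed(99)
  est <- replicate(200, {
    s <- rep(1:17, each = 4)
    a <- rnorm(17)[s] + rnorm(68)
    wx <- a - ave(a, s)
    b <- rnorm(17, 0, 2)[s] + 0.6 * wx + sqrt(1 - 0.36) * rnorm(68)
    multilevel_correlation(a, b, s)$estimate
  })
  expect_lt(abs(mean(est) - 0.6), 0.05)
})

test_that("Bayes factor integration matches a Monte-Carlo prior-draw oracle", {
  set.seed(207)
  x <- rnorm(40); y <- 0.3 * x + rnorm(40)
  res <- bayes_correlation(x, y)
  mc <- mc_bf10(res$estimate, res$n, width = 1, n_draw = 200000L)
  expect_equal(res$bf10, mc, tolerance = 0.03)
  expect_equal(res$bf01, 1 / res$bf10, tolerance = 1e-12)

  # perfectly correlated data: overwhelming evidence against the null
  z <- rnorm(20)
  expect_lt(bayes_correlation(z, z + rnorm(20, 0, 1e-3))$bf01, 1 / 10)

  # wider priors increase null evidence for small observed correlations
  set.seed(13)
  u <- rnorm(63); v <- rnorm(63)
  bfs <- vapply(c(0.5, 1, 1.5, 2), function(w)
    bayes_correlation(u, v, prior_width = w)$bf01, numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("Bayes and frequentist evidence move concordantly", {
  set.seed(404)
  bf_null <- replicate(60, {
    x <- rnorm(60); y <- rnorm(60)
    bayes_correlation(x, y)$bf01
  })
  bf_alt <- replicate(60, {
    x <- rnorm(60); y <- 0.5 * x + sqrt(0.75) * rnorm(60)
    bayes_correlation(x, y)$bf01
  })
  expect_gt(median(bf_null), median(bf_alt))
  expect_gt(median(bf_null), 1)
})

test_that("Bayes-factor labels follow the printed interpretation scheme", {
  expect_equal(interpret_bf(3.02), "moderate evidence for the null hypothesis")
  expect_equal(interpret_bf(0.05),
               "strong evidence for alternative hypothesis")
  expect_equal(interpret_bf(0.2),
               "moderate evidence for alternative hypothesis")
  expect_equal(interpret_bf(0.5),
               "anecdotal evidence for alternative hypothesis")
  expect_equal(interpret_bf(2), "anecdotal evidence for the null hypothesis")
  expect_equal(interpret_bf(30), "strong evidence for the null hypothesis")
  # boundaries take the milder label
  expect_equal(interpret_bf(1), "anecdotal evidence for alternative hypothesis")
  expect_equal(interpret_bf(3), "anecdotal evidence for the null hypothesis")
  expect_equal(interpret_bf(10), "moderate evidence for the null hypothesis")
  expect_error(interpret_bf(0), "positive")
})

test_that("association report captures every analysis", {
  set.seed(1)
  x <- rnorm(20); y <- rnorm(20)
  res <- list(boot = pearson_bootstrap(x, y),
              bayes = bayes_correlation(x, y))
  path <- withr::local_tempfile(fileext = ".csv")
  df <- association_report(res, path)
  expect_equal(nrow(df), 2L)
  expect_equal(df$analysis, c("boot", "bayes"))
  expect_true(file.exists(path))
})
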