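test_that("generator configuration validates components and derives the true ICC", {
  cfg <- generator_config()
  expect_equal(unname(cfg$icc_true["plasma"]),
               0.34^2 / (0.34^2 + 0.30^2 + 0.44^2))
  expect_error(generator_config(assay_cv = 12), "<= 10")
  expect_error(generator_config(sigma_between = -1), "sigma_between")
  expect_error(generator_config(fluids = "plasma", mu_log = c(saliva = 1)),
               "mu_log")
  expect_error(generator_config(sigma_between = 0, sigma_visit = 0,
                                sigma_within = 0), "zero")

  sig <- variance_components_for_icc(0.29, 0.63)
  expect_equal(unname(sig["sigma_between"]^2 / sum(sig^2)), 0.29,
               tolerance = 1e-12)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- generator_config(seed = 123)
  t1 <- simulate_baseline(cfg)
  t2 <- simulate_baseline(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  i1 <- simulate_intervention(cfg)
  i2 <- simulate_intervention(cfg)
  expect_identical(as.data.frame(i1), as.data.frame(i2))
  t3 <- simulate_baseline(generator_config(seed = 124))
  expect_false(identical(t3$concentration_pg_ml, t1$concentration_pg_ml))
  # the caller's RNG stream is untouched
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(simulate_baseline(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("degenerate variance components pin the downstream ICC", {
  # no visit or residual noise: subjects identical across visits -> ICC 1
  cfg1 <- generator_config(n_subjects = 12, sigma_visit = 0,
                           sigma_within = 0, assay_cv = 0, seed = 8,
                           fluids = "plasma", mu_log = c(plasma = log(4)))
  w <- suppressMessages(to_wide(simulate_baseline(cfg1), "plasma"))
  expect_equal(apply(w, 1, stats::sd), setNames(rep(0, 12), rownames(w)))
  expect_equal(suppressWarnings(icc_absolute_agreement(w))$icc, 1)

  # no subject effects: ICC near zero at large n
  cfg0 <- generator_config(n_subjects = 500, sigma_between = 0, seed = 9,
                           fluids = "plasma", mu_log = c(plasma = log(4)))
  fit0 <- suppressMessages(reliability(simulate_baseline(cfg0), "plasma"))
  expect_lt(abs(fit0$icc$icc), 0.05)
})

test_that("analytic true ICC matches the large-sample estimate", {
  cfg <- generator_config(n_subjects = 2000, fluids = "plasma",
                          mu_log = c(plasma = log(4)), seed = 303)
  fit <- suppressMessages(reliability(simulate_baseline(cfg), "plasma"))
  expect_lt(abs(fit$icc$icc - cfg$icc_true[["plasma"]]), 0.01)
})

test_that("dataset-shaped recovery: true ICC 0.29, n=16, k=4", {
  set.seed(71)
  sig <- variance_components_for_icc(0.29, 0.63)
  est <- replicate(300, {
    cfg <- generator_config(n_subjects = 16, n_visits = 4,
                            fluids = "plasma", mu_log = c(plasma = log(4)),
                            sigma_between = sig[["sigma_between"]],
                            sigma_visit = sig[["sigma_visit"]],
                            sigma_within = sig[["sigma_within"]],
                            assay_cv = 0, seed = sample.int(1e6, 1))
    suppressMessages(reliability(simulate_baseline(cfg), "plasma"))$icc$icc
  })
  expect_lt(abs(mean(est) - 0.29), 0.03)
})

test_that("detection-floor censoring removes values without altering the rest", {
  cfg_lo <- generator_config(n_subjects = 60, detection_floor = 0, seed = 44,
                             fluids = "plasma", mu_log = c(plasma = log(1.2)))
  cfg_hi <- generator_config(n_subjects = 60, detection_floor = 1, seed = 44,
                             fluids = "plasma", mu_log = c(plasma = log(1.2)))
  lo <- simulate_baseline(cfg_lo)$concentration_pg_ml
  hi <- simulate_baseline(cfg_hi)$concentration_pg_ml
  expect_gt(sum(is.na(hi)), 0)
  expect_identical(hi[!is.na(hi)], lo[!is.na(hi)])
  expect_true(all(lo[is.na(hi)] < 1))
})

test_that("cross-fluid correlation of subject effects is honoured", {
  cfg <- generator_config(n_subjects = 800, cross_fluid_rho = 0.8,
                          sigma_visit = 0.1, sigma_within = 0.1,
                          sigma_between = 0.5, seed = 21)
  tab <- simulate_baseline(cfg)
  ws <- suppressMessages(to_wide(tab, "saliva"))
  wp <- suppressMessages(to_wide(tab, "plasma"))
  common <- intersect(rownames(ws), rownames(wp))
  r <- cor(rowMeans(ws[common, ]), rowMeans(wp[common, ]))
  expect_gt(r, 0.6)
  cfg0 <- generator_config(n_subjects = 800, cross_fluid_rho = 0,
                           sigma_visit = 0.1, sigma_within = 0.1,
                           sigma_between = 0.5, seed = 21)
  tab0 <- simulate_baseline(cfg0)
  r0 <- cor(rowMeans(suppressMessages(to_wide(tab0, "saliva"))),
            rowMeans(suppressMessages(to_wide(tab0, "plasma"))))
  expect_lt(abs(r0), 0.15)
})

test_that("crossover design is counterbalanced with four routes per subject", {
  cfg <- generator_config(n_subjects = 16, seed = 31)
  tab <- simulate_intervention(cfg)
  base <- tab[tab$fluid == "plasma" & tab$time_point == "baseline", ]
  per_subject <- tapply(base$treatment, base$subject_id,
                        function(x) length(unique(x)))
  expect_true(all(per_subject == 4L))
  # each visit sees every route equally often (16 = 4 x full square)
  counts <- table(base$visit, base$treatment)
  expect_true(all(counts == 4L))
  expect_error(simulate_intervention(
    generator_config(treatment_effects = list(spray = c(saliva = 1,
                                                        plasma = 1)))),
    "treatment_effects")
})

test_that("intravenous route leaves saliva flat while raising plasma", {
  set.seed(2025)
  sal_p <- numeric(30); pla_p <- numeric(30)
  for (i in 1:30) {
    cfg <- generator_config(n_subjects = 13, seed = sample.int(1e6, 1))
    tab <- simulate_intervention(cfg)
    a <- suppressMessages(rm_anova_twoway(tab, "saliva"))
    ph <- posthoc_paired_tukey(a)
    sal_p[i] <- ph$p_adjusted[ph$treatment == "intravenous"]
    php <- posthoc_paired_tukey(suppressMessages(
      rm_anova_twoway(tab, "plasma")))
    pla_p[i] <- php$p_adjusted[php$treatment == "intravenous"]
  }
  expect_gte(mean(sal_p > 0.05), 0.9)   # saliva untouched by IV
  expect_gte(mean(pla_p < 0.05), 0.9)   # plasma raised by IV
})

test_that("pulsatile traces behave like an episodic-release process", {
  cfg <- generator_config(pulsatile = TRUE, seed = 3)
  # zero pulse rate: flat basal trace
  flat <- simulate_pulsatile_trace(
    generator_config(pulsatile = TRUE, pulse_rate_per_hour = 0, seed = 3),
    duration_min = 120, sampling_times = c(0, 30, 60, 120), basal = 2)
  expect_equal(flat, rep(2, 4))
  expect_error(simulate_pulsatile_trace(cfg, -5, 0), "non-negative")
  expect_error(simulate_pulsatile_trace(generator_config(), 10, 5),
               "pulsatile")

  # samples minutes apart agree better than samples on different 'days'
  set.seed(15)
  close_diff <- numeric(300); far_diff <- numeric(300)
  for (i in 1:300) {
    tr <- simulate_pulsatile_trace(cfg, duration_min = 2000,
                                   sampling_times = c(100, 105, 1540),
                                   seed = sample.int(1e6, 1))
    close_diff[i] <- abs(tr[2] - tr[1])
    far_diff[i] <- abs(tr[3] - tr[1])
  }
  expect_lt(mean(close_diff), mean(far_diff))

  # doubling amplitude raises between-sample variability monotonically
  amp_cv <- vapply(c(1, 2, 4), function(amp) {
    cfga <- generator_config(pulsatile = TRUE, pulse_amplitude = amp,
                             seed = 3)
    vals <- vapply(1:300, function(i)
      simulate_pulsatile_trace(cfga, 3000,
                               sampling_times = i * 10, seed = i)[1],
      numeric(1))
    stats::sd(vals) / mean(vals)
  }, numeric(1))
  expect_true(all(diff(amp_cv) > 0))
})

test_that("recovery suite tabulates bias and coverage deterministically", {
  rep1 <- recovery_suite(icc_grid = c(0.2, 0.8), n_grid = c(20, 100),
                         n_replicates = 10, seed = 6)
  expect_equal(nrow(rep1), 4L)
  expect_true(all(abs(rep1$icc_bias[rep1$n_subjects == 100]) < 0.15))
  rep2 <- recovery_suite(icc_grid = c(0.2, 0.8), n_grid = c(20, 100),
                         n_replicates = 10, seed = 6)
  expect_identical(rep1, rep2)
  one <- recovery_suite(icc_grid = 0.5, n_grid = 20, n_replicates = 1,
                        seed = 2)
  expect_true(is.na(one$ci_coverage))
  path <- withr::local_tempfile(fileext = ".csv")
  recovery_suite(icc_grid = 0.5, n_grid = 15, n_replicates = 3, seed = 4,
                 path = path)
  expect_true(file.exists(path))
})
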