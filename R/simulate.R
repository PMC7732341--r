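#' Configuration for the hormone-concentration generator
#'
#' Defines the variance-components model the simulated data follow. On the
#' natural-log scale the baseline concentration of subject i, visit j, fluid
#' f is
#' \deqn{y_{ijf} = \mu_f + b_{if} + v_{ijf} + e_{ijf}}
#' with subject (trait) effect b ~ N(0, sigma_between^2), correlated between
#' fluids by `cross_fluid_rho`; session-specific biological state
#' v ~ N(0, sigma_visit^2), independent across fluids; and residual
#' e ~ N(0, sigma_within^2). The implied true single-measurement reliability
#' is
#' \deqn{ICC = \sigma^2_b / (\sigma^2_b + \sigma^2_v + \sigma^2_w)}
#' and is stored (read-only) as `icc_true`. Concentrations are exponentiated
#' to pg/ml, multiplied by log-normal assay noise of coefficient of variation
#' `assay_cv` percent, and censored to missing below `detection_floor`.
#'
#' Defaults emulate a four-visit morning-sampling study of healthy male
#' volunteers: concentrations in the typical 1-10 pg/ml physiological range,
#' a true ICC near 0.29 with raw-scale within-subject CV near 57%, assay CV
#' under the 10% intra-assay bound of radioimmunoassay, and a 0.1 pg/ml
#' detection floor.
#'
#' @param n_subjects number of subjects (default 17).
#' @param n_visits number of visits (default 4).
#' @param fluids fluids to generate.
#' @param mu_log named log-scale means (log pg/ml) per fluid.
#' @param sigma_between,sigma_visit,sigma_within log-scale standard
#'   deviations of the subject, visit and residual components.
#' @param cross_fluid_rho correlation of subject effects between fluids
#'   (default 0.10, the weak saliva-plasma association typical of baseline
#'   data).
#' @param treatment_effects named list: route -> named numeric vector of
#'   multiplicative post/baseline concentration ratios per fluid. Defaults
#'   encode intranasal routes raising saliva strongly (drip-down peptide),
#'   intravenous raising plasma only, placebo neutral.
#' @param pulsatile logical; add pulsatile secretion when tracing (see
#'   [simulate_pulsatile_trace()]).
#' @param pulse_rate_per_hour,pulse_amplitude,pulse_decay_per_min pulse
#'   process parameters: Poisson pulse rate, mean pulse height (pg/ml) and
#'   exponential decay constant (per minute; default log(2)/10, a 10-min
#'   half-life).
#' @param assay_cv percent assay coefficient of variation, must be <= 10.
#' @param detection_floor pg/ml; simulated values below it become missing.
#' @param visit_gap_mean_days,visit_gap_sd_days,visit_gap_range_days
#'   between-visit spacing distribution (normal, truncated to the range,
#'   rounded to whole days).
#' @param seed integer RNG seed; all simulation is deterministic given it.
#' @return validated list of class `"generator_config"`, with `icc_true`
#'   (named per fluid) computed from the variance components.
#' @export
generator_config <- function(n_subjects = 17L, n_visits = 4L,
                             fluids = c("saliva", "plasma"),
                             mu_log = c(saliva = log(2.5), plasma = log(4)),
                             sigma_between = 0.34, sigma_visit = 0.30,
                             sigma_within = 0.44,
                             cross_fluid_rho = 0.10,
                             treatment_effects = list(
                               spray = c(saliva = 12, plasma = 1.3),
                               nebuliser = c(saliva = 12, plasma = 1.1),
                               intravenous = c(saliva = 1.0, plasma = 2.8),
                               placebo = c(saliva = 1.0, plasma = 1.0)),
                             pulsatile = FALSE,
                             pulse_rate_per_hour = 3,
                             pulse_amplitude = 2,
                             pulse_decay_per_min = log(2) / 10,
                             assay_cv = 8,
                             detection_floor = 0.1,
                             visit_gap_mean_days = 8.8,
                             visit_gap_sd_days = 5.7,
                             visit_gap_range_days = c(3, 28),
                             seed = 1L) {
  stopifnot(n_subjects >= 1L, n_visits >= 1L,
            all(fluids %in% FLUIDS), length(fluids) >= 1L,
            sigma_between >= 0, sigma_visit >= 0, sigma_within >= 0,
            abs(cross_fluid_rho) <= 1,
            assay_cv >= 0, detection_floor >= 0,
            pulse_rate_per_hour >= 0, pulse_amplitude >= 0,
            pulse_decay_per_min > 0)
  if (assay_cv > 10)
    stop("assay_cv must be <= 10 (percent), the assay's intra-assay bound")
  if (!all(fluids %in% names(mu_log)))
    stop("mu_log must name every generated fluid")
  total <- sigma_between^2 + sigma_visit^2 + sigma_within^2
  if (total == 0) stop("all variance components are zero")
  icc_true <- sigma_between^2 / total
  structure(list(n_subjects = as.integer(n_subjects),
                 n_visits = as.integer(n_visits), fluids = fluids,
                 mu_log = mu_log, sigma_between = sigma_between,
                 sigma_visit = sigma_visit, sigma_within = sigma_within,
                 icc_true = stats::setNames(rep(icc_true, length(fluids)),
                                            fluids),
                 cross_fluid_rho = cross_fluid_rho,
                 treatment_effects = treatment_effects,
                 pulsatile = pulsatile,
                 pulse_rate_per_hour = pulse_rate_per_hour,
                 pulse_amplitude = pulse_amplitude,
                 pulse_decay_per_min = pulse_decay_per_min,
                 assay_cv = assay_cv, detection_floor = detection_floor,
                 visit_gap_mean_days = visit_gap_mean_days,
                 visit_gap_sd_days = visit_gap_sd_days,
                 visit_gap_range_days = visit_gap_range_days,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Hormone generator: %d subjects x %d visits, fluids %s\n",
              x$n_subjects, x$n_visits, paste(x$fluids, collapse = "+")))
  cat(sprintf("  log-scale sd (subject/visit/residual): %.2f/%.2f/%.2f -> true ICC = %.3f\n",
              x$sigma_between, x$sigma_visit, x$sigma_within,
              x$icc_true[1L]))
  cat(sprintf("  assay CV %.0f%%, detection floor %.2g pg/ml, seed %d\n",
              x$assay_cv, x$detection_floor, x$seed))
  invisible(x)
}

#' Variance components realising a target reliability
#'
#' Convenience inverse of the `icc_true` relation: splits a total log-scale
#' variance into a subject component carrying `icc_true` of it and visit /
#' residual components sharing the remainder equally.
#'
#' @param icc_true target true ICC in \[0, 1).
#' @param sigma_total total log-scale standard deviation (default 0.63, the
#'   package's default total).
#' @return named numeric vector `sigma_between`, `sigma_visit`,
#'   `sigma_within`.
#' @export
variance_components_for_icc <- function(icc_true, sigma_total = 0.63) {
  stopifnot(icc_true >= 0, icc_true < 1, sigma_total > 0)
  v <- sigma_total^2
  c(sigma_between = sqrt(icc_true * v),
    sigma_visit = sqrt((1 - icc_true) * v / 2),
    sigma_within = sqrt((1 - icc_true) * v / 2))
}

# Draw per-subject visit-date offsets: day 0, then gaps ~ N(mean, sd)
# truncated to the configured range, rounded to whole days.
draw_visit_offsets <- function(config) {
  gaps <- matrix(0, config$n_subjects, max(config$n_visits - 1L, 0L))
  if (ncol(gaps) > 0L) {
    lo <- config$visit_gap_range_days[1L]; hi <- config$visit_gap_range_days[2L]
    k <- length(gaps)
    draws <- stats::rnorm(k, config$visit_gap_mean_days,
                          config$visit_gap_sd_days)
    while (any(bad <- draws < lo | draws > hi))
      draws[bad] <- stats::rnorm(sum(bad), config$visit_gap_mean_days,
                                 config$visit_gap_sd_days)
    gaps[] <- round(draws)
  }
  cbind(0, t(apply(gaps, 1L, cumsum)))[, seq_len(config$n_visits),
                                       drop = FALSE]
}

# Latent log-scale baseline array [subject, visit, fluid] plus subject
# effects, all RNG inside the caller's stream.
draw_baseline_log <- function(config) {
  ns <- config$n_subjects; nv <- config$n_visits
  nf <- length(config$fluids)
  rho <- config$cross_fluid_rho
  z <- matrix(stats::rnorm(ns * nf), ns, nf)
  if (nf == 2L) z[, 2L] <- rho * z[, 1L] + sqrt(1 - rho^2) * z[, 2L]
  b <- config$sigma_between * z
  y <- array(NA_real_, c(ns, nv, nf),
             dimnames = list(NULL, NULL, config$fluids))
  for (f in seq_len(nf)) {
    v <- matrix(stats::rnorm(ns * nv, 0, config$sigma_visit), ns, nv)
    e <- matrix(stats::rnorm(ns * nv, 0, config$sigma_within), ns, nv)
    y[, , f] <- config$mu_log[config$fluids[f]] + b[, f] + v + e
  }
  y
}

# Multiplicative log-normal assay noise with the configured percent CV,
# then detection-floor censoring to NA.
apply_assay <- function(conc, config) {
  if (config$assay_cv > 0) {
    sdlog <- sqrt(log1p((config$assay_cv / 100)^2))
    conc <- conc * exp(stats::rnorm(length(conc), -sdlog^2 / 2, sdlog))
  }
  conc[conc < config$detection_floor] <- NA_real_
  conc
}

#' Simulate baseline-only repeated measurements
#'
#' Generates a long-format table of baseline concentrations (treatment
#' `"none"`) under the variance-components model of the configuration:
#' subject, visit and residual log-scale effects, assay noise, and
#' detection-floor censoring (censored values become missing, never
#' floor-imputed). Deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return a [sample_table()] with `visit_date_offset_days` filled in.
#' @examples
#' tab <- simulate_baseline(generator_config(n_subjects = 8, seed = 3))
#' tab
#' @export
simulate_baseline <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    y <- draw_baseline_log(config)
    offsets <- draw_visit_offsets(config)
    grid <- expand.grid(subject = seq_len(config$n_subjects),
                        visit = seq_len(config$n_visits),
                        fluid = config$fluids,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    conc <- apply_assay(exp(y[cbind(grid$subject, grid$visit,
                                    match(grid$fluid, config$fluids))]),
                        config)
    records <- data.frame(
      subject_id = sprintf("S%02d", grid$subject),
      visit = grid$visit,
      fluid = grid$fluid,
      time_point = "baseline",
      treatment = "none",
      concentration_pg_ml = conc,
      collection_offset_min = 0,
      visit_date_offset_days = offsets[cbind(grid$subject, grid$visit)])
    sample_table(records, dataset = "synthetic-baseline",
                 assay = sprintf("simulated, assay CV %.0f%%, seed %d",
                                 config$assay_cv, config$seed))
  })
}

#' Simulate a four-treatment crossover intervention study
#'
#' Emulates a within-subject crossover: each subject receives each route
#' (spray, nebuliser, intravenous, placebo) once across `n_visits = 4`
#' visits, in an order counterbalanced by a seeded Latin square. Each visit
#' contributes a baseline and a post-administration sample per fluid; the
#' post-administration concentration is the visit's baseline times the
#' route- and fluid-specific ratio from `treatment_effects`, times fresh
#' residual and assay noise.
#'
#' @param config a [generator_config()] with `n_visits = 4` and
#'   `treatment_effects` covering all four routes.
#' @param post_offset_min minutes after administration at which the post
#'   sample is recorded (default 115).
#' @return a [sample_table()] with baseline and post records per treatment.
#' @export
simulate_intervention <- function(config, post_offset_min = 115) {
  stopifnot(inherits(config, "generator_config"))
  routes <- c("spray", "nebuliser", "intravenous", "placebo")
  if (!all(routes %in% names(config$treatment_effects)))
    stop("treatment_effects must define all of: ",
         paste(routes, collapse = ", "))
  for (r in routes)
    if (!all(config$fluids %in% names(config$treatment_effects[[r]])))
      stop("treatment_effects$", r, " must name every generated fluid")
  if (config$n_visits != 4L)
    stop("the crossover design uses exactly 4 visits")
  with_seed(config$seed, {
    ns <- config$n_subjects
    y <- draw_baseline_log(config)
    offsets <- draw_visit_offsets(config)
    # Latin square rows assign a treatment order; rows permuted by seed and
    # recycled over subjects for counterbalancing.
    square <- t(vapply(0:3, function(s) routes[(s + 0:3) %% 4L + 1L],
                       character(4L)))
    square <- square[sample.int(4L), , drop = FALSE]
    order_by_subject <- square[(seq_len(ns) - 1L) %% 4L + 1L, , drop = FALSE]
    rows <- list()
    for (f in config$fluids) {
      fi <- match(f, config$fluids)
      for (j in 1:4) {
        base_log <- y[, j, fi]
        ratio <- vapply(order_by_subject[, j], function(r)
          config$treatment_effects[[r]][[f]], numeric(1L))
        post_log <- base_log + log(ratio) +
          stats::rnorm(ns, 0, config$sigma_within)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("S%02d", seq_len(ns)), visit = j, fluid = f,
          time_point = "baseline", treatment = order_by_subject[, j],
          concentration_pg_ml = exp(base_log),
          collection_offset_min = 0,
          visit_date_offset_days = offsets[, j])
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("S%02d", seq_len(ns)), visit = j, fluid = f,
          time_point = "post_administration",
          treatment = order_by_subject[, j],
          concentration_pg_ml = exp(post_log),
          collection_offset_min = post_offset_min,
          visit_date_offset_days = offsets[, j])
      }
    }
    records <- do.call(rbind, rows)
    records$concentration_pg_ml <- apply_assay(records$concentration_pg_ml,
                                               config)
    sample_table(records, dataset = "synthetic-intervention",
                 assay = sprintf("simulated, assay CV %.0f%%, seed %d",
                                 config$assay_cv, config$seed))
  })
}

#' Simulate a pulsatile secretion trace
#'
#' Superimposes Poisson-timed secretory pulses with exponential decay on a
#' constant basal level and reads the concentration at the requested
#' sampling times. Illustrates why a single-time sample of a pulsatile
#' process is phase-dependent: samples minutes apart agree far better than
#' samples days apart.
#'
#' @param config a [generator_config()] with `pulsatile = TRUE`.
#' @param duration_min length of the simulated trace in minutes (>= 0).
#' @param sampling_times minutes at which to read the concentration.
#' @param basal basal concentration in pg/ml.
#' @param seed optional seed override (defaults to `config$seed`).
#' @return numeric vector of concentrations at `sampling_times`.
#' @export
simulate_pulsatile_trace <- function(config, duration_min, sampling_times,
                                     basal = 2, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!config$pulsatile) stop("config does not enable pulsatile secretion")
  if (duration_min < 0) stop("duration_min must be non-negative")
  stopifnot(all(sampling_times >= 0), all(sampling_times <= duration_min))
  with_seed(seed, {
    n_pulses <- stats::rpois(1L, config$pulse_rate_per_hour *
                               duration_min / 60)
    pulse_times <- sort(stats::runif(n_pulses, 0, duration_min))
    amplitudes <- stats::rexp(n_pulses, 1 / config$pulse_amplitude)
    vapply(sampling_times, function(t) {
      active <- pulse_times <= t
      basal + sum(amplitudes[active] *
                    exp(-config$pulse_decay_per_min * (t - pulse_times[active])))
    }, numeric(1L))
  })
}

#' Parameter-recovery study for the reliability pipeline
#'
#' For each configuration on an ICC-by-sample-size grid, repeatedly
#' simulates baseline data, runs the reliability fit, and tabulates the
#' bias and root-mean-square error of the ICC estimate, the mean
#' within-subject CV and the empirical coverage of the 95% ICC confidence
#' interval. Acts as the package's own calibration report.
#'
#' @param icc_grid true ICC values to simulate.
#' @param n_grid numbers of subjects.
#' @param k number of visits.
#' @param n_replicates replicates per cell (coverage reported only when
#'   > 1).
#' @param seed master seed; replicate seeds are derived from it.
#' @param sigma_total total log-scale sd passed to
#'   [variance_components_for_icc()].
#' @param path optional CSV output path.
#' @return data.frame with one row per grid cell.
#' @export
recovery_suite <- function(icc_grid = c(0.2, 0.5, 0.8),
                           n_grid = c(20L, 100L), k = 4L,
                           n_replicates = 50L, seed = 1L,
                           sigma_total = 0.63, path = NULL) {
  stopifnot(length(icc_grid) >= 1L, length(n_grid) >= 1L,
            n_replicates >= 1L)
  grid <- expand.grid(icc_true = icc_grid, n_subjects = n_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    sig <- variance_components_for_icc(grid$icc_true[g], sigma_total)
    est <- matrix(NA_real_, n_replicates, 4L,
                  dimnames = list(NULL, c("icc", "cv", "lo", "hi")))
    for (rep in seq_len(n_replicates)) {
      cfg <- generator_config(
        n_subjects = grid$n_subjects[g], n_visits = k, fluids = "plasma",
        mu_log = c(plasma = log(4)),
        sigma_between = sig[["sigma_between"]],
        sigma_visit = sig[["sigma_visit"]],
        sigma_within = sig[["sigma_within"]],
        seed = (seed * 10007L + g * 211L + rep) %% .Machine$integer.max)
      fit <- suppressMessages(
        reliability(simulate_baseline(cfg), fluid = "plasma"))
      est[rep, ] <- c(fit$icc$icc, fit$cv$cv_mean, fit$icc$ci_low,
                      fit$icc$ci_high)
    }
    data.frame(icc_true = grid$icc_true[g],
               n_subjects = grid$n_subjects[g], k = k,
               n_replicates = n_replicates,
               icc_mean = mean(est[, "icc"]),
               icc_bias = mean(est[, "icc"]) - grid$icc_true[g],
               icc_rmse = sqrt(mean((est[, "icc"] - grid$icc_true[g])^2)),
               cv_mean = mean(est[, "cv"]),
               ci_coverage = if (n_replicates > 1L)
                 mean(est[, "lo"] <= grid$icc_true[g] &
                        est[, "hi"] >= grid$icc_true[g])
               else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
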