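#' Run the full analysis pipeline on a simulated crossover study
#'
#' End-to-end composition of the package: simulate a crossover study
#' ([simulate_intervention()]), screen outliers stratum-wise and drop
#' missing values ([screen_outliers()], [apply_exclusions()]), fit
#' between-visit reliability per fluid ([reliability()]), project the
#' Spearman-Brown samples-needed table ([project_reliability()]), run the
#' treatment-by-time repeated-measures ANOVA with Tukey-adjusted paired
#' post-hocs ([rm_anova_twoway()], [posthoc_paired_tukey()]), and correlate
#' saliva with plasma at baseline (multilevel) and post-administration per
#' treatment (bootstrap Pearson plus Bayes factor). All report CSVs are
#' written to `out_dir`; everything is deterministic given the
#' configuration seed.
#'
#' @param config a [generator_config()] (both fluids, 4 visits).
#' @param out_dir output directory, created if needed.
#' @param boot_seed seed for the bootstrap resampling.
#' @return invisibly, a list with every intermediate result object.
#' @export
run_pipeline <- function(config = generator_config(), out_dir,
                         boot_seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tab <- simulate_intervention(config)
  write_sample_table(tab, file.path(out_dir, "samples.csv"))

  excl <- apply_exclusions(tab, outlier = screen_outliers(tab))
  utils::write.csv(excl$report, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  clean <- excl$table

  fits <- lapply(stats::setNames(config$fluids, config$fluids), function(f)
    suppressMessages(reliability(clean, fluid = f)))
  reliability_report(fits, file.path(out_dir, "reliability.csv"))

  projections <- lapply(fits, function(fit)
    if (fit$icc$icc > 0 && fit$icc$icc < 1)
      project_reliability(fit$icc$icc) else NULL)
  proj_df <- do.call(rbind, lapply(names(projections), function(f)
    if (!is.null(projections[[f]]))
      data.frame(fluid = f, as.data.frame(projections[[f]]))))
  utils::write.csv(proj_df, file.path(out_dir, "projection.csv"),
                   row.names = FALSE)

  anovas <- lapply(stats::setNames(config$fluids, config$fluids), function(f)
    suppressMessages(rm_anova_twoway(clean, fluid = f)))
  anova_df <- do.call(rbind, lapply(names(anovas), function(f)
    data.frame(fluid = f, as.data.frame(anovas[[f]]))))
  utils::write.csv(anova_df, file.path(out_dir, "anova.csv"),
                   row.names = FALSE)
  posthoc_df <- do.call(rbind, lapply(names(anovas), function(f)
    data.frame(fluid = f, posthoc_paired_tukey(anovas[[f]]))))
  utils::write.csv(posthoc_df, file.path(out_dir, "posthoc.csv"),
                   row.names = FALSE)

  cors <- list()
  if (all(c("saliva", "plasma") %in% config$fluids)) {
    base <- merge(
      clean[clean$fluid == "saliva" & clean$time_point == "baseline",
            c("subject_id", "visit", "concentration_pg_ml")],
      clean[clean$fluid == "plasma" & clean$time_point == "baseline",
            c("subject_id", "visit", "concentration_pg_ml")],
      by = c("subject_id", "visit"), suffixes = c("_saliva", "_plasma"))
    cors$baseline_multilevel <- multilevel_correlation(
      log(base$concentration_pg_ml_saliva),
      log(base$concentration_pg_ml_plasma), base$subject_id)
    cors$baseline_bayes <- bayes_correlation(
      log(base$concentration_pg_ml_saliva),
      log(base$concentration_pg_ml_plasma))
    for (tr in names(config$treatment_effects)) {
      post <- merge(
        clean[clean$fluid == "saliva" & clean$treatment == tr &
              clean$time_point == "post_administration",
              c("subject_id", "concentration_pg_ml")],
        clean[clean$fluid == "plasma" & clean$treatment == tr &
              clean$time_point == "post_administration",
              c("subject_id", "concentration_pg_ml")],
        by = "subject_id", suffixes = c("_saliva", "_plasma"))
      if (nrow(post) >= 4L)
        cors[[paste0("post_", tr)]] <- pearson_bootstrap(
          log(post$concentration_pg_ml_saliva),
          log(post$concentration_pg_ml_plasma), seed = boot_seed)
    }
  }
  association_report(cors, file.path(out_dir, "associations.csv"))

  invisible(list(table = tab, clean = clean, exclusions = excl$report,
                 reliability = fits, projections = projections,
                 anova = anovas, posthoc = posthoc_df,
                 correlations = cors))
}
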