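#' Fit a test-retest reliability model to repeated hormone measurements
#'
#' The package's main fitting function. For one fluid, extracts the
#' complete-case subjects-by-visits matrix from a long-format table, then
#' quantifies relative reliability by the single-measures absolute-agreement
#' intraclass correlation (on natural-log concentrations by default, since
#' hormone concentrations are right-skewed) and absolute reliability by the
#' within-subject coefficient of variation (always meaningful only on the raw
#' scale). The returned object carries both, with the usual methods
#' (`print`, `summary`, `coef`, `confint`); `summary` adds the
#' Spearman-Brown projection of the number of measurements needed per
#' individual to reach fair/moderate/good reliability of an averaged measure.
#'
#' @param table a [sample_table()].
#' @param fluid `"saliva"` or `"plasma"`.
#' @param visits visits to include (default: all present).
#' @param time_point sampling time-point (default `"baseline"`).
#' @param treatment optional treatment filter passed to [to_wide()].
#' @param icc_scale scale for the ICC: `"log"` (default) or `"raw"`.
#' @param conf.level confidence level for the ICC interval.
#' @return object of class `"reliability_estimate"`.
#' @examples
#' cfg <- generator_config(n_subjects = 20, n_visits = 4, seed = 7)
#' tab <- simulate_baseline(cfg)
#' fit <- reliability(tab, fluid = "plasma")
#' fit
#' summary(fit)
#' @export
reliability <- function(table, fluid, visits = NULL, time_point = "baseline",
                        treatment = NULL, icc_scale = c("log", "raw"),
                        conf.level = 0.95) {
  icc_scale <- match.arg(icc_scale)
  raw <- to_wide(table, fluid = fluid, visits = visits,
                 time_point = time_point, treatment = treatment,
                 log_scale = FALSE)
  icc_mat <- if (icc_scale == "log") log(raw) else raw
  icc <- icc_absolute_agreement(icc_mat, conf.level = conf.level)
  cv <- within_subject_cv(raw)
  structure(list(icc = icc, cv = cv,
                 fluid = fluid, time_point = time_point,
                 visits = as.integer(sub("visit_", "", colnames(raw))),
                 icc_scale = icc_scale,
                 dataset = attr(table, "dataset"),
                 n_subjects = nrow(raw), n_occasions = ncol(raw)),
            class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("Test-retest reliability: %s, %s (dataset %s)\n",
              x$fluid, x$time_point, x$dataset))
  cat(sprintf("  visits %s | N = %d complete subjects\n",
              paste(x$visits, collapse = ","), x$n_subjects))
  cat(sprintf("  ICC = %.*f  [%.*f, %.*f]  F(%d, %d) = %.2f, p = %.3g  (%s scale)\n",
              digits, x$icc$icc, digits, x$icc$ci_low, digits, x$icc$ci_high,
              x$icc$df1, x$icc$df2, x$icc$f_stat, x$icc$p_value, x$icc_scale))
  cat(sprintf("  CV  = %.0f%% (SD %.0f%%)  (raw scale)\n",
              x$cv$cv_mean, x$cv$cv_sd))
  invisible(x)
}

#' @export
coef.reliability_estimate <- function(object, ...) {
  c(icc = object$icc$icc, cv_mean = object$cv$cv_mean,
    cv_sd = object$cv$cv_sd)
}

#' @export
confint.reliability_estimate <- function(object, parm = "icc",
                                         level = NULL, ...) {
  if (!is.null(level) && !isTRUE(all.equal(level, object$icc$conf.level)))
    stop("interval was computed at level ", object$icc$conf.level,
         "; refit with conf.level = ", level)
  matrix(c(object$icc$ci_low, object$icc$ci_high), nrow = 1L,
         dimnames = list("icc", c("lower", "upper")))
}

#' @export
summary.reliability_estimate <- function(object,
                                         targets = c(0.80, 0.70, 0.50),
                                         ...) {
  proj <- if (object$icc$icc > 0 && object$icc$icc < 1)
    project_reliability(object$icc$icc, targets = targets)
  else NULL
  structure(list(fit = object, projection = proj),
            class = "summary.reliability_estimate")
}

#' @export
print.summary.reliability_estimate <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$projection)) {
    cat("  Spearman-Brown: measurements per individual needed for an\n")
    cat("  averaged measure to reach target reliability:\n")
    with(x$projection, cat(sprintf("    target %.2f -> %.2f samples\n",
                                   icc_target, samples_needed), sep = ""))
  }
  invisible(x)
}

#' Reliability for every pair of visits
#'
#' Recomputes the complete-case reliability fit separately for each unordered
#' pair of visits (complete cases are re-extracted per pair, maximising the n
#' available to each). Pairs with fewer than 2 complete subjects are skipped
#' with a warning.
#'
#' @inheritParams reliability
#' @return named list of `reliability_estimate` objects, keyed like
#'   `"1-2"`; class `"pairwise_reliability"`.
#' @export
pairwise_reliability <- function(table, fluid, time_point = "baseline",
                                 treatment = NULL, conf.level = 0.95) {
  visits <- sort(unique(table$visit[table$fluid == fluid &
                                    table$time_point == time_point]))
  if (length(visits) < 2L) stop("need at least 2 visits")
  pairs <- utils::combn(visits, 2L)
  out <- list()
  for (j in seq_len(ncol(pairs))) {
    key <- paste(pairs[, j], collapse = "-")
    est <- tryCatch(
      suppressMessages(
        reliability(table, fluid = fluid, visits = pairs[, j],
                    time_point = time_point, treatment = treatment,
                    conf.level = conf.level)),
      error = function(e) {
        warning("pair ", key, " skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(est)) out[[key]] <- est
  }
  structure(out, class = "pairwise_reliability")
}

#' @export
print.pairwise_reliability <- function(x, ...) {
  df <- as.data.frame(x)
  cat("Pairwise between-visit reliability:\n")
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
as.data.frame.pairwise_reliability <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(k) {
    e <- x[[k]]
    data.frame(pair = k, n = e$n_subjects, icc = e$icc$icc,
               ci_low = e$icc$ci_low, ci_high = e$icc$ci_high,
               p = e$icc$p_value, cv_mean = e$cv$cv_mean,
               cv_sd = e$cv$cv_sd)
  }))
}

#' Does between-visit spacing variability explain concentration variability?
#'
#' Per subject, computes the variance of the intervals (days) between
#' consecutive visits and the variance of the concentrations across visits,
#' then correlates the two across subjects with a Spearman rank correlation
#' (average ranks for ties). A null association supports the interpretation
#' that poor between-visit reliability is not driven by uneven visit spacing.
#'
#' @inheritParams reliability
#' @param on_log compute the concentration variance on log values
#'   (default `TRUE`, matching the analysis scale).
#' @return list with `rho`, `p_value`, `n_subjects` and the per-subject
#'   variance table.
#' @export
interval_variance_association <- function(table, fluid,
                                          time_point = "baseline",
                                          on_log = TRUE) {
  stopifnot(inherits(table, "sample_table"))
  if (!"visit_date_offset_days" %in% names(table))
    stop("visit_date_offset_days column is required")
  sub <- table[table$fluid == fluid & table$time_point == time_point &
               !is.na(table$concentration_pg_ml), , drop = FALSE]
  missing_dates <- unique(sub$subject_id[is.na(sub$visit_date_offset_days)])
  if (length(missing_dates) > 0L)
    stop("missing visit date offsets for subject(s): ",
         paste(missing_dates, collapse = ", "))
  per <- lapply(split(sub, sub$subject_id), function(d) {
    d <- d[order(d$visit), ]
    if (nrow(d) < 3L) return(NULL)  # need >= 2 intervals for a variance
    conc <- if (on_log) log(d$concentration_pg_ml) else d$concentration_pg_ml
    data.frame(subject_id = d$subject_id[1L],
               interval_var = stats::var(diff(d$visit_date_offset_days)),
               concentration_var = stats::var(conc))
  })
  tab <- do.call(rbind, per)
  if (is.null(tab) || nrow(tab) < 5L)
    stop("need >= 5 subjects with >= 3 dated visits")
  ct <- suppressWarnings(
    stats::cor.test(tab$interval_var, tab$concentration_var,
                    method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_subjects = nrow(tab), per_subject = tab)
}

#' Write a reliability report CSV
#'
#' One row per analysis: dataset, fluid, visits, n, ICC with CI and F-test,
#' and the CV summary.
#'
#' @param fits list of `reliability_estimate` objects (or a single one).
#' @param path output CSV path.
#' @return the report data.frame, invisibly.
#' @export
reliability_report <- function(fits, path = NULL) {
  if (inherits(fits, "reliability_estimate")) fits <- list(fits)
  df <- do.call(rbind, lapply(fits, function(e) {
    data.frame(dataset = e$dataset, fluid = e$fluid,
               visits = paste(e$visits, collapse = ";"),
               n = e$n_subjects,
               icc = e$icc$icc, ci_low = e$icc$ci_low,
               ci_high = e$icc$ci_high,
               f = e$icc$f_stat, df1 = e$icc$df1, df2 = e$icc$df2,
               p = e$icc$p_value,
               cv_mean = e$cv$cv_mean, cv_sd = e$cv$cv_sd)
  }))
  rownames(df) <- NULL
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
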