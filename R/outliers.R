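#' Flag outliers by the boxplot labelling rule
#'
#' A value is flagged when it lies more than `g` interquartile ranges above
#' the third quartile or below the first quartile. Quartiles use linear
#' interpolation between order statistics by default (`quantile` type 7, the
#' common default in mainstream statistical software); other conventions are
#' available through `type`.
#'
#' @param values numeric vector with at least 4 finite values.
#' @param g fence multiplier (default 1.5, the classical labelling rule).
#' @param type quartile definition passed to [stats::quantile()].
#' @return logical mask, `TRUE` where the value is outside the fences.
#'   Missing values are never flagged. A constant vector (zero IQR) yields no
#'   flags.
#' @export
label_outliers <- function(values, g = 1.5, type = 7) {
  stopifnot(is.numeric(values), g >= 0)
  if (sum(is.finite(values)) < 4L)
    stop("need at least 4 finite values to apply the labelling rule")
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE,
                       type = type)
  iqr <- q[2L] - q[1L]
  mask <- !is.na(values) & (values > q[2L] + g * iqr |
                            values < q[1L] - g * iqr)
  attr(mask, "fences") <- c(lower = q[1L] - g * iqr, upper = q[2L] + g * iqr)
  mask
}

#' Screen a sample table for outliers stratum-wise
#'
#' Applies [label_outliers()] separately within each fluid x time-point x
#' treatment stratum (strata with fewer than 4 observed values are left
#' unscreened), mirroring per-condition screening of repeated-measures
#' designs.
#'
#' @param table a `sample_table`.
#' @param g fence multiplier.
#' @param on_log if `TRUE`, screen natural-log concentrations instead of raw.
#' @return logical mask aligned with the rows of `table`.
#' @export
screen_outliers <- function(table, g = 1.5, on_log = FALSE) {
  stopifnot(inherits(table, "sample_table"))
  conc <- table$concentration_pg_ml
  if (on_log) conc <- log(conc)
  stratum <- interaction(table$fluid, table$time_point, table$treatment,
                         drop = TRUE)
  mask <- logical(nrow(table))
  for (s in levels(stratum)) {
    idx <- which(stratum == s)
    if (sum(is.finite(conc[idx])) >= 4L)
      mask[idx] <- label_outliers(conc[idx], g = g)
  }
  mask
}

#' Remove flagged and missing records, with a report
#'
#' Returns a filtered copy of the table together with a report listing every
#' removed record and the reason (`"outlier"` or `"missing"`). Records are
#' never imputed.
#'
#' @param table a `sample_table`.
#' @param outlier logical mask of outliers aligned with `table` rows (e.g.
#'   from [screen_outliers()]); default none.
#' @param missing logical mask of records to drop as missing; default rows
#'   with `NA` concentration.
#' @param g fence multiplier recorded in the report.
#' @return list with `table` (filtered `sample_table`) and `report`
#'   (data.frame with the record key, value, rule and threshold).
#' @export
apply_exclusions <- function(table, outlier = NULL, missing = NULL, g = 1.5) {
  stopifnot(inherits(table, "sample_table"))
  n <- nrow(table)
  if (is.null(outlier)) outlier <- logical(n)
  if (is.null(missing)) missing <- is.na(table$concentration_pg_ml)
  stopifnot(length(outlier) == n, length(missing) == n)
  drop <- outlier | missing
  reason <- ifelse(outlier, "outlier", "missing")[drop]
  report <- data.frame(
    as.data.frame(table)[drop, c("subject_id", "visit", "fluid",
                                 "time_point", "treatment",
                                 "concentration_pg_ml")],
    reason = reason,
    rule = ifelse(reason == "outlier",
                  sprintf("%.1fxIQR labelling rule", g), "missing value"),
    row.names = NULL)
  kept <- as.data.frame(table)[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(table = sample_table(kept, dataset = attr(table, "dataset"),
                            units = attr(table, "units"),
                            assay = attr(table, "assay")),
       report = report)
}
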