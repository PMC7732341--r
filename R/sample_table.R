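#' @keywords internal
"_PACKAGE"

FLUIDS <- c("saliva", "plasma")
TIME_POINTS <- c("baseline", "post_administration")
TREATMENTS <- c("spray", "nebuliser", "intravenous", "placebo", "none")

REQUIRED_COLUMNS <- c("subject_id", "visit", "fluid", "time_point",
                      "treatment", "concentration_pg_ml")
OPTIONAL_COLUMNS <- c("collection_offset_min", "visit_date_offset_days")

#' Construct a validated sample table
#'
#' A sample table is the long-format container used throughout the package:
#' one row per measurement of one fluid from one subject at one visit and
#' time-point. Concentrations are in pg/ml and must be positive (a natural-log
#' transform has to be defined) or missing (`NA`, e.g. censored below the
#' assay detection limit).
#'
#' @param records data.frame with columns `subject_id`, `visit` (integer
#'   >= 1), `fluid` (`"saliva"` or `"plasma"`), `time_point` (`"baseline"` or
#'   `"post_administration"`), `treatment` (`"spray"`, `"nebuliser"`,
#'   `"intravenous"`, `"placebo"` or `"none"`), `concentration_pg_ml`
#'   (positive or `NA`), and optionally `collection_offset_min` and
#'   `visit_date_offset_days`.
#' @param dataset label for the dataset the records belong to.
#' @param units unit declaration shared by all records; only `"pg/ml"` is
#'   supported.
#' @param assay free-text assay note (e.g. quantification method).
#'
#' @return A data.frame of class `"sample_table"` carrying `dataset`, `units`
#'   and `assay` attributes.
#' @export
sample_table <- function(records, dataset = "synthetic", units = "pg/ml",
                         assay = "") {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(records))
  if (length(missing_cols) > 0L)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (!identical(units, "pg/ml"))
    stop("units must be 'pg/ml'")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$subject_id <- as.character(records$subject_id)
  records$visit <- as.integer(records$visit)
  records$concentration_pg_ml <- as.numeric(records$concentration_pg_ml)
  for (col in OPTIONAL_COLUMNS)
    if (col %in% names(records)) records[[col]] <- as.numeric(records[[col]])

  validate_records(records)
  structure(records,
            class = c("sample_table", "data.frame"),
            dataset = dataset, units = units, assay = assay)
}

validate_records <- function(records) {
  bad_visit <- which(is.na(records$visit) | records$visit < 1L)
  if (length(bad_visit) > 0L)
    stop("invalid visit (must be integer >= 1) in row(s): ",
         paste(utils::head(bad_visit, 5L), collapse = ", "))
  check_enum <- function(col, allowed) {
    bad <- which(!(records[[col]] %in% allowed))
    if (length(bad) > 0L)
      stop("invalid ", col, " '", records[[col]][bad[1L]], "' in row ",
           bad[1L], "; allowed: ", paste(allowed, collapse = ", "))
  }
  check_enum("fluid", FLUIDS)
  check_enum("time_point", TIME_POINTS)
  check_enum("treatment", TREATMENTS)
  conc <- records$concentration_pg_ml
  bad_conc <- which(!is.na(conc) & conc <= 0)
  if (length(bad_conc) > 0L)
    stop("non-positive concentration in row(s) ",
         paste(utils::head(bad_conc, 5L), collapse = ", "),
         " (log-transform undefined)")
  key <- do.call(paste, c(records[c("subject_id", "visit", "fluid",
                                    "time_point", "treatment")], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup) > 0L)
    stop("duplicate (subject, visit, fluid, time_point, treatment) key in ",
         "row(s): ", paste(utils::head(dup, 5L), collapse = ", "))
  invisible(records)
}

#' Read a long-format sample table from CSV
#'
#' Comma-delimited UTF-8 with a header row naming at least the required
#' columns (see [sample_table()]). Lines starting with `#` before the header
#' carry metadata as `# key: value` (keys `dataset`, `units`, `assay`) and are
#' round-tripped by [write_sample_table()]. Missing concentrations are coded
#' as an empty field or `NA`.
#'
#' @param path file path.
#' @return A `sample_table`.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(dataset = "unknown", units = "pg/ml", assay = "")
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([a-z_]+)\\s*:\\s*(.*)$", ml))[[1L]]
    if (length(m) == 3L && m[2L] %in% names(meta)) meta[[m[2L]]] <- m[3L]
  }
  body <- lines[!grepl("^#", lines)]
  n_fields <- lengths(strsplit(body, ",", fixed = TRUE))
  # trailing empty fields are dropped by strsplit; count separators instead
  n_sep <- nchar(body) - nchar(gsub(",", "", body, fixed = TRUE))
  if (length(body) < 2L) stop("no data rows in ", path)
  if (any(n_sep[-1L] != n_sep[1L])) {
    bad <- which(n_sep[-1L] != n_sep[1L])[1L] + 1L
    stop("malformed row at line ", which(!grepl("^#", lines))[bad],
         " of ", path, ": expected ", n_sep[1L] + 1L, " fields")
  }
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE, na.strings = c("", "NA"))
  tab <- tryCatch(
    sample_table(df, dataset = meta$dataset, units = meta$units,
                 assay = meta$assay),
    error = function(e) stop("invalid sample table in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  tab
}

#' Write a sample table to CSV
#'
#' Writes metadata as `# key: value` comment lines followed by a standard
#' comma-delimited body, so that [read_sample_table()] round-trips records and
#' metadata exactly.
#'
#' @param table a `sample_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path) {
  stopifnot(inherits(table, "sample_table"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", c("dataset", "units", "assay"),
                     c(attr(table, "dataset"), attr(table, "units"),
                       attr(table, "assay"))), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("Sample table '%s' (%s): %d records, %d subjects, visits %s\n",
              attr(x, "dataset"), attr(x, "units"), nrow(x),
              length(unique(x$subject_id)),
              paste(sort(unique(x$visit)), collapse = ",")))
  cat(sprintf("  fluids: %s | time points: %s | missing concentrations: %d\n",
              paste(sort(unique(x$fluid)), collapse = ", "),
              paste(sort(unique(x$time_point)), collapse = ", "),
              sum(is.na(x$concentration_pg_ml))))
  invisible(x)
}

#' Reshape a sample table to a complete-case subjects-by-visits matrix
#'
#' Extracts one stratum (fluid, time-point, optionally treatment) and pivots
#' it to an n x k matrix with one row per subject and one column per requested
#' visit. Only subjects with a non-missing concentration at every requested
#' visit are retained (complete-case analysis); dropped subjects are reported
#' via `message()`.
#'
#' @param table a `sample_table`.
#' @param fluid `"saliva"` or `"plasma"`.
#' @param visits integer vector of visits to use; default all visits present
#'   in the stratum.
#' @param time_point which sampling time to use; default `"baseline"`.
#' @param treatment optional treatment filter; `NULL` (default) pools over
#'   treatments (at most one record per subject x visit is then required).
#' @param log_scale if `TRUE`, values are natural-log transformed.
#' @return numeric matrix with subject row names, visit column names and a
#'   `"scale"` attribute (`"log"` or `"raw"`).
#' @export
to_wide <- function(table, fluid, visits = NULL, time_point = "baseline",
                    treatment = NULL, log_scale = TRUE) {
  stopifnot(inherits(table, "sample_table"))
  sub <- table[table$fluid == fluid & table$time_point == time_point, ,
               drop = FALSE]
  if (!is.null(treatment)) sub <- sub[sub$treatment %in% treatment, ,
                                      drop = FALSE]
  if (is.null(visits)) visits <- sort(unique(sub$visit))
  if (length(visits) == 0L) stop("no visits requested")
  sub <- sub[sub$visit %in% visits, , drop = FALSE]
  subjects <- unique(sub$subject_id)
  m <- matrix(NA_real_, nrow = length(subjects), ncol = length(visits),
              dimnames = list(subjects, paste0("visit_", visits)))
  for (i in seq_len(nrow(sub))) {
    r <- which(subjects == sub$subject_id[i])
    cc <- which(visits == sub$visit[i])
    if (!is.na(m[r, cc]))
      stop("multiple records for subject ", sub$subject_id[i], ", visit ",
           sub$visit[i], " in the requested stratum")
    m[r, cc] <- sub$concentration_pg_ml[i]
  }
  complete <- stats::complete.cases(m)
  if (any(!complete))
    message(sum(!complete), " subject(s) dropped (incomplete cases): ",
            paste(subjects[!complete], collapse = ", "))
  m <- m[complete, , drop = FALSE]
  m <- m[order(rownames(m)), , drop = FALSE]
  if (nrow(m) < 2L)
    stop("insufficient data: fewer than 2 complete subjects")
  if (log_scale) m <- log(m)
  attr(m, "scale") <- if (log_scale) "log" else "raw"
  m
}
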