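# Orthonormal within-subject contrast matrix, (k-1) x k.
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)            # k x (k-1)
  C <- sweep(C, 2L, sqrt(colSums(C^2)), "/")
  t(C)
}

# Greenhouse-Geisser epsilon for an effect, from the covariance of the
# contrast-transformed subject scores Z (n x d). epsilon in (1/d, 1].
gg_epsilon <- function(Z) {
  S <- stats::cov(Z)
  d <- ncol(Z)
  sum(diag(S))^2 / (d * sum(S^2))
}

huynh_feldt_epsilon <- function(eps_gg, n, d) {
  min(1, (n * d * eps_gg - 2) / (d * (n - 1 - d * eps_gg)))
}

#' One-way repeated-measures ANOVA with sphericity correction
#'
#' Within-subject F-test of equal condition means: F = MS_condition /
#' MS_(condition x subject). When the condition covariance matrix violates
#' sphericity the degrees of freedom are multiplied by the
#' Greenhouse-Geisser epsilon (Huynh-Feldt available), giving the fractional
#' dfs conventional for repeated-measures hormone analyses. With k = 2
#' conditions epsilon is exactly 1 and F equals the squared paired t.
#'
#' @param m complete numeric matrix, subjects in rows, conditions in columns
#'   (k >= 2).
#' @param correction `"greenhouse-geisser"` (default), `"huynh-feldt"` or
#'   `"none"`.
#' @return object of class `"rm_anova"`: a data.frame with the effect's F,
#'   uncorrected dfs, `epsilon`, corrected dfs and p-value.
#' @export
rm_anova_oneway <- function(m, correction = c("greenhouse-geisser",
                                              "huynh-feldt", "none")) {
  correction <- match.arg(correction)
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 2L, k >= 2L, !anyNA(m))
  grand <- mean(m)
  row_means <- rowMeans(m); col_means <- colMeans(m)
  ss_cond <- n * sum((col_means - grand)^2)
  ss_err <- sum((m - outer(row_means, col_means, "+") + grand)^2)
  df1 <- k - 1L; df2 <- (n - 1L) * (k - 1L)
  ms_cond <- ss_cond / df1; ms_err <- ss_err / df2
  if (ms_err == 0) stop("degenerate input: zero error variance")
  f <- ms_cond / ms_err
  Z <- m %*% t(orthonormal_contrasts(k))
  eps <- switch(correction,
                "greenhouse-geisser" = gg_epsilon(Z),
                "huynh-feldt" = huynh_feldt_epsilon(gg_epsilon(Z), n, k - 1L),
                "none" = 1)
  if (k == 2L) eps <- 1  # single contrast: sphericity holds by construction
  out <- data.frame(effect = "condition", f_stat = f,
                    df1 = df1, df2 = df2, epsilon = eps,
                    df1_corr = eps * df1, df2_corr = eps * df2,
                    p_value = stats::pf(f, eps * df1, eps * df2,
                                        lower.tail = FALSE))
  structure(out, class = c("rm_anova", "data.frame"),
            correction = correction, n_subjects = n)
}

#' Two-way fully-within repeated-measures ANOVA (treatment x time)
#'
#' For a complete crossed within-subject design, tests both main effects and
#' the interaction, each against its own subject-interaction error term. The
#' treatment-by-time interaction is tested on ((A-1)(B-1), (A-1)(B-1)(n-1))
#' df; with four treatments and two time-points that is (3, 3(n-1)).
#' Greenhouse-Geisser epsilons are reported per effect; p-values use
#' uncorrected dfs by default (set `correction` to correct them), matching
#' the common practice of leaving two-level factors uncorrected.
#'
#' @param table a [sample_table()] containing baseline and
#'   post-administration records under each treatment.
#' @param fluid which fluid to analyse.
#' @param treatments treatment levels forming the first factor.
#' @param log_scale analyse natural-log concentrations (default `TRUE`).
#' @param correction `"none"` (default), `"greenhouse-geisser"` or
#'   `"huynh-feldt"`, applied to every within effect's p-value.
#' @param on_incomplete `"drop"` (default) removes subjects with missing
#'   cells, reporting them in a message; `"error"` treats any missing cell
#'   as an error naming the subject and cell.
#' @return object of class `"rm_anova"`: data.frame with one row per effect
#'   (treatment, time, treatment:time). The complete-case cell matrix is
#'   attached as attribute `"cells"` for post-hoc analysis.
#' @export
rm_anova_twoway <- function(table, fluid,
                            treatments = c("spray", "nebuliser",
                                           "intravenous", "placebo"),
                            log_scale = TRUE,
                            correction = c("none", "greenhouse-geisser",
                                           "huynh-feldt"),
                            on_incomplete = c("drop", "error")) {
  correction <- match.arg(correction)
  cells <- cell_matrix(table, fluid, treatments, log_scale,
                       on_incomplete = on_incomplete)
  A <- length(treatments); B <- 2L
  n <- nrow(cells)
  Y <- array(cells, dim = c(n, B, A))  # columns ordered time within treatment
  grand <- mean(Y)
  subj <- apply(Y, 1L, mean)
  a_means <- apply(Y, 3L, mean); b_means <- apply(Y, 2L, mean)
  ab_means <- apply(Y, c(2L, 3L), mean)
  sa <- apply(Y, c(1L, 3L), mean)  # subject x treatment
  sb <- apply(Y, c(1L, 2L), mean)  # subject x time

  ss_a <- n * B * sum((a_means - grand)^2)
  ss_b <- n * A * sum((b_means - grand)^2)
  dev_ab <- sweep(sweep(ab_means, 1L, b_means, "-"), 2L, a_means, "-") + grand
  ss_ab <- n * sum(dev_ab^2)
  ss_sa <- B * sum((sa - outer(subj, a_means, "+") + grand)^2)
  ss_sb <- A * sum((sb - outer(subj, b_means, "+") + grand)^2)
  fit_full <- array(NA_real_, dim(Y))
  for (i in seq_len(n)) for (b in seq_len(B)) for (a in seq_len(A))
    fit_full[i, b, a] <- subj[i] + (a_means[a] - grand) +
      (b_means[b] - grand) + dev_ab[b, a] +
      (sa[i, a] - subj[i] - a_means[a] + grand) +
      (sb[i, b] - subj[i] - b_means[b] + grand)
  ss_sab <- sum((Y - fit_full)^2)

  dfs <- list(treatment = c(A - 1L, (A - 1L) * (n - 1L)),
              time = c(B - 1L, (B - 1L) * (n - 1L)),
              `treatment:time` = c((A - 1L) * (B - 1L),
                                   (A - 1L) * (B - 1L) * (n - 1L)))
  sss <- list(treatment = c(ss_a, ss_sa), time = c(ss_b, ss_sb),
              `treatment:time` = c(ss_ab, ss_sab))

  # per-effect epsilon from orthonormal effect contrasts on the cell matrix
  CA <- orthonormal_contrasts(A); CB <- orthonormal_contrasts(B)
  ones_a <- matrix(1 / A, 1L, A); ones_b <- matrix(1 / B, 1L, B)
  # cells columns ordered (time within treatment): contrast = kron(treat, time)
  Ms <- list(treatment = kronecker(CA, ones_b),
             time = kronecker(ones_a, CB),
             `treatment:time` = kronecker(CA, CB))
  rows <- lapply(names(dfs), function(effn) {
    df1 <- dfs[[effn]][1L]; df2 <- dfs[[effn]][2L]
    ms1 <- sss[[effn]][1L] / df1; ms2 <- sss[[effn]][2L] / df2
    if (ms2 == 0) stop("degenerate input: zero error variance for ", effn)
    f <- ms1 / ms2
    Z <- cells %*% t(Ms[[effn]])
    eps <- if (df1 == 1L) 1 else switch(correction,
      "huynh-feldt" = huynh_feldt_epsilon(gg_epsilon(Z), n, df1),
      gg_epsilon(Z))
    use_eps <- if (correction == "none") 1 else eps
    data.frame(effect = effn, f_stat = f, df1 = df1, df2 = df2,
               epsilon = eps, df1_corr = use_eps * df1,
               df2_corr = use_eps * df2,
               p_value = stats::pf(f, use_eps * df1, use_eps * df2,
                                   lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("rm_anova", "data.frame"),
            correction = correction, n_subjects = n, cells = cells,
            treatments = treatments)
}

# Complete-case subject x (treatment x time) cell matrix; columns ordered
# baseline, post within each treatment. on_incomplete = "drop" removes
# subjects with missing cells (message), "error" reports them instead.
cell_matrix <- function(table, fluid, treatments, log_scale = TRUE,
                        on_incomplete = c("drop", "error")) {
  on_incomplete <- match.arg(on_incomplete)
  stopifnot(inherits(table, "sample_table"))
  sub <- table[table$fluid == fluid & table$treatment %in% treatments, ,
               drop = FALSE]
  subjects <- sort(unique(sub$subject_id))
  cols <- as.vector(outer(TIME_POINTS, treatments,
                          function(tp, tr) paste(tr, tp, sep = ".")))
  m <- matrix(NA_real_, length(subjects), length(cols),
              dimnames = list(subjects, cols))
  for (i in seq_len(nrow(sub))) {
    cc <- paste(sub$treatment[i], sub$time_point[i], sep = ".")
    m[sub$subject_id[i], cc] <- sub$concentration_pg_ml[i]
  }
  complete <- stats::complete.cases(m)
  if (sum(complete) < 2L || (on_incomplete == "error" && any(!complete))) {
    bad <- subjects[!complete][1L]
    stop("incomplete design: subject ", bad, " lacks cell(s) ",
         paste(cols[is.na(m[bad, ])], collapse = ", "))
  }
  if (any(!complete))
    message(sum(!complete), " subject(s) dropped (missing cells): ",
            paste(subjects[!complete], collapse = ", "))
  m <- m[complete, , drop = FALSE]
  if (log_scale) m <- log(m)
  m
}

#' @export
print.rm_anova <- function(x, ...) {
  corr <- attr(x, "correction")
  cat(sprintf("Repeated-measures ANOVA (n = %d subjects, correction: %s)\n",
              attr(x, "n_subjects"), corr))
  for (i in seq_len(nrow(x))) {
    if (corr == "none")
      cat(sprintf("  %-16s F(%g, %g) = %.2f, p = %.3g (GG eps = %.2f)\n",
                  x$effect[i], x$df1[i], x$df2[i], x$f_stat[i],
                  x$p_value[i], x$epsilon[i]))
    else
      cat(sprintf("  %-16s F(%.2f, %.2f) = %.2f, p = %.3g (eps = %.2f)\n",
                  x$effect[i], x$df1_corr[i], x$df2_corr[i], x$f_stat[i],
                  x$p_value[i], x$epsilon[i]))
  }
  invisible(x)
}

#' Paired t-test
#'
#' Thin wrapper around [stats::t.test()] for two paired vectors, returning
#' the statistic, df = n - 1 and the two-tailed p-value.
#'
#' @param a,b equal-length numeric vectors (n >= 2), paired by position.
#' @return list with `t_stat`, `df`, `p_value`, `n`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  if (stats::sd(a - b) == 0)
    stop("degenerate input: zero variance of paired differences")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n = length(a))
}

#' Tukey-adjusted paired baseline-vs-post contrasts
#'
#' Follows up a significant treatment-by-time interaction: for each
#' treatment, a paired t-test of baseline vs post-administration on that
#' contrast's own error term (df = n - 1), with family-wise adjustment via
#' the studentized-range distribution. The family size is the number of cell
#' means spanned by the contrasts (2 per treatment), so each adjusted
#' p-value is `ptukey(|t| * sqrt(2), nmeans, df)`.
#'
#' @param anova an `rm_anova` object from [rm_anova_twoway()] (its attached
#'   cell matrix is reused), or a cell matrix as produced internally.
#' @param treatments treatments to contrast; default those of the fit.
#' @return data.frame with one row per treatment: `t_stat`, `df`,
#'   `p_unadjusted`, `p_adjusted`.
#' @export
posthoc_paired_tukey <- function(anova, treatments = NULL) {
  cells <- if (is.matrix(anova)) anova else attr(anova, "cells")
  if (is.null(cells)) stop("no cell matrix available; fit rm_anova_twoway first")
  if (is.null(treatments))
    treatments <- attr(anova, "treatments") %||%
      unique(sub("\\..*$", "", colnames(cells)))
  n <- nrow(cells)
  if (n < 3L) stop("need at least 3 complete pairs per contrast")
  nmeans <- 2L * length(treatments)
  out <- do.call(rbind, lapply(treatments, function(tr) {
    bas <- cells[, paste(tr, "baseline", sep = ".")]
    post <- cells[, paste(tr, "post_administration", sep = ".")]
    d <- post - bas
    se <- stats::sd(d) / sqrt(n)
    # null contrast with zero spread: define t = 0 rather than 0/0
    t_stat <- if (se == 0 && mean(d) == 0) 0 else mean(d) / se
    df <- n - 1L
    data.frame(treatment = tr, t_stat = t_stat, df = df,
               p_unadjusted = 2 * stats::pt(abs(t_stat), df,
                                            lower.tail = FALSE),
               p_adjusted = stats::ptukey(abs(t_stat) * sqrt(2), nmeans, df,
                                          lower.tail = FALSE))
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
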