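# Cohort-level statistics: dual-rater averaging, splenomegaly
# classification, descriptive tables and the multiple linear regression of
# spleen volume on length and the single-slice predictors. The regression
# is computed from first principles (QR least squares, standardized betas,
# t and F tests) so it can be verified against a brute-force
# normal-equations oracle.

REGRESSION_PREDICTORS <- c("age", "spleen_length", "l1_ap", "l1_tv",
                           "l1_area", "abd_ap", "abd_tv", "abd_circ",
                           "canal_area")

PREDICTOR_LABELS <- c(
  age = "Age", spleen_length = "Spleen length", spleen_volume = "Spleen volume",
  l1_ap = "L1 AP diameter (cm)", l1_tv = "L1 transverse diameter (cm)",
  l1_area = "L1 transverse area (cm2)", abd_ap = "Abdomen AP diameter (cm)",
  abd_tv = "Abdomen transverse diameter (cm)",
  abd_circ = "Abdomen circumference (cm)", canal_area = "Spinal canal area (cm)")

#' Average duplicate rater measurements into one record per subject
#'
#' Every measurement is taken twice by independent raters and only the
#' average is analysed. Numeric fields are averaged over the available
#' (non-missing) rater values; subjects with a single record pass through
#' and are flagged, as are fields where only one rater contributed. More
#' than two raters for one subject is an error.
#'
#' @param records data.frame with `subject_id`, `rater_id` and measurement
#'   columns (see [write_cohort_csv()]).
#' @return data.frame with one row per subject, `rater_id` replaced by
#'   `n_raters`, plus a logical `single_rater` flag and an `incomplete_pair`
#'   flag marking subjects where some field had only one value.
#' @export
average_raters <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("subject_id", "rater_id") %in% names(records)))
  counts <- table(records$subject_id)
  if (any(counts > 2))
    stop("more than two raters for subject(s): ",
         paste(names(counts)[counts > 2], collapse = ", "))
  num_cols <- intersect(cohort_numeric_cols, names(records))
  keep_cols <- setdiff(names(records), c("rater_id", num_cols))
  out <- lapply(split(records, records$subject_id), function(grp) {
    row <- grp[1, keep_cols, drop = FALSE]
    incomplete <- FALSE
    for (col in num_cols) {
      v <- grp[[col]][!is.na(grp[[col]])]
      row[[col]] <- if (length(v)) mean(v) else NA_real_
      if (nrow(grp) == 2 && length(v) == 1) incomplete <- TRUE
    }
    row$n_raters <- nrow(grp)
    row$single_rater <- nrow(grp) == 1
    row$incomplete_pair <- incomplete
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$subject_id), , drop = FALSE]
}

#' Classify spleen volumes as normal or high
#'
#' `high` iff the volume strictly exceeds the threshold (a volume exactly at
#' the threshold is normal). No clinical cut-off is assumed: the threshold
#' is a required, explicit configuration value.
#'
#' @param volume numeric vector of spleen volumes, cm^3.
#' @param threshold splenomegaly cut-off, cm^3, `> 0`.
#' @return factor with levels `normal`, `high`; `NA` where volume is missing.
#' @export
classify_volume <- function(volume, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold > 0)
  factor(ifelse(volume > threshold, "high", "normal"),
         levels = c("normal", "high"))
}

#' Descriptive statistics per variable, optionally stratified by sex
#'
#' Sample mean, sample SD (n-1 denominator) and SEM (`SD / sqrt(n)`) for
#' each variable; `n` counts non-missing values. Groups with fewer than two
#' observations get a mean but no SD/SEM.
#'
#' @param cohort data.frame of per-subject measurements.
#' @param variables columns to describe (default: every known numeric
#'   measurement present).
#' @param group_by optional grouping column name, e.g. `"sex"`.
#' @return long data.frame with columns `group`, `variable`, `n`, `mean`,
#'   `sd`, `sem`.
#' @export
describe_cohort <- function(cohort, variables = NULL, group_by = NULL) {
  stopifnot(is.data.frame(cohort))
  if (is.null(variables))
    variables <- intersect(cohort_numeric_cols, names(cohort))
  groups <- if (is.null(group_by)) list(all = cohort)
            else split(cohort, cohort[[group_by]])
  rows <- list()
  for (g in names(groups)) for (v in variables) {
    x <- groups[[g]][[v]]
    x <- x[!is.na(x)]
    n <- length(x)
    s <- if (n >= 2) stats::sd(x) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      group = g, variable = v, n = n,
      mean = if (n) mean(x) else NA_real_,
      sd = s, sem = s / sqrt(n))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multiple linear regression with standardized coefficients
#'
#' Ordinary least squares of the response on the predictors, computed from
#' first principles: coefficients by Householder QR, standard errors from
#' the unbiased residual variance, standardized betas
#' `beta_j = B_j * s_xj / s_y` from sample SDs, two-sided p-values from the
#' t distribution with `n - k - 1` degrees of freedom, and the overall
#' ANOVA `F = (R^2/k) / ((1-R^2)/(n-k-1))`. Rows with any missing value are
#' dropped (listwise deletion) and the retained n is reported.
#'
#' @param cohort data.frame of per-subject measurements.
#' @param response response column (default `"spleen_volume"`).
#' @param predictors predictor columns (default: age, spleen length and the
#'   seven single-slice metrics).
#' @return an object of class `regression_result`: list with `coefficients`
#'   (data.frame rows `(Constant)` + predictors with columns `B, SE, beta,
#'   t, p`), `r_squared`, `anova_f`, `anova_p`, `df`, `n`, `n_dropped`.
#' @export
ols_fit <- function(cohort, response = "spleen_volume",
                    predictors = REGRESSION_PREDICTORS) {
  stopifnot(is.data.frame(cohort), response %in% names(cohort),
            all(predictors %in% names(cohort)))
  dat <- cohort[, c(response, predictors), drop = FALSE]
  complete <- stats::complete.cases(dat)
  dat <- dat[complete, , drop = FALSE]
  n <- nrow(dat); k <- length(predictors)
  if (n <= k + 1)
    stop("need more than ", k + 1, " complete cases; have ", n)
  sds <- vapply(dat, stats::sd, numeric(1))
  if (any(sds[predictors] == 0))
    stop("constant predictor(s): ",
         paste(predictors[sds[predictors] == 0], collapse = ", "))

  y <- dat[[response]]
  X <- cbind(`(Constant)` = 1, as.matrix(dat[, predictors, drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  B <- qr.coef(qx, y)
  fitted <- drop(X %*% B)
  rss <- sum((y - fitted)^2)
  df <- n - k - 1
  sigma2 <- rss / df
  unpivot <- order(qx$pivot)
  xtx_inv <- chol2inv(qr.R(qx))[unpivot, unpivot, drop = FALSE]
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- B / se
  pval <- 2 * stats::pt(-abs(tval), df)
  beta <- c(NA_real_, B[-1] * sds[predictors] / sds[response])
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  f <- (r2 / k) / ((1 - r2) / df)
  coefs <- data.frame(term = names(B), B = unname(B), SE = unname(se),
                      beta = unname(beta), t = unname(tval), p = unname(pval))
  structure(list(coefficients = coefs, r_squared = r2, anova_f = f,
                 anova_p = stats::pf(f, k, df, lower.tail = FALSE),
                 df = df, n = n, n_dropped = sum(!complete)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, digits = 3, ...) {
  cat(sprintf("Linear regression: n = %d (%d dropped), R Square = %.2f, ANOVA F = %.2f, P = %.3g\n",
              x$n, x$n_dropped, x$r_squared, x$anova_f, x$anova_p))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Run the full cohort analysis and emit the study tables
#'
#' Produces the four result tables of a volumetry study from a per-subject
#' measurement table: volume classification counts, sex-stratified volume
#' and length, overall descriptives for every analysis variable (both SD
#' and SEM are printed), and the regression of spleen volume on the nine
#' predictors. Written as `table3.csv` .. `table6.csv` plus `report.txt`
#' when `out_dir` is given.
#'
#' @param cohort per-subject data.frame (after [average_raters()] if the
#'   input had duplicate raters).
#' @param volume_threshold required splenomegaly cut-off, cm^3.
#' @param out_dir optional output directory for CSVs and the text report.
#' @return list with `classification`, `by_sex`, `descriptives`,
#'   `regression` and the `report` text lines, invisibly when `out_dir` is
#'   written.
#' @export
run_study <- function(cohort, volume_threshold, out_dir = NULL) {
  stopifnot(is.data.frame(cohort), "spleen_volume" %in% names(cohort))
  cls <- classify_volume(cohort$spleen_volume, volume_threshold)
  n_known <- sum(!is.na(cls))
  classification <- data.frame(
    volume_class = c("normal", "high"),
    frequency = as.integer(table(cls)),
    percentage = round(100 * as.integer(table(cls)) / max(n_known, 1), 1))

  by_sex <- describe_cohort(cohort,
                            variables = intersect(c("spleen_volume",
                                                    "spleen_length"),
                                                  names(cohort)),
                            group_by = if ("sex" %in% names(cohort)) "sex")
  descriptives <- describe_cohort(cohort)
  regression <- ols_fit(cohort)

  report <- c(
    sprintf("Subjects analysed: %d", nrow(cohort)),
    sprintf("Volume classification (threshold %.1f cm^3): %d normal (%.1f%%), %d high (%.1f%%)",
            volume_threshold, classification$frequency[1],
            classification$percentage[1], classification$frequency[2],
            classification$percentage[2]),
    "",
    "Volume and length by sex (mean +/- SD):",
    vapply(split(by_sex, seq_len(nrow(by_sex))), function(r)
      sprintf("  %s %s: %.2f +/- %.2f (SEM %.3f, n=%d)", r$group,
              r$variable, r$mean, r$sd, r$sem, r$n), character(1)),
    "",
    sprintf("Regression of spleen volume on %d predictors: R Square = %.2f, ANOVA F = %.2f, P = %.3g, n = %d",
            length(REGRESSION_PREDICTORS), regression$r_squared,
            regression$anova_f, regression$anova_p, regression$n))

  result <- list(classification = classification, by_sex = by_sex,
                 descriptives = descriptives, regression = regression,
                 report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(classification, file.path(out_dir, "table3.csv"),
                     row.names = FALSE)
    utils::write.csv(by_sex, file.path(out_dir, "table4.csv"),
                     row.names = FALSE)
    utils::write.csv(descriptives, file.path(out_dir, "table5.csv"),
                     row.names = FALSE)
    coefs <- regression$coefficients
    coefs$term <- ifelse(coefs$term %in% names(PREDICTOR_LABELS),
                         PREDICTOR_LABELS[coefs$term], coefs$term)
    utils::write.csv(coefs, file.path(out_dir, "table6.csv"),
                     row.names = FALSE)
    writeLines(report, file.path(out_dir, "report.txt"))
    return(invisible(result))
  }
  result
}
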