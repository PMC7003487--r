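#' Two-group comparison of a continuous feature
#'
#' Two-sample t-test between the non-response (NRG) and response (RG)
#' groups; pooled-variance Student's test by default, Welch via
#' `var_equal = FALSE`. Two groups with zero pooled variance and equal
#' means are reported as `t = 0, p = 1` rather than an error.
#'
#' @param values_nrg,values_rg Numeric vectors (each length >= 2).
#' @param var_equal Pooled-variance test if `TRUE` (default).
#' @param alpha Two-sided significance level (default 0.05).
#' @return A one-row data.frame: `mean_nrg`, `mean_rg`, `statistic`, `df`,
#'   `p_value`, `significant`.
#' @examples
#' compare_continuous(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
compare_continuous <- function(values_nrg, values_rg, var_equal = TRUE,
                               alpha = 0.05) {
  if (length(values_nrg) < 2L || length(values_rg) < 2L)
    glyconact_error("each group needs at least 2 values",
                    "glyconact_insufficient_data_error")
  if (anyNA(values_nrg) || anyNA(values_rg))
    glyconact_error("missing values in group comparison",
                    "glyconact_input_error")
  if (stats::var(values_nrg) + stats::var(values_rg) == 0) {
    equal <- mean(values_nrg) == mean(values_rg)
    tt <- list(statistic = if (equal) 0 else Inf,
               parameter = length(values_nrg) + length(values_rg) - 2,
               p.value = if (equal) 1 else 0)
  } else {
    tt <- stats::t.test(values_nrg, values_rg, var.equal = var_equal)
  }
  data.frame(mean_nrg = mean(values_nrg), mean_rg = mean(values_rg),
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, significant = tt$p.value < alpha)
}

#' Association test for a categorical clinical variable
#'
#' Test choice follows the classical clinical-table convention: 2x2 tables
#' use the chi-squared test with Yates continuity correction; larger tables
#' the Pearson chi-squared test; whenever any expected cell count falls
#' below `fisher_threshold`, Fisher's exact test is used instead (exact for
#' 2x2; for larger tables exact by network algorithm, or Monte Carlo via
#' `fisher_simulate`).
#'
#' @param table An r x c contingency table of non-negative integer counts
#'   (matrix), rows = variable levels, columns = outcome groups.
#' @param fisher_threshold Expected-count threshold triggering Fisher's
#'   exact test (default 5).
#' @param fisher_simulate Use Monte Carlo p-values for r x c Fisher tests.
#' @param alpha Significance level.
#' @return A one-row data.frame: `test`, `statistic` (`NA` for Fisher),
#'   `p_value`, `significant`; the table is attached as attribute `table`.
#' @examples
#' compare_categorical(matrix(c(13, 12, 11, 13), 2, byrow = TRUE))
#' @export
compare_categorical <- function(table, fisher_threshold = 5,
                                fisher_simulate = FALSE, alpha = 0.05) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m)))
    glyconact_error("contingency table must hold non-negative integers",
                    "glyconact_input_error")
  if (nrow(m) < 2L || ncol(m) < 2L)
    glyconact_error("contingency table must be at least 2x2",
                    "glyconact_input_error")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    glyconact_error("degenerate contingency table: zero margin",
                    "glyconact_input_error")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < fisher_threshold)) {
    ft <- stats::fisher.test(m, simulate.p.value = fisher_simulate)
    res <- data.frame(test = "fisher-exact", statistic = NA_real_,
                      p_value = ft$p.value,
                      significant = ft$p.value < alpha)
  } else {
    correct <- nrow(m) == 2L && ncol(m) == 2L
    ct <- stats::chisq.test(m, correct = correct)
    res <- data.frame(
      test = if (correct) "chisq-yates" else "chisq-pearson",
      statistic = unname(ct$statistic), p_value = ct$p.value,
      significant = ct$p.value < alpha)
  }
  attr(res, "table") <- m
  res
}

#' Per-feature ROC AUC with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney probability that a random responder's value
#' exceeds a random non-responder's (ties count 0.5). Default orientation
#' is "as-is" (higher value predicts responder); `orientation =
#' "directional"` flips features whose responder mean is lower so the AUC
#' lands at or above 0.5. The 95 percent confidence interval uses DeLong's
#' variance estimator, truncated to [0, 1].
#'
#' @param values Numeric feature values.
#' @param labels Logical (or 0/1) responder labels, same length.
#' @param orientation `"as-is"` (default) or `"directional"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row data.frame: `auc`, `ci_low`, `ci_high`, `direction`.
#' @examples
#' per_feature_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' @export
per_feature_auc <- function(values, labels, orientation = c("as-is", "directional"),
                            conf_level = 0.95) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  if (length(values) != length(labels) || anyNA(values) || anyNA(labels))
    glyconact_error("values and labels must align with no missing entries",
                    "glyconact_input_error")
  if (!any(labels) || all(labels))
    glyconact_error("both responder classes must be present",
                    "glyconact_single_class_error")
  flip <- orientation == "directional" &&
    mean(values[labels]) < mean(values[!labels])
  v <- if (flip) -values else values
  r <- pROC::roc(response = labels, predictor = v, direction = "<",
                 levels = c(FALSE, TRUE), quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(r, conf.level = conf_level,
                                      method = "delong"))
  data.frame(auc = as.numeric(pROC::auc(r)),
             ci_low = max(0, ci[1]), ci_high = min(1, ci[3]),
             direction = if (flip) "inverted" else "as-is",
             stringsAsFactors = FALSE)
}

#' Univariate screening table for glycan features
#'
#' One row per feature (peak or trait): group means, pooled t-test p-value,
#' AUC with DeLong 95 percent CI and a significance flag -- the layout of a
#' glycome group-comparison table. No multiple-testing correction is
#' applied by default (`p_adjust = "none"`); Benjamini-Hochberg is
#' available via `p_adjust = "BH"`.
#'
#' @param features A data.frame of numeric feature columns (plus an
#'   ignored `sample_id` column if present).
#' @param responder Logical responder labels, one per row.
#' @param var_equal,orientation,alpha Passed to the underlying tests.
#' @param p_adjust Multiple-testing correction method (default `"none"`).
#' @return A data.frame: `feature`, `mean_nrg`, `mean_rg`, `p_value`,
#'   `auc`, `ci_low`, `ci_high`, `significant`.
#' @export
compare_features <- function(features, responder, var_equal = TRUE,
                             orientation = "as-is", alpha = 0.05,
                             p_adjust = "none") {
  responder <- as.logical(responder)
  features <- features[, setdiff(names(features), c("sample_id", "timepoint")),
                       drop = FALSE]
  rows <- lapply(names(features), function(f) {
    x <- features[[f]]
    tt <- compare_continuous(x[!responder], x[responder],
                             var_equal = var_equal, alpha = alpha)
    au <- per_feature_auc(x, responder, orientation = orientation)
    data.frame(feature = f, mean_nrg = tt$mean_nrg, mean_rg = tt$mean_rg,
               p_value = tt$p_value, auc = au$auc, ci_low = au$ci_low,
               ci_high = au$ci_high, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_value < alpha
  out
}
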