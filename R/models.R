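#' Fit a logistic response-prediction model with optional stepwise selection
#'
#' Maximum-likelihood logistic regression of the responder outcome on
#' forced clinical terms plus (optionally) stepwise-selected candidate
#' terms. Forced terms are always retained; selection only ever operates on
#' the candidates. Selection criteria: `"aic"` (default), `"bic"`, or
#' `"p"` (likelihood-ratio enter/remove thresholds `p_enter`/`p_remove`).
#'
#' Complete or quasi-complete separation is detected (fitted probabilities
#' pinned at 0/1 with runaway coefficients) and flagged; a ridge-stabilized
#' refit is then reported alongside so downstream ROC analysis has finite,
#' usable scores.
#'
#' @param data A data.frame holding the outcome and all terms.
#' @param forced Character vector of forced model terms (may be empty).
#' @param candidates Character vector of candidate terms for selection.
#' @param outcome Name of the logical outcome column (default `responder`).
#' @param selection `"none"`, `"forward"`, `"backward"` or
#'   `"bidirectional"` (default `"none"`).
#' @param criterion `"aic"`, `"bic"` or `"p"`.
#' @param p_enter,p_remove Thresholds for the `"p"` criterion.
#' @param name Model name carried in the result.
#' @return An object of class `glyco_model`: list with `name`, `terms`,
#'   `coefficients` (term, estimate, se, z, p), `fitted` (probabilities),
#'   `converged`, `separation`, `ridge_stabilized`, `aic`, and the
#'   underlying `fit`.
#' @export
fit_logistic <- function(data, forced = character(0),
                         candidates = character(0),
                         outcome = "responder",
                         selection = c("none", "forward", "backward",
                                       "bidirectional"),
                         criterion = c("aic", "bic", "p"),
                         p_enter = 0.05, p_remove = 0.10,
                         name = "model") {
  selection <- match.arg(selection)
  criterion <- match.arg(criterion)
  if (length(intersect(forced, candidates)))
    glyconact_error("forced and candidate terms must be disjoint",
                    "glyconact_model_error")
  y <- data[[outcome]]
  if (is.null(y) || !any(y) || all(y))
    glyconact_error("outcome must be present with both classes",
                    "glyconact_single_class_error")
  n <- nrow(data)
  rhs <- function(terms) if (length(terms)) paste(terms, collapse = " + ") else "1"
  form <- function(terms)
    stats::as.formula(paste(outcome, "~", rhs(terms)), env = environment())

  fit_glm <- function(terms)
    suppressWarnings(stats::glm(form(terms), data = data, family = stats::binomial()))

  if (selection == "none" || length(candidates) == 0L) {
    fit <- fit_glm(c(forced, if (selection == "none") candidates))
  } else if (criterion == "p") {
    fit <- stepwise_p(data, form, fit_glm, forced, candidates, selection,
                      p_enter, p_remove)
  } else {
    k <- if (criterion == "bic") log(n) else 2
    start <- if (selection == "backward") c(forced, candidates) else forced
    fit <- suppressWarnings(stats::step(
      fit_glm(start),
      scope = list(lower = form(forced), upper = form(c(forced, candidates))),
      direction = if (selection == "bidirectional") "both" else selection,
      k = k, trace = 0))
  }

  selected <- attr(stats::terms(fit), "term.labels")
  p_hat <- stats::fitted(fit)
  separation <- any(p_hat > 1 - 1e-8 | p_hat < 1e-8) &&
    max(abs(stats::coef(fit)), na.rm = TRUE) > 10
  ridge <- FALSE
  if (separation || !fit$converged) {
    rg <- ridge_logistic(stats::model.matrix(fit), as.numeric(y))
    p_hat <- rg$fitted
    ridge <- TRUE
  }
  cf <- summary(fit)$coefficients
  structure(list(
    name = name,
    terms = selected,
    forced = forced,
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              se = cf[, 2], z = cf[, 3], p = cf[, 4],
                              row.names = NULL, stringsAsFactors = FALSE),
    fitted = as.numeric(p_hat),
    converged = fit$converged,
    separation = separation,
    ridge_stabilized = ridge,
    aic = stats::AIC(fit),
    fit = fit
  ), class = "glyco_model")
}

# Forward/backward/bidirectional selection on likelihood-ratio p-values
# (enter if the best candidate's LRT p < p_enter; remove if the weakest
# non-forced term's p > p_remove).
stepwise_p <- function(data, form, fit_glm, forced, candidates, selection,
                       p_enter, p_remove) {
  current <- if (selection == "backward") c(forced, candidates) else forced
  repeat {
    changed <- FALSE
    fit0 <- fit_glm(current)
    if (selection %in% c("forward", "bidirectional")) {
      pool <- setdiff(candidates, current)
      if (length(pool)) {
        pvals <- vapply(pool, function(tm) {
          stats::anova(fit0, fit_glm(c(current, tm)), test = "LRT")$`Pr(>Chi)`[2]
        }, numeric(1))
        if (min(pvals) < p_enter) {
          current <- c(current, pool[which.min(pvals)])
          changed <- TRUE
        }
      }
    }
    if (selection %in% c("backward", "bidirectional")) {
      removable <- setdiff(current, forced)
      if (length(removable)) {
        fit1 <- fit_glm(current)
        pvals <- vapply(removable, function(tm) {
          stats::anova(fit_glm(setdiff(current, tm)), fit1,
                       test = "LRT")$`Pr(>Chi)`[2]
        }, numeric(1))
        if (max(pvals) > p_remove) {
          current <- setdiff(current, removable[which.max(pvals)])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  fit_glm(current)
}

# Ridge-penalized logistic IRLS (intercept unpenalized); used only as a
# stabilizer when ordinary ML separates.
ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 100, tol = 1e-10) {
  beta <- numeric(ncol(X))
  pen <- diag(rep(lambda, ncol(X)))
  if ("(Intercept)" %in% colnames(X)) pen[1, 1] <- 0
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    beta_new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  list(coefficients = as.numeric(beta),
       fitted = as.numeric(stats::plogis(X %*% beta)))
}

#' Empirical ROC analysis of model scores
#'
#' Computes the empirical ROC curve over all score thresholds, the AUC with
#' a DeLong 95 percent confidence interval, and the Youden-index operating
#' point (maximizing sensitivity + specificity - 1); threshold ties are
#' resolved toward the higher specificity.
#'
#' @param probabilities Numeric per-sample scores.
#' @param labels Logical responder labels.
#' @param conf_level Confidence level for the AUC CI.
#' @return An object of class `roc_result`: list with `curve` (data.frame
#'   `fpr`, `tpr`, `threshold`), `auc`, `ci_low`, `ci_high`, `threshold`,
#'   `sensitivity`, `specificity`.
#' @examples
#' roc_analysis(c(0.1, 0.4, 0.6, 0.9), c(FALSE, FALSE, TRUE, TRUE))
#' @export
roc_analysis <- function(probabilities, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    glyconact_error("both responder classes must be present",
                    "glyconact_single_class_error")
  r <- pROC::roc(response = labels, predictor = probabilities,
                 direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(r, conf.level = conf_level,
                                      method = "delong"))
  curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities,
                      threshold = r$thresholds)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  j <- r$sensitivities + r$specificities - 1
  best <- which(j > max(j) - 1e-12)
  best <- best[which.max(r$specificities[best])]
  structure(list(
    curve = curve,
    auc = as.numeric(pROC::auc(r)),
    ci_low = max(0, ci[1]), ci_high = min(1, ci[3]),
    threshold = r$thresholds[best],
    sensitivity = r$sensitivities[best],
    specificity = r$specificities[best]
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f), sens %.1f%% / spec %.1f%% at %.3g\n",
              x$auc, x$ci_low, x$ci_high, 100 * x$sensitivity,
              100 * x$specificity, x$threshold))
  invisible(x)
}

#' @export
print.glyco_model <- function(x, ...) {
  cat(sprintf("<glyco_model '%s'> terms: %s\n", x$name,
              paste(if (length(x$terms)) x$terms else "(intercept only)",
                    collapse = " + ")))
  if (x$separation) cat("  note: separation detected; ridge-stabilized fit reported\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Build the three NACT response-prediction models
#'
#' The clinical model uses age (dichotomized at 60), histology and
#' chemotherapy regimen; the glyco model the three glycan peaks GP4
#' (H3N4F1), GP6 (H3N5F1) and GP18 (H5N4F1S1); the combined model the
#' union of both term sets. In `mode = "paper"` the glycan terms are fixed
#' to those three peaks; in `mode = "discovery"` they are instead chosen by
#' stepwise selection over all 24 panel peaks (clinical terms stay forced
#' in the combined model). Each model is fitted in-sample and paired with a
#' full ROC analysis.
#'
#' @param cohort A data.frame holding clinical covariates, `responder`, and
#'   the 24 peak columns (percent); pre-treatment rows are used if a
#'   `timepoint` column is present.
#' @param mode `"paper"` (fixed glycan terms, default) or `"discovery"`.
#' @param selection,criterion,p_enter,p_remove Stepwise options for
#'   discovery mode (default bidirectional AIC).
#' @return A named list (`clinical`, `glyco`, `combined`) of lists with
#'   elements `model` (`glyco_model`) and `roc` (`roc_result`).
#' @export
build_paper_models <- function(cohort, mode = c("paper", "discovery"),
                               selection = "bidirectional",
                               criterion = "aic",
                               p_enter = 0.05, p_remove = 0.10) {
  mode <- match.arg(mode)
  if ("timepoint" %in% names(cohort))
    cohort <- cohort[cohort$timepoint == "pre", , drop = FALSE]
  check_profile_columns(cohort)
  cohort <- encode_clinical(cohort)
  clinical_terms <- c(attr(cohort, "age_term"), "histology", "regimen")
  glyco_terms <- c("GP4", "GP6", "GP18")
  all_peaks <- panel_peak_ids()

  one <- function(name, forced, candidates, sel) {
    m <- fit_logistic(cohort, forced = forced, candidates = candidates,
                      selection = sel, criterion = criterion,
                      p_enter = p_enter, p_remove = p_remove, name = name)
    list(model = m, roc = roc_analysis(m$fitted, cohort$responder))
  }
  if (mode == "paper") {
    list(
      clinical = one("clinical", clinical_terms, character(0), "none"),
      glyco = one("glyco", glyco_terms, character(0), "none"),
      combined = one("combined", c(clinical_terms, glyco_terms),
                     character(0), "none"))
  } else {
    list(
      clinical = one("clinical", clinical_terms, character(0), "none"),
      glyco = one("glyco", character(0), all_peaks, selection),
      combined = one("combined", clinical_terms, all_peaks, selection))
  }
}

#' Cross-validated AUC of a fixed-term logistic model
#'
#' Stratified k-fold cross-validation: the model is refitted on each
#' training split and out-of-fold predicted probabilities are pooled into a
#' single ROC AUC. Used for honest evaluation (the headline in-sample ROC
#' mirrors the reference analysis, which did not cross-validate).
#'
#' @param data Data.frame with outcome and terms.
#' @param terms Model terms (no selection inside folds).
#' @param outcome Outcome column name.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return The cross-validated AUC (numeric scalar).
#' @export
cv_model_auc <- function(data, terms, outcome = "responder", k = 5,
                         seed = 1) {
  y <- as.logical(data[[outcome]])
  folds <- integer(nrow(data))
  withr::with_seed(seed, {
    folds[y] <- sample(rep_len(seq_len(k), sum(y)))
    folds[!y] <- sample(rep_len(seq_len(k), sum(!y)))
  })
  form <- stats::as.formula(paste(
    outcome, "~", if (length(terms)) paste(terms, collapse = " + ") else "1"))
  scores <- numeric(nrow(data))
  for (f in seq_len(k)) {
    train <- folds != f
    fit <- suppressWarnings(stats::glm(form, data = data[train, , drop = FALSE],
                                       family = stats::binomial()))
    scores[!train] <- stats::predict(fit, newdata = data[!train, , drop = FALSE],
                                     type = "response")
  }
  per_feature_auc(scores, y)$auc
}
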