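.becker_grades <- c("1a", "1b", "2", "3")
.clinical_levels <- list(
  sex = c("male", "female"),
  site = c("U", "M", "L", "Overlapping"),
  histology = c("Adenocarcinoma", "SRC", "Other"),
  regimen = c("DOS", "XELOX", "Other"))

#' Becker-grade responder rule
#'
#' Histopathological tumor regression after NACT is graded on the Becker
#' scale (1a complete regression, 1b < 10 percent residual tumor, 2 =
#' 10-50 percent residual, 3 > 50 percent residual). Grades 1a, 1b and 2
#' define the response group; grade 3 the non-response group.
#'
#' @param grade Character vector of grades in `{"1a","1b","2","3"}`.
#' @return Logical vector: `TRUE` for responders.
#' @examples
#' becker_responder(c("1b", "3"))
#' @export
becker_responder <- function(grade) {
  grade <- as.character(grade)
  bad <- setdiff(unique(grade[!is.na(grade)]), .becker_grades)
  if (length(bad) || anyNA(grade))
    glyconact_error(sprintf("invalid Becker grade(s): %s",
                            paste(c(bad, if (anyNA(grade)) "NA"),
                                  collapse = ", ")),
                    "glyconact_grade_error")
  grade != "3"
}

#' Read a clinical metadata CSV
#'
#' Expected columns: `sample_id`, `age`, `sex`, `site`, `histology`,
#' `regimen`, `becker_grade` and optionally `timepoint` (`pre`/`post`,
#' defaults to `pre`). The responder label is always derived from the
#' Becker grade via [becker_responder()], never read from the file, and an
#' `age_group` dichotomy at 60 years is added. Eligibility bounds
#' (18 < age < 80) are validated as warnings.
#'
#' @param path File path.
#' @return A validated clinical data.frame with derived `age_group` and
#'   `responder` columns.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' @rdname read_clinical_csv
#' @param clinical A clinical data.frame (same schema as the CSV).
#' @export
validate_clinical <- function(clinical) {
  need <- c("sample_id", "age", "sex", "site", "histology", "regimen",
            "becker_grade")
  missing <- setdiff(need, names(clinical))
  if (length(missing))
    glyconact_error(sprintf("missing clinical column(s): %s",
                            paste(missing, collapse = ", ")),
                    "glyconact_schema_error")
  if (!"timepoint" %in% names(clinical)) clinical$timepoint <- "pre"
  if (!all(clinical$timepoint %in% c("pre", "post")))
    glyconact_error("timepoint must be 'pre' or 'post'",
                    "glyconact_schema_error")
  dup <- duplicated(clinical[, c("sample_id", "timepoint")])
  if (any(dup))
    glyconact_error("duplicated sample_id within a timepoint",
                    "glyconact_schema_error")
  for (v in names(.clinical_levels)) {
    bad <- setdiff(unique(clinical[[v]]), .clinical_levels[[v]])
    if (length(bad))
      glyconact_error(sprintf("unknown %s level(s): %s", v,
                              paste(bad, collapse = ", ")),
                      "glyconact_schema_error")
  }
  if (any(clinical$age <= 18 | clinical$age >= 80))
    glyconact_warning("age outside the 18-80 eligibility window",
                      "glyconact_eligibility_warning")
  clinical$responder <- becker_responder(clinical$becker_grade)
  clinical$age_group <- factor(ifelse(clinical$age <= 60, "<=60", ">60"),
                               levels = c("<=60", ">60"))
  clinical
}

#' Summarize a cohort the way a clinical baseline table does
#'
#' Counts and percentages per covariate level, overall and within the
#' response (RG) / non-response (NRG) groups, plus the Becker grade
#' distribution and the responder rate.
#'
#' @param clinical A validated clinical data.frame (pre-treatment rows are
#'   used if `timepoint` is present).
#' @return A list with `n`, `responder_rate` (percent), `by_covariate`
#'   (data.frame: variable, level, counts and percentages overall/NRG/RG)
#'   and `grades` (counts and percentages per Becker grade).
#' @examples
#' cl <- data.frame(sample_id = paste0("s", 1:4), age = c(50, 65, 58, 70),
#'                  sex = "male", site = "U", histology = "Other",
#'                  regimen = "XELOX", becker_grade = c("1b", "2", "3", "3"))
#' summarize_cohort(validate_clinical(cl))$responder_rate
#' @export
summarize_cohort <- function(clinical) {
  if (!nrow(clinical))
    glyconact_error("empty cohort", "glyconact_input_error")
  if ("timepoint" %in% names(clinical))
    clinical <- clinical[clinical$timepoint == "pre", , drop = FALSE]
  n <- nrow(clinical)
  resp <- clinical$responder
  pct <- function(k, d) if (d > 0) 100 * k / d else rep(NA_real_, length(k))
  rows <- lapply(c("age_group", "sex", "site", "histology", "regimen"),
                 function(v) {
    levs <- if (v == "age_group") c("<=60", ">60") else .clinical_levels[[v]]
    x <- factor(as.character(clinical[[v]]), levels = levs)
    data.frame(variable = v, level = levs,
               n_total = as.integer(table(x)),
               pct_total = pct(as.integer(table(x)), n),
               n_nrg = as.integer(table(x[!resp])),
               pct_nrg = pct(as.integer(table(x[!resp])), sum(!resp)),
               n_rg = as.integer(table(x[resp])),
               pct_rg = pct(as.integer(table(x[resp])), sum(resp)),
               stringsAsFactors = FALSE)
  })
  grades <- factor(clinical$becker_grade, levels = .becker_grades)
  list(n = n,
       n_rg = sum(resp), n_nrg = sum(!resp),
       responder_rate = 100 * sum(resp) / n,
       by_covariate = do.call(rbind, rows),
       grades = data.frame(grade = .becker_grades,
                           n = as.integer(table(grades)),
                           pct = pct(as.integer(table(grades)), n)))
}

#' Encode clinical covariates for modelling
#'
#' Age enters as the `<=60` / `>60` dichotomy (the baseline-table encoding)
#' unless `age_continuous = TRUE`; histology and regimen are dummy-coded
#' factors with the most frequent level of the reference cohort as
#' reference (`Other` and `XELOX` respectively).
#'
#' @param clinical A validated clinical data.frame.
#' @param age_continuous Use continuous age instead of the dichotomy.
#' @return The data.frame with model-ready factor columns.
#' @export
encode_clinical <- function(clinical, age_continuous = FALSE) {
  clinical$age_group <- factor(as.character(clinical$age_group),
                               levels = c("<=60", ">60"))
  clinical$histology <- stats::relevel(
    factor(clinical$histology, levels = .clinical_levels$histology), "Other")
  clinical$regimen <- stats::relevel(
    factor(clinical$regimen, levels = .clinical_levels$regimen), "XELOX")
  clinical$sex <- factor(clinical$sex, levels = .clinical_levels$sex)
  clinical$site <- factor(clinical$site, levels = .clinical_levels$site)
  attr(clinical, "age_term") <- if (age_continuous) "age" else "age_group"
  clinical
}
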