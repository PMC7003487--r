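# Reference summary statistics from a 49-patient locally advanced gastric
# cancer NACT cohort (24 non-responders, 25 responders): group-mean relative
# abundances (percent of total chromatogram area) and two-sided t-test
# p-values per peak, plus clinical covariate frequencies. These summaries
# are the calibration targets of the cohort simulator and the worked
# examples of the trait calculator; no patient-level data are included.

.reference_peaks <- data.frame(
  peak_id = paste0("GP", 1:24),
  mean_nrg = c(0.137, 0.623, 0.013, 22.580, 0.157, 6.588, 0.353, 20.344,
               10.108, 6.424, 0.691, 1.005, 0.033, 15.783, 1.840, 2.313,
               0.620, 7.218, 0.778, 0.027, 0.495, 0.003, 0.835, 1.033),
  mean_rg  = c(0.182, 0.828, 0.005, 27.448, 0.144, 7.577, 0.348, 19.628,
               9.925, 6.097, 0.725, 0.820, 0.014, 12.944, 1.496, 2.255,
               0.521, 5.976, 0.737, 0.011, 0.519, 0.002, 0.792, 1.006),
  p_value  = c(0.048, 0.075, 0.179, 0.003, 0.460, 0.042, 0.902, 0.264,
               0.678, 0.446, 0.542, 0.276, 0.209, 0.007, 0.017, 0.657,
               0.146, 0.028, 0.446, 0.168, 0.692, 0.622, 0.689, 0.859),
  stringsAsFactors = FALSE)

.reference_n <- c(nrg = 24L, rg = 25L)

#' Reference cohort group-mean glycan profiles
#'
#' Group-mean relative abundances (percent) of the 24 panel peaks in the
#' reference gastric-cancer NACT cohort, for the non-response group (NRG,
#' n = 24) and the response group (RG, n = 25), with the reported two-sided
#' t-test p-value per peak. These means are the default centres of
#' [simulation_config()].
#'
#' @return A data.frame with columns `peak_id`, `mean_nrg`, `mean_rg`,
#'   `p_value`.
#' @export
reference_group_profiles <- function() .reference_peaks

#' Reference cohort group sizes
#' @return Named integer vector `c(nrg = 24, rg = 25)`.
#' @export
reference_group_sizes <- function() .reference_n

#' Per-peak between-subject dispersion implied by the reference cohort
#'
#' The reference study reports group means and t-test p-values but no
#' standard deviations. Assuming a pooled-variance two-sample t-test at
#' n = 24/25 (df 47), each printed p-value implies a pooled standard
#' deviation `sd = |mean_rg - mean_nrg| / (t * sqrt(1/24 + 1/25))`. The
#' simulator's default dispersion is this implied SD expressed as a
#' coefficient of variation against the pooled mean, used as the log-scale
#' sigma of the logistic-normal noise and capped at `cap` for numerical
#' sanity on near-zero peaks.
#'
#' @param cap Upper bound on the log-scale sigma (default 2.5).
#' @return Named numeric vector of 24 log-scale sigmas.
#' @export
reference_dispersion <- function(cap = 2.5) {
  tab <- .reference_peaks
  n1 <- .reference_n[["nrg"]]; n2 <- .reference_n[["rg"]]
  tval <- stats::qt(1 - tab$p_value / 2, df = n1 + n2 - 2)
  sd_pooled <- abs(tab$mean_rg - tab$mean_nrg) / (tval * sqrt(1 / n1 + 1 / n2))
  pooled_mean <- (n1 * tab$mean_nrg + n2 * tab$mean_rg) / (n1 + n2)
  sigma <- pmin(sd_pooled / pooled_mean, cap)
  names(sigma) <- tab$peak_id
  sigma
}

#' Reference cohort clinical covariate frequencies
#'
#' Per-group frequencies of the clinical covariates in the reference cohort
#' (counts as published; the regimen row of the source table is internally
#' inconsistent, so counts are normalized within each group as given).
#'
#' @return A list with one element per covariate; each element is a list of
#'   per-group probability vectors (`nrg`, `rg`) over the covariate levels.
#' @export
reference_clinical_frequencies <- function() {
  norm <- function(x) x / sum(x)
  list(
    age_group = list(levels = c("<=60", ">60"),
                     nrg = norm(c(13, 11)), rg = norm(c(12, 13))),
    sex = list(levels = c("male", "female"),
               nrg = norm(c(16, 8)), rg = norm(c(18, 7))),
    site = list(levels = c("U", "M", "L", "Overlapping"),
                nrg = norm(c(6, 8, 9, 1)), rg = norm(c(5, 7, 7, 6))),
    histology = list(levels = c("Adenocarcinoma", "SRC", "Other"),
                     nrg = norm(c(4, 4, 16)), rg = norm(c(7, 2, 16))),
    regimen = list(levels = c("DOS", "XELOX", "Other"),
                   nrg = norm(c(6, 11, 5)), rg = norm(c(4, 12, 8)))
  )
}

#' Reference Becker-grade distribution among responders
#'
#' In the reference cohort tumor regression was grade 1b in 10 patients,
#' grade 2 in 15, grade 3 in 24; all responders are grade 1b or 2 and all
#' non-responders grade 3.
#'
#' @return Probability vector over grades `1a`, `1b`, `2` for responders.
#' @export
reference_responder_grades <- function() {
  c("1a" = 0, "1b" = 10 / 25, "2" = 15 / 25)
}
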