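#' Configuration for the two-group cohort simulator
#'
#' Defaults emulate the reference NACT study: group sizes 24 (NRG) / 25
#' (RG); group mean profiles equal to the reference group-mean relative
#' abundances (renormalized to sum to 100); between-subject dispersion per
#' peak equal to the log-scale sigma implied by the reference t-tests
#' ([reference_dispersion()]); clinical covariate frequencies and Becker
#' grade distribution as published; no pre/post treatment effect. Noise is
#' logistic-normal: a mean-zero Gaussian perturbation per peak in log
#' space, mapped back to the percent simplex (Dirichlet available via
#' `noise_model = "dirichlet"`). Raw totals are log-normal so total-area
#' normalization is exercised.
#'
#' @param n_nrg,n_rg Group sizes.
#' @param mean_nrg,mean_rg Group mean profiles (percent, named by peak).
#' @param dispersion Log-scale sigma(s): scalar or per-peak vector, >= 0.
#' @param noise_model `"logistic-normal"` (default) or `"dirichlet"`.
#' @param dirichlet_precision Concentration for the Dirichlet option.
#' @param covariate_frequencies As [reference_clinical_frequencies()].
#' @param grade_probs Becker grade probabilities for responders.
#' @param paired_effect Named log-scale post-minus-pre shift per peak
#'   (default all zero: the null treatment effect).
#' @param within_dispersion Within-subject (pre vs post) log-scale sigma.
#' @param total_area_meanlog,total_area_sdlog Log-normal raw total area.
#' @param seed Integer seed (required; all randomness flows from it).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_nrg = 24, n_rg = 25,
                              mean_nrg = NULL, mean_rg = NULL,
                              dispersion = reference_dispersion(),
                              noise_model = c("logistic-normal", "dirichlet"),
                              dirichlet_precision = 100,
                              covariate_frequencies = reference_clinical_frequencies(),
                              grade_probs = reference_responder_grades(),
                              paired_effect = NULL,
                              within_dispersion = 0.05,
                              total_area_meanlog = log(1e6),
                              total_area_sdlog = 0.2,
                              seed) {
  if (missing(seed) || !is.numeric(seed))
    glyconact_error("simulation_config requires an integer seed",
                    "glyconact_config_error")
  ref <- reference_group_profiles()
  ids <- panel_peak_ids()
  if (is.null(mean_nrg)) mean_nrg <- stats::setNames(ref$mean_nrg, ids)
  if (is.null(mean_rg)) mean_rg <- stats::setNames(ref$mean_rg, ids)
  mean_nrg <- 100 * mean_nrg[ids] / sum(mean_nrg[ids])
  mean_rg <- 100 * mean_rg[ids] / sum(mean_rg[ids])
  if (any(!is.finite(mean_nrg)) || any(mean_nrg <= 0) ||
      any(!is.finite(mean_rg)) || any(mean_rg <= 0))
    glyconact_error("group mean profiles must be strictly positive on all peaks",
                    "glyconact_config_error")
  if (n_nrg < 2 || n_rg < 2)
    glyconact_error("group sizes must be >= 2", "glyconact_config_error")
  if (length(dispersion) == 1L) dispersion <- stats::setNames(rep(dispersion, 24), ids)
  dispersion <- dispersion[ids]
  if (anyNA(dispersion) || any(dispersion < 0))
    glyconact_error("dispersion must be non-negative for every peak",
                    "glyconact_config_error")
  if (is.null(paired_effect)) paired_effect <- stats::setNames(rep(0, 24), ids)
  structure(list(
    n_nrg = as.integer(n_nrg), n_rg = as.integer(n_rg),
    mean_nrg = mean_nrg, mean_rg = mean_rg,
    dispersion = dispersion,
    noise_model = match.arg(noise_model),
    dirichlet_precision = dirichlet_precision,
    covariate_frequencies = covariate_frequencies,
    grade_probs = grade_probs,
    paired_effect = paired_effect[ids],
    within_dispersion = within_dispersion,
    total_area_meanlog = total_area_meanlog,
    total_area_sdlog = total_area_sdlog,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# --- logistic-normal machinery -------------------------------------------

row_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.calib_cache <- new.env(parent = emptyenv())

# Log-space centre such that E[softmax(mu + eps)] hits the target mean
# fractions. The expectation has no closed form, so mu is found by a
# fixed-point iteration against a large common-random-numbers Monte Carlo
# sample (deterministic: internal fixed seed, caller RNG untouched).
calibrate_logmean <- function(target_frac, sigma, n_mc = 2e5, iter = 12) {
  if (all(sigma == 0)) return(log(target_frac))
  key <- paste(signif(c(target_frac, sigma), 12), collapse = ",")
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- length(target_frac)
  eps <- withr::with_seed(190919, matrix(stats::rnorm(n_mc * k), n_mc, k))
  eps <- sweep(eps, 2, sigma, `*`)
  mu <- log(target_frac)
  for (i in seq_len(iter)) {
    m_hat <- colMeans(row_softmax(sweep(eps, 2, mu, `+`)))
    mu <- mu + log(target_frac) - log(m_hat)
  }
  .calib_cache[[key]] <- mu
  mu
}

draw_profiles <- function(n, mean_pct, config) {
  frac <- mean_pct / 100
  if (config$noise_model == "dirichlet") {
    alpha <- config$dirichlet_precision * frac
    g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
                nrow = n)
    return(100 * g / rowSums(g))
  }
  sigma <- config$dispersion
  if (all(sigma == 0)) return(matrix(mean_pct, n, length(frac), byrow = TRUE))
  mu <- calibrate_logmean(frac, sigma)
  eps <- sweep(matrix(stats::rnorm(n * length(frac)), n), 2, sigma, `*`)
  100 * row_softmax(sweep(eps, 2, mu, `+`))
}

draw_covariates <- function(n, group, freqs, grade_probs) {
  draw <- function(spec) sample(spec$levels, n, replace = TRUE,
                                prob = spec[[group]])
  age_group <- draw(freqs$age_group)
  # continuous age consistent with the dichotomy (cohort mean ~57.6 y)
  age <- ifelse(age_group == "<=60",
                stats::runif(n, 40, 60), stats::runif(n, 60.5, 79))
  grade <- if (group == "rg") {
    sample(names(grade_probs), n, replace = TRUE, prob = grade_probs)
  } else rep("3", n)
  data.frame(age = round(age, 1), sex = draw(freqs$sex),
             site = draw(freqs$site), histology = draw(freqs$histology),
             regimen = draw(freqs$regimen), becker_grade = grade,
             stringsAsFactors = FALSE)
}

#' Simulate a two-group NACT cohort with raw peak areas
#'
#' Per sample: a logistic-normal draw around the group's mean profile on
#' the percent simplex, scaled by a random log-normal total area into raw
#' peak areas; clinical covariates drawn per the configured group-specific
#' frequencies; Becker grades assigned per group (responders 1a/1b/2,
#' non-responders 3) and the responder label derived via
#' [becker_responder()]. Byte-identical output for identical config.
#'
#' @param config A [simulation_config()].
#' @return A list: `areas` (data.frame `sample_id` + `GP1..GP24` raw
#'   areas), `clinical` (validated clinical data.frame with `group`
#'   column), and `profiles` (the underlying percent profiles).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config, id_prefix = "S") {
  ids <- panel_peak_ids()
  n <- config$n_nrg + config$n_rg
  group <- rep(c("nrg", "rg"), c(config$n_nrg, config$n_rg))
  prof <- rbind(draw_profiles(config$n_nrg, config$mean_nrg, config),
                draw_profiles(config$n_rg, config$mean_rg, config))
  colnames(prof) <- ids
  total <- stats::rlnorm(n, config$total_area_meanlog, config$total_area_sdlog)
  areas <- prof / 100 * total
  sample_id <- sprintf("%s%03d", id_prefix, seq_len(n))
  clin <- rbind(
    draw_covariates(config$n_nrg, "nrg", config$covariate_frequencies,
                    config$grade_probs),
    draw_covariates(config$n_rg, "rg", config$covariate_frequencies,
                    config$grade_probs))
  clin <- cbind(data.frame(sample_id = sample_id, stringsAsFactors = FALSE),
                clin)
  clin$timepoint <- "pre"
  clin <- validate_clinical(clin)
  clin$group <- toupper(group)
  list(areas = cbind(data.frame(sample_id = sample_id,
                                stringsAsFactors = FALSE),
                     as.data.frame(areas)),
       clinical = clin,
       profiles = cbind(data.frame(sample_id = sample_id,
                                   stringsAsFactors = FALSE),
                        as.data.frame(prof)))
}

#' Simulate paired pre/post-NACT profiles under a configurable effect
#'
#' Pre-treatment samples are drawn as in [simulate_cohort()]; each
#' post-treatment profile is its patient's pre-treatment profile perturbed
#' in log space by fresh within-subject noise (`within_dispersion`) plus
#' the configured `paired_effect` (default zero: the null treatment
#' effect), then renormalized and rescaled by a fresh total area.
#'
#' @param config A [simulation_config()] (for the pre/post reference
#'   design use `n_nrg = 18, n_rg = 22`).
#' @return As [simulate_cohort()], with pre and post rows per patient
#'   (same `sample_id`, `timepoint` distinguishing them).
#' @export
simulate_pre_post <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    pre <- simulate_cohort_impl(config)
    ids <- panel_peak_ids()
    prof_pre <- as.matrix(pre$profiles[, ids])
    n <- nrow(prof_pre)
    z <- log(prof_pre / 100)
    if (config$within_dispersion > 0)
      z <- z + matrix(stats::rnorm(n * length(ids),
                                   sd = config$within_dispersion), n)
    z <- sweep(z, 2, config$paired_effect, `+`)
    prof_post <- 100 * row_softmax(z)
    total <- stats::rlnorm(n, config$total_area_meanlog,
                           config$total_area_sdlog)
    areas_post <- prof_post / 100 * total
    post_clin <- pre$clinical
    post_clin$timepoint <- "post"
    mk <- function(m) cbind(data.frame(sample_id = pre$areas$sample_id,
                                       stringsAsFactors = FALSE),
                            as.data.frame(m))
    pre$clinical$group <- NULL
    post_clin$group <- NULL
    list(areas = rbind(cbind(pre$areas, timepoint = "pre"),
                       cbind(mk(areas_post), timepoint = "post")),
         clinical = rbind(pre$clinical, post_clin),
         profiles = rbind(cbind(pre$profiles, timepoint = "pre"),
                          cbind(mk(prof_post), timepoint = "post")))
  })
}

#' Emit synthetic chromatogram traces for a set of raw areas
#'
#' Optional extra for exercising the integration stage: each peak becomes a
#' Gaussian of the requested area centred in its retention window (sd =
#' width/8), sampled on a regular time grid spanning the windows.
#'
#' @param areas Raw-area data.frame (`sample_id` + peak columns).
#' @param windows Integration window set (as [read_windows()]).
#' @param points_per_min Sampling density of the grid (default 60).
#' @return A long data.frame `sample_id`, `time_min`, `intensity`.
#' @export
simulate_traces <- function(areas, windows, points_per_min = 60) {
  span <- range(c(windows$start_min, windows$end_min))
  tt <- seq(span[1], span[2], by = 1 / points_per_min)
  out <- lapply(seq_len(nrow(areas)), function(i) {
    y <- numeric(length(tt))
    for (j in seq_len(nrow(windows))) {
      a <- areas[i, windows$peak_id[j]]
      centre <- (windows$start_min[j] + windows$end_min[j]) / 2
      sd <- (windows$end_min[j] - windows$start_min[j]) / 8
      y <- y + a * stats::dnorm(tt, centre, sd)
    }
    data.frame(sample_id = areas$sample_id[i], time_min = tt, intensity = y,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
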