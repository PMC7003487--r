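test_that("simulation config validates its inputs", {
  expect_error(simulation_config(), class = "glyconact_config_error")
  expect_error(simulation_config(seed = 1, dispersion = -0.1),
               class = "glyconact_config_error")
  expect_error(simulation_config(seed = 1, n_nrg = 1),
               class = "glyconact_config_error")
  bad_mean <- setNames(c(0, rep(1, 23)), panel_peak_ids())
  expect_error(simulation_config(seed = 1, mean_nrg = bad_mean),
               class = "glyconact_config_error")
  cfg <- simulation_config(seed = 1)
  expect_equal(sum(cfg$mean_nrg), 100, tolerance = 1e-9)
  expect_equal(sum(cfg$mean_rg), 100, tolerance = 1e-9)
})

test_that("same config and seed give byte-identical cohorts", {
  cfg <- simulation_config(seed = 202)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  # and the seed actually matters
  expect_false(identical(simulate_cohort(cfg),
                         simulate_cohort(simulation_config(seed = 203))))
})

test_that("zero dispersion collapses every profile onto its group mean", {
  cfg <- simulation_config(seed = 7, dispersion = 0, n_nrg = 3, n_rg = 3)
  sim <- simulate_cohort(cfg)
  prof <- normalize_areas(sim$areas)
  m <- as.matrix(prof[, -1])
  resp <- sim$clinical$responder
  for (i in which(!resp))
    expect_equal(unname(m[i, ]), unname(cfg$mean_nrg), tolerance = 1e-9)
  for (i in which(resp))
    expect_equal(unname(m[i, ]), unname(cfg$mean_rg), tolerance = 1e-9)
})

test_that("simulated samples pass profile invariants and carry coherent labels", {
  cfg <- simulation_config(seed = 97)
  sim <- simulate_cohort(cfg)
  prof <- normalize_areas(sim$areas)
  expect_equal(rowSums(prof[, -1]), rep(100, nrow(prof)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(as.matrix(prof[, -1]) >= 0))
  expect_identical(sim$clinical$responder,
                   becker_responder(sim$clinical$becker_grade))
  expect_identical(sim$clinical$group[sim$clinical$responder][1], "RG")
  expect_equal(sum(!sim$clinical$responder), 24)
  expect_equal(sum(sim$clinical$responder), 25)
})

test_that("per-peak sample means recover the configured group means at large n", {
  cfg <- simulation_config(n_nrg = 10000, n_rg = 10000, seed = 404)
  sim <- simulate_cohort(cfg)
  prof <- as.matrix(sim$profiles[, panel_peak_ids()])
  resp <- sim$clinical$responder
  z_all <- c()
  for (g in list(list(rows = !resp, target = cfg$mean_nrg),
                 list(rows = resp, target = cfg$mean_rg))) {
    m <- colMeans(prof[g$rows, ])
    se <- apply(prof[g$rows, ], 2, sd) / sqrt(sum(g$rows))
    z_all <- c(z_all, (m - g$target) / se)
  }
  expect_lte(sum(abs(z_all) > 3), 2)   # 48 checks; allow chance excursions
  expect_lt(max(abs(z_all)), 4)
})

test_that("covariate frequencies and grade mix recover at large n", {
  cfg <- simulation_config(n_nrg = 4000, n_rg = 4000, seed = 405)
  sim <- simulate_cohort(cfg)
  cl <- sim$clinical
  freqs <- reference_clinical_frequencies()
  p_male_rg <- mean(cl$sex[cl$responder] == "male")
  expect_equal(p_male_rg, freqs$sex$rg[1], tolerance = 0.03)
  p_u_nrg <- mean(cl$site[!cl$responder] == "U")
  expect_equal(p_u_nrg, freqs$site$nrg[1], tolerance = 0.03)
  grades_rg <- table(cl$becker_grade[cl$responder]) / sum(cl$responder)
  expect_equal(unname(grades_rg[["1b"]]), 0.4, tolerance = 0.03)
  expect_true(all(cl$becker_grade[!cl$responder] == "3"))
})

test_that("dirichlet noise option is mean-unbiased and deterministic", {
  cfg <- simulation_config(seed = 55, noise_model = "dirichlet",
                           n_nrg = 5000, n_rg = 2)
  sim <- simulate_cohort(cfg)
  m <- colMeans(as.matrix(
    sim$profiles[!sim$clinical$responder, panel_peak_ids()]))
  expect_equal(unname(m), unname(cfg$mean_nrg), tolerance = 0.15)
  expect_identical(sim, simulate_cohort(cfg))
})

test_that("pre/post pairing: zero noise reproduces pre exactly", {
  cfg <- simulation_config(seed = 9, n_nrg = 4, n_rg = 4,
                           within_dispersion = 0)
  pp <- simulate_pre_post(cfg)
  ids <- panel_peak_ids()
  pre <- pp$profiles[pp$profiles$timepoint == "pre", ids]
  post <- pp$profiles[pp$profiles$timepoint == "post", ids]
  expect_equal(as.matrix(post), as.matrix(pre), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(pp$clinical$sample_id[pp$clinical$timepoint == "pre"],
                   pp$clinical$sample_id[pp$clinical$timepoint == "post"])
})

test_that("a large targeted paired effect is detected on GP4, others only via closure", {
  eff <- setNames(rep(0, 24), panel_peak_ids())
  eff["GP4"] <- 0.4
  rejected <- logical(20)
  shadow_ratio <- numeric(20)
  for (rep in 1:20) {
    cfg <- simulation_config(seed = 3000 + rep, n_nrg = 18, n_rg = 22,
                             paired_effect = eff)
    pp <- simulate_pre_post(cfg)
    pre <- pp$profiles[pp$profiles$timepoint == "pre", ]
    post <- pp$profiles[pp$profiles$timepoint == "post", ]
    rejected[rep] <- t.test(post$GP4 - pre$GP4, paired = FALSE)$p.value < 0.05
    lfc <- function(pk) abs(mean(log(post[[pk]] / pre[[pk]])))
    # closure spreads a single-peak shift onto the rest of the simplex, but
    # only as the common renormalization factor, far below the target shift
    shadow_ratio[rep] <- max(vapply(c("GP8", "GP12", "GP14"), lfc,
                                    numeric(1))) / lfc("GP4")
  }
  expect_gte(mean(rejected), 0.95)      # power ~ 1 on the shifted peak
  expect_lt(max(shadow_ratio), 0.5)
})

test_that("calibrated cohorts separate groups better than null cohorts (in-sample glyco AUC)", {
  auc_cal <- auc_null <- numeric(50)
  null_mean <- setNames(reference_group_profiles()$mean_nrg, panel_peak_ids())
  for (rep in 1:50) {
    sim <- simulate_cohort(simulation_config(seed = 5000 + rep))
    cohort <- merge(sim$clinical, normalize_areas(sim$areas), by = "sample_id")
    m <- fit_logistic(cohort, forced = c("GP4", "GP6", "GP18"))
    auc_cal[rep] <- roc_analysis(m$fitted, cohort$responder)$auc

    sim0 <- simulate_cohort(simulation_config(mean_rg = null_mean,
                                              seed = 6000 + rep))
    cohort0 <- merge(sim0$clinical, normalize_areas(sim0$areas),
                     by = "sample_id")
    m0 <- fit_logistic(cohort0, forced = c("GP4", "GP6", "GP18"))
    auc_null[rep] <- roc_analysis(m0$fitted, cohort0$responder)$auc
  }
  expect_true(all(auc_cal > 0.5 & auc_cal < 1))
  expect_gt(mean(auc_cal), mean(auc_null))
})

test_that("default dispersion makes the six reference-significant peaks the most detectable", {
  sig_peaks <- c("GP1", "GP4", "GP6", "GP14", "GP15", "GP18")
  pmat <- matrix(NA_real_, 30, 24, dimnames = list(NULL, panel_peak_ids()))
  for (rep in 1:30) {
    sim <- simulate_cohort(simulation_config(seed = 7000 + rep))
    prof <- normalize_areas(sim$areas)
    resp <- sim$clinical$responder
    for (pk in panel_peak_ids())
      pmat[rep, pk] <- compare_continuous(prof[[pk]][!resp],
                                          prof[[pk]][resp])$p_value
  }
  flagged <- colMeans(pmat < 0.05)
  expect_gt(mean(flagged[sig_peaks]),
            mean(flagged[setdiff(panel_peak_ids(), sig_peaks)]))
  # every one of the six exceeds the average background flag rate
  expect_true(all(flagged[sig_peaks] >
                    mean(flagged[setdiff(panel_peak_ids(), sig_peaks)])))
})

test_that("synthetic traces integrate back to their generating areas", {
  w <- read_windows(system.file("extdata", "windows_synthetic.csv",
                                package = "glyconact"))
  sim <- simulate_cohort(simulation_config(seed = 77, n_nrg = 2, n_rg = 2))
  traces <- simulate_traces(sim$areas[1, ], w, points_per_min = 240)
  got <- integrate_fixed_windows(traces, w, sample_id = "S001")
  target <- as.numeric(sim$areas[1, panel_peak_ids()])
  # windows truncate each Gaussian at +/- 4 sd: ~99.99% of the area
  expect_equal(as.numeric(got[panel_peak_ids()]), target,
               tolerance = 2e-3)
})
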