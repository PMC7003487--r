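make_signal_cohort <- function(n, seed, beta = c(1.5, 0)) {
  withr::with_seed(seed, {
    x1 <- rnorm(n); x2 <- rnorm(n)
    p <- plogis(-0.2 + beta[1] * x1 + beta[2] * x2)
    data.frame(x1 = x1, x2 = x2, responder = runif(n) < p)
  })
}

test_that("logistic fit agrees with an independent IRLS implementation", {
  d <- make_signal_cohort(80, seed = 41)
  m <- fit_logistic(d, forced = c("x1", "x2"))
  X <- cbind(1, d$x1, d$x2)
  oracle <- irls_logistic_oracle(X, as.numeric(d$responder))
  expect_equal(unname(m$coefficients$estimate), unname(oracle),
               tolerance = 1e-6)
  expect_true(m$converged)
  expect_false(m$separation)
  expect_true(all(m$fitted > 0 & m$fitted < 1))
})

test_that("intercept-only model on a balanced outcome predicts ~0.5", {
  d <- data.frame(responder = rep(c(TRUE, FALSE), 25))
  m <- fit_logistic(d)
  expect_equal(unname(m$coefficients$estimate[1]), 0, tolerance = 1e-8)
  expect_equal(unique(round(m$fitted, 8)), 0.5)
})

test_that("outcome with a single class is rejected", {
  d <- data.frame(x1 = rnorm(10), responder = rep(TRUE, 10))
  expect_error(fit_logistic(d, forced = "x1"),
               class = "glyconact_single_class_error")
  expect_error(fit_logistic(make_signal_cohort(20, 1),
                            forced = "x1", candidates = "x1"),
               class = "glyconact_model_error")
})

test_that("stepwise selection retains a deterministic driver, drops pure noise", {
  hits_x1 <- 0; clean <- 0
  for (rep in 1:30) {
    d <- withr::with_seed(500 + rep, {
      x <- matrix(rnorm(200 * 5), 200)
      colnames(x) <- paste0("x", 1:5)
      d <- as.data.frame(x)
      d$responder <- d$x1 > median(d$x1)
      d
    })
    m <- fit_logistic(d, candidates = paste0("x", 1:5),
                      selection = "bidirectional", criterion = "aic")
    if ("x1" %in% m$terms) hits_x1 <- hits_x1 + 1
    if (length(setdiff(m$terms, "x1")) == 0) clean <- clean + 1
    expect_true(m$separation)   # deterministic rule separates perfectly
  }
  expect_gte(hits_x1, 29)       # >= 95% of replicates
  expect_gte(clean, 29)
})

test_that("with pure-noise candidates, forced terms only are kept in the majority of runs", {
  kept_forced_only <- 0
  for (rep in 1:50) {
    d <- withr::with_seed(900 + rep, {
      d <- data.frame(z1 = rnorm(200), z2 = rnorm(200), f = rnorm(200))
      d$responder <- runif(200) < plogis(0.8 * d$f)
      d
    })
    m <- fit_logistic(d, forced = "f", candidates = c("z1", "z2"),
                      selection = "bidirectional", criterion = "aic")
    expect_true("f" %in% m$terms)           # forced term never dropped
    if (setequal(m$terms, "f")) kept_forced_only <- kept_forced_only + 1
  }
  expect_gt(kept_forced_only, 25)
})

test_that("a jittered duplicate noise feature never disturbs the forced-terms contract", {
  d <- make_signal_cohort(150, seed = 43)
  d$x1_dup <- d$x1 + rnorm(150, sd = 1e-3)
  m <- fit_logistic(d, forced = "x1", candidates = c("x2", "x1_dup"),
                    selection = "forward", criterion = "bic")
  expect_true("x1" %in% m$terms)
})

test_that("p-value stepwise criterion also recovers the signal", {
  d <- make_signal_cohort(300, seed = 44, beta = c(2, 0))
  m <- fit_logistic(d, candidates = c("x1", "x2"), selection = "forward",
                    criterion = "p", p_enter = 0.01)
  expect_true("x1" %in% m$terms)
  expect_false("x2" %in% m$terms)
})

test_that("coefficients are recovered within 3 SE on large simulated cohorts", {
  ok <- 0; reps <- 40
  for (rep in seq_len(reps)) {
    d <- withr::with_seed(1300 + rep, {
      x1 <- rnorm(2000); x2 <- rnorm(2000)
      p <- plogis(-0.5 + 0.8 * x1 - 0.4 * x2)
      data.frame(x1 = x1, x2 = x2, responder = runif(2000) < p)
    })
    m <- fit_logistic(d, forced = c("x1", "x2"))
    cf <- m$coefficients
    truth <- c(-0.5, 0.8, -0.4)
    if (all(abs(cf$estimate - truth) < 3 * cf$se)) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.95 - 0.10)  # binomial slack at 40 replicates
})

test_that("ROC analysis: trivial scores, reversal, and dual-oracle AUC", {
  lab <- c(FALSE, FALSE, TRUE, TRUE, TRUE)
  perfect <- roc_analysis(as.numeric(lab), lab)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(roc_analysis(1 - as.numeric(lab), lab)$auc, 0)

  withr::with_seed(45, {
    for (rep in 1:10) {
      n <- sample(8:25, 1)
      lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
      sc <- round(runif(n), 2)
      r <- roc_analysis(sc, lab)
      expect_equal(r$auc, auc_pair_oracle(sc, lab), tolerance = 1e-12)
      expect_equal(r$auc, auc_trapezoid(r$curve$fpr, r$curve$tpr),
                   tolerance = 1e-12)
      # curve runs monotonically from (0,0) to (1,1)
      expect_true(all(diff(r$curve$fpr) >= 0))
      expect_true(all(diff(r$curve$tpr) >= -1e-12))
      expect_equal(range(r$curve$fpr), c(0, 1))
    }
  })
})

test_that("Youden threshold ties resolve toward higher specificity", {
  # scores where (sens, spec) = (1, .5) and (.5, 1) tie on Youden's J
  lab <- c(FALSE, FALSE, TRUE, TRUE)
  sc <- c(0.1, 0.4, 0.4, 0.9)
  r <- roc_analysis(sc, lab)
  expect_equal(r$specificity, 1)
  expect_equal(r$sensitivity, 0.5)
})

test_that("the three reference models carry the published term sets", {
  cfg <- simulation_config(seed = 61)
  sim <- simulate_cohort(cfg)
  cohort <- merge(sim$clinical, normalize_areas(sim$areas), by = "sample_id")
  models <- build_paper_models(cohort)
  expect_setequal(names(models), c("clinical", "glyco", "combined"))
  expect_setequal(models$clinical$model$terms,
                  c("age_group", "histology", "regimen"))
  expect_setequal(models$glyco$model$terms, c("GP4", "GP6", "GP18"))
  expect_setequal(models$combined$model$terms,
                  c("age_group", "histology", "regimen", "GP4", "GP6", "GP18"))
  for (m in models) {
    expect_true(all(m$model$fitted > 0 & m$model$fitted < 1))
    expect_gte(m$roc$auc, 0)
    expect_lte(m$roc$auc, 1)
  }
})

test_that("cross-validated AUC is near 0.5 on null cohorts for all three models", {
  # no group differences anywhere: same mean profile and same covariate
  # frequencies in both groups
  freqs <- reference_clinical_frequencies()
  for (v in names(freqs)) freqs[[v]]$rg <- freqs[[v]]$nrg
  aucs <- matrix(NA_real_, 30, 3)
  for (rep in 1:30) {
    cfg <- simulation_config(mean_rg = setNames(
      reference_group_profiles()$mean_nrg, panel_peak_ids()),
      covariate_frequencies = freqs,
      seed = 2100 + rep)
    sim <- simulate_cohort(cfg)
    cohort <- encode_clinical(
      merge(sim$clinical, normalize_areas(sim$areas), by = "sample_id"))
    aucs[rep, 1] <- cv_model_auc(cohort, c("age_group", "histology", "regimen"),
                                 seed = rep)
    aucs[rep, 2] <- cv_model_auc(cohort, c("GP4", "GP6", "GP18"), seed = rep)
    aucs[rep, 3] <- cv_model_auc(cohort, c("age_group", "histology", "regimen",
                                           "GP4", "GP6", "GP18"), seed = rep)
  }
  for (j in 1:3)
    expect_lt(abs(mean(aucs[, j]) - 0.5), 0.06)
})
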