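#' Run the end-to-end IgG glycomics NACT analysis
#'
#' Sequences the full analysis: (optional) fixed-window integration of
#' chromatogram traces, total-area normalization, trait computation,
#' univariate group comparison of peaks and traits, and the three logistic
#' prediction models with ROC analysis. Deterministic given inputs and
#' seed; every artifact directory carries a `run_info.json` with the
#' package version and a hash of the effective configuration, and the log
#' records every analysis default in effect.
#'
#' @param config A named list (or path to a JSON file) with entries:
#'   `areas_csv` (or `traces_csv` + `windows`), `clinical_csv`, or
#'   `simulate` (arguments for [simulation_config()]); `outdir`; `seed`;
#'   optional `options` (`var_equal`, `orientation`, `p_adjust`,
#'   `model_mode`, `selection`, `criterion`, `baseline`, `roc_plot`).
#' @return Invisibly, a list with the in-memory artifacts (`profiles`,
#'   `traits`, `comparison`, `models`) and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  opts <- utils::modifyList(
    list(var_equal = TRUE, orientation = "as-is", p_adjust = "none",
         model_mode = "paper", selection = "bidirectional",
         criterion = "aic", baseline = FALSE, roc_plot = FALSE),
    config$options %||% list())
  outdir <- config$outdir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "pipeline.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  say("glyconact %s", as.character(utils::packageVersion("glyconact")))
  say("defaults in effect: t-test=%s, orientation=%s, p_adjust=%s, model_mode=%s, stepwise=%s/%s, threshold=youden(ties->specificity)",
      if (opts$var_equal) "pooled" else "welch", opts$orientation,
      opts$p_adjust, opts$model_mode, opts$selection, opts$criterion)

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    sim <- simulate_cohort(do.call(simulation_config, sim_args))
    areas <- sim$areas
    clinical <- sim$clinical
    say("simulated cohort: %d NRG + %d RG samples (seed %d)",
        sum(!sim$clinical$responder), sum(sim$clinical$responder),
        as.integer(sim_args$seed))
  } else {
    if (!is.null(config$traces_csv)) {
      traces <- read_traces_csv(config$traces_csv)
      windows <- read_windows(config$windows)
      areas <- do.call(rbind, lapply(split(traces, traces$sample_id),
        function(tr) integrate_fixed_windows(tr, windows,
                                             baseline = isTRUE(opts$baseline),
                                             sample_id = tr$sample_id[1])))
      say("integrated %d traces over %d fixed windows",
          length(unique(traces$sample_id)), nrow(windows))
    } else if (!is.null(config$areas_csv)) {
      areas <- read_areas_csv(config$areas_csv)
    } else {
      glyconact_error("config needs areas_csv, traces_csv or simulate",
                      "glyconact_config_error")
    }
    clinical <- if (!is.null(config$clinical_csv))
      read_clinical_csv(config$clinical_csv) else NULL
  }

  # --- normalize + traits ---------------------------------------------------
  profiles <- normalize_areas(areas)
  defs <- if (!is.null(config$trait_definitions))
    read_trait_definitions(config$trait_definitions) else default_trait_set()
  traits <- compute_traits(profiles, defs)
  write_profiles_csv(profiles, file.path(outdir, "profiles.csv"))
  write_profiles_csv(traits, file.path(outdir, "traits.csv"))
  say("normalized %d samples; computed %d traits", nrow(profiles),
      length(defs))

  comparison <- NULL
  models <- NULL
  if (!is.null(clinical)) {
    pre <- clinical[clinical$timepoint == "pre", ]
    feat <- merge(profiles, traits, by = "sample_id")
    feat <- merge(feat, pre[, c("sample_id", "responder")], by = "sample_id")
    comparison <- compare_features(
      feat[, setdiff(names(feat), "responder")], feat$responder,
      var_equal = opts$var_equal, orientation = opts$orientation,
      p_adjust = opts$p_adjust)
    write_csv_atomic(comparison, file.path(outdir, "comparison.csv"))
    say("compared %d features between groups; %d significant at 0.05",
        nrow(comparison), sum(comparison$significant))

    cohort <- merge(pre, profiles, by = "sample_id")
    models <- build_paper_models(cohort, mode = opts$model_mode,
                                 selection = opts$selection,
                                 criterion = opts$criterion)
    report <- lapply(models, function(m) list(
      terms = m$model$terms,
      coefficients = m$model$coefficients,
      separation = m$model$separation,
      auc = m$roc$auc, ci_low = m$roc$ci_low, ci_high = m$roc$ci_high,
      threshold = m$roc$threshold, sensitivity = m$roc$sensitivity,
      specificity = m$roc$specificity))
    write_json_atomic(report, file.path(outdir, "model_report.json"))
    curves <- do.call(rbind, lapply(names(models), function(nm)
      cbind(model = nm, models[[nm]]$roc$curve)))
    write_csv_atomic(curves, file.path(outdir, "roc_points.csv"))
    for (nm in names(models))
      say("model %s: AUC %.3f (%.3f-%.3f), sens %.1f%%, spec %.1f%%", nm,
          models[[nm]]$roc$auc, models[[nm]]$roc$ci_low,
          models[[nm]]$roc$ci_high, 100 * models[[nm]]$roc$sensitivity,
          100 * models[[nm]]$roc$specificity)
    if (isTRUE(opts$roc_plot))
      plot_roc_models(models, file.path(outdir, "roc_curves.png"))
  }

  info <- list(package_version = as.character(utils::packageVersion("glyconact")),
               config_hash = config_hash(config),
               seed = config$seed)
  write_json_atomic(info, file.path(outdir, "run_info.json"))
  writeLines(log_lines, log_path)
  invisible(list(profiles = profiles, traits = traits,
                 comparison = comparison, models = models,
                 outdir = outdir, run_info = info))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  config <- config[setdiff(names(config), "outdir")]  # paths don't change the analysis
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Plot the three model ROC curves overlaid
#'
#' @param models Output of [build_paper_models()].
#' @param path Optional PNG path; plots to the active device if `NULL`.
#' @export
plot_roc_models <- function(models, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 800, res = 130)
    on.exit(grDevices::dev.off())
  }
  cols <- c(clinical = "steelblue", glyco = "goldenrod", combined = "firebrick")
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "NACT response prediction")
  for (nm in names(models)) {
    cv <- models[[nm]]$roc$curve
    graphics::lines(cv$fpr, cv$tpr, col = cols[[nm]], lwd = 2)
  }
  graphics::legend("bottomright", bty = "n", lwd = 2, col = cols[names(models)],
                   legend = sprintf("%s (AUC %.3f)", names(models),
                                    vapply(models, function(m) m$roc$auc,
                                           numeric(1))))
  invisible(NULL)
}
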