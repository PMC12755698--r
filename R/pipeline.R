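#' Pipeline run configuration
#'
#' A run is a pure function of its configuration: the exposure and hazard
#' data-generating processes (for simulated inputs), exposure windows, the
#' trimming quantile, the model, prior and MCMC settings, the contrast
#' quantiles and the seed.
#'
#' @param dgp An [exposure_dgp()].
#' @param hazard A [hazard_dgp()].
#' @param n_persons Persons at risk in the simulation.
#' @param p_primary Probability of a primary-position diagnosis.
#' @param window A [window_spec()].
#' @param trim_quantile PM2.5 trimming quantile (default 0.95).
#' @param model A [model_spec()].
#' @param prior_sd,chains,warmup,iter Bayesian fit settings
#'   (see [fit_clogit_bayes()]).
#' @param contrast_probs Reference and comparison case-day quantiles.
#' @param seed Integer seed for every random stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(dgp = exposure_dgp(), hazard = hazard_dgp(),
                       n_persons = 2000, p_primary = 0.532,
                       window = window_spec(), trim_quantile = 0.95,
                       model = model_spec(), prior_sd = 5, chains = 4,
                       warmup = 1000, iter = 1000,
                       contrast_probs = c(0.5, 0.95), seed = 1) {
  stopifnot(inherits(dgp, "exposure_dgp"), inherits(hazard, "hazard_dgp"),
            inherits(window, "window_spec"), inherits(model, "model_spec"))
  if (trim_quantile <= 0 || trim_quantile > 1) {
    abort("`trim_quantile` must lie in (0, 1].",
          class = "heatpm_invalid_config")
  }
  structure(
    list(dgp = dgp, hazard = hazard, n_persons = n_persons,
         p_primary = p_primary, window = window,
         trim_quantile = trim_quantile, model = model,
         prior_sd = prior_sd, chains = chains, warmup = warmup,
         iter = iter, contrast_probs = contrast_probs,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; the `dgp`, `hazard`,
#' `window` and `model` keys hold nested maps of the corresponding
#' constructor arguments (for `model`, sub-keys `temp_df`, `pm_df`,
#' `interaction`, `tensor_df`).
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$dgp)) args$dgp <- do.call(exposure_dgp, y$dgp)
  if (!is.null(y$hazard)) args$hazard <- do.call(hazard_dgp, y$hazard)
  if (!is.null(y$window)) args$window <- do.call(window_spec, y$window)
  if (!is.null(y$model)) {
    m <- y$model
    args$model <- model_spec(
      temp = spline_spec(m$temp_df %||% 4),
      pm = spline_spec(m$pm_df %||% 4),
      interaction = m$interaction %||% "linear_product",
      tensor_df = unlist(m$tensor_df %||% c(4, 4))
    )
  }
  scalars <- intersect(names(y), c("n_persons", "p_primary",
                                   "trim_quantile", "prior_sd", "chains",
                                   "warmup", "iter", "seed"))
  args[scalars] <- y[scalars]
  if (!is.null(y$contrast_probs)) args$contrast_probs <- unlist(y$contrast_probs)
  do.call(run_config, args)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "heatpm_stage_error", parent = e, stage = stage)
  })
}

config_echo <- function(config) {
  dgp <- config$dgp
  hz <- config$hazard
  list(
    dgp = list(baseline_temp = dgp$baseline_temp, amplitude = dgp$amplitude,
               peak_day = dgp$peak_day, temp_sd = dgp$temp_sd,
               ar_coef = dgp$ar_coef, pm_log_mean = dgp$pm_log_mean,
               pm_log_sd = dgp$pm_log_sd, temp_pm_corr = dgp$temp_pm_corr,
               n_areas = dgp$n_areas,
               date_start = format(dgp$date_start),
               date_end = format(dgp$date_end)),
    hazard = list(alpha = hz$alpha, beta_T = hz$beta_T, beta_P = hz$beta_P,
                  beta_TP = hz$beta_TP,
                  nonlinear = !is.null(hz$nonlinear_f)),
    n_persons = config$n_persons, p_primary = config$p_primary,
    window = unclass(config$window),
    trim_quantile = config$trim_quantile,
    model = list(temp_df = config$model$temp$df,
                 pm_df = config$model$pm$df,
                 interaction = config$model$interaction,
                 tensor_df = config$model$tensor_df),
    prior_sd = config$prior_sd, chains = config$chains,
    warmup = config$warmup, iter = config$iter,
    contrast_probs = config$contrast_probs, seed = config$seed
  )
}

#' Run the full case-crossover analysis pipeline
#'
#' Executes, in order: exposure/event simulation, case selection and
#' matched-set construction, PM2.5 trimming, design construction, the
#' Bayesian conditional-logistic fit, and effect estimation (contrast ORs,
#' RERI, multiplicative interaction, exposure-response curves, OR grid,
#' cohort summary).  Identical configuration and seed give byte-identical
#' outputs.  Any stage failure aborts with the stage name; a run manifest
#' records thresholds, knots, seeds, diagnostics, and an exact person-day
#' accounting ledger.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, all result tables are
#'   written as CSV and the manifest as JSON.
#' @param through Last stage to run: `"simulate"`, `"cohort"`, `"fit"`, or
#'   `"effects"` (default, the full pipeline).
#' @return A list of class `cc_pipeline` with the stage outputs produced
#'   and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         through = c("effects", "fit", "cohort",
                                     "simulate")) {
  stopifnot(inherits(config, "run_config"))
  through <- match.arg(through)
  stage_rank <- c(simulate = 1, cohort = 2, fit = 3, effects = 4)
  want <- stage_rank[[through]]
  bundle <- list(config = config)
  manifest <- list(config = config_echo(config))

  bundle$exposures <- run_stage("simulate",
    simulate_exposures(config$dgp, seed = config$seed))
  bundle$events <- run_stage("simulate",
    simulate_events(bundle$exposures, config$hazard, config$n_persons,
                    seed = config$seed + 1L, p_primary = config$p_primary,
                    window = config$window))
  manifest$counts <- list(n_area_days = nrow(bundle$exposures),
                          n_events = nrow(bundle$events))

  if (want >= 2) {
    bundle$cases <- run_stage("cohort", select_cases(bundle$events))
    sets <- run_stage("cohort",
      build_matched_sets(bundle$cases, bundle$exposures, config$window))
    design_log <- attr(sets, "design_log")
    bundle$analysis <- run_stage("cohort",
      trim_extreme_pm(sets, config$trim_quantile))
    trim_log <- attr(bundle$analysis, "trim_log")
    manifest$trim_threshold <- attr(bundle$analysis, "trim_threshold")
    manifest$counts$n_cases <- nrow(bundle$cases)
    ledger <- bind_rows(
      design_log |> filter(.data$reason != "retained"),
      trim_log
    )
    manifest$person_day_ledger <- as.list(setNames(ledger$n_rows,
                                                   ledger$reason))
    bundle$cohort_summary <- run_stage("cohort",
      describe_cohort(bundle$cases, bundle$analysis))
  }

  if (want >= 3) {
    design <- run_stage("fit", build_design(bundle$analysis, config$model))
    bundle$design <- design
    manifest$knots <- design$frozen[
      intersect(names(design$frozen),
                c("temp", "pm", "tensor_temp", "tensor_pm"))]
    bundle$fit <- run_stage("fit",
      fit_clogit_bayes(design, prior_sd = config$prior_sd,
                       chains = config$chains, warmup = config$warmup,
                       iter = config$iter, seed = config$seed + 2L))
    manifest$mcmc <- list(
      accept_rate = bundle$fit$accept_rate,
      diagnostics = as.list(bundle$fit$diagnostics))
  }

  if (want >= 4) {
    bundle$contrast <- run_stage("effects",
      default_contrast(bundle$analysis, config$contrast_probs))
    manifest$contrast <- unclass(bundle$contrast)
    bundle$effects <- run_stage("effects",
      estimate_reri(bundle$fit, bundle$contrast))
    if (config$model$interaction == "linear_product") {
      bundle$effects <- bind_rows(bundle$effects,
        run_stage("effects", multiplicative_interaction(bundle$fit)))
    }
    bundle$or_curve_temp <- run_stage("effects",
      or_curve(bundle$fit, "temp", bundle$contrast))
    bundle$or_curve_pm <- run_stage("effects",
      or_curve(bundle$fit, "pm", bundle$contrast))
    bundle$or_grid <- run_stage("effects",
      or_grid(bundle$fit, bundle$contrast))
  }

  bundle$manifest <- manifest
  class(bundle) <- "cc_pipeline"
  if (!is.null(out_dir)) write_pipeline(bundle, out_dir)
  bundle
}

write_pipeline <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    readr::write_csv(x, file.path(out_dir, paste0(name, ".csv")))
  }
  if (!is.null(bundle$exposures)) wr(bundle$exposures, "exposures")
  if (!is.null(bundle$events)) wr(bundle$events, "events")
  if (!is.null(bundle$cases)) wr(bundle$cases, "cases")
  if (!is.null(bundle$analysis)) wr(bundle$analysis, "analysis")
  if (!is.null(bundle$fit)) {
    wr(as_tibble(bundle$fit$draws), "draws")
    wr(bundle$fit$diagnostics, "diagnostics")
  }
  if (!is.null(bundle$effects)) wr(bundle$effects, "effects")
  if (!is.null(bundle$or_curve_temp)) {
    wr(bundle$or_curve_temp, "or_curve_temp")
    wr(bundle$or_curve_pm, "or_curve_pm")
    wr(bundle$or_grid, "or_grid")
  }
  if (!is.null(bundle$cohort_summary)) {
    wr(bundle$cohort_summary$exposures, "cohort_exposures")
    if (nrow(bundle$cohort_summary$categories)) {
      wr(bundle$cohort_summary$categories, "cohort_categories")
    }
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(bundle)
}

#' @export
print.cc_pipeline <- function(x, ...) {
  cat("<cc_pipeline>\n")
  if (!is.null(x$manifest$counts$n_cases)) {
    cat("  cases:", x$manifest$counts$n_cases, "\n")
  }
  if (!is.null(x$manifest$trim_threshold)) {
    cat("  PM2.5 trim threshold:",
        sprintf("%.2f ug/m3", x$manifest$trim_threshold), "\n")
  }
  if (!is.null(x$effects)) print(x$effects)
  invisible(x)
}
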