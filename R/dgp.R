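#' Exposure data-generating process
#'
#' Parameters of the synthetic area-day exposure generator.  Daily maximum
#' temperature is a seasonal sinusoid plus AR(1) Gaussian deviations; daily
#' PM2.5 is lognormal with its log-scale innovation correlated with the
#' same-day temperature deviation.  The defaults are calibrated so that the
#' pooled warm-season (June-September) temperature has mean 29.2 degC and SD
#' 5.0 degC, and the 3-day mean PM2.5, trimmed at its own 95th percentile,
#' has mean 9.4 and SD 3.7 ug/m3 -- the descriptive moments this generator
#' is designed to emulate.
#'
#' @param baseline_temp Seasonal sinusoid baseline (degC).
#' @param amplitude Seasonal amplitude (degC).
#' @param peak_day Day-of-year at which the seasonal mean peaks.
#' @param temp_sd Stationary SD of daily temperature deviations (degC).
#' @param ar_coef AR(1) coefficient of temperature deviations, in `[0, 1)`.
#' @param pm_log_mean Mean of log PM2.5 (log ug/m3).
#' @param pm_log_sd SD of log PM2.5 (log ug/m3), `>= 0`.
#' @param temp_pm_corr Correlation between the standardized temperature
#'   deviation and the log-PM2.5 innovation, in `(-1, 1)`.
#' @param n_areas Number of areas to simulate.
#' @param date_start,date_end Inclusive date range (coerced with `as.Date()`).
#' @return A list of class `exposure_dgp`.
#' @seealso [simulate_exposures()]
#' @export
exposure_dgp <- function(baseline_temp = 23.53,
                         amplitude = 7,
                         peak_day = 201,
                         temp_sd = 4.83,
                         ar_coef = 0.7,
                         pm_log_mean = 2.062,
                         pm_log_sd = 0.717,
                         temp_pm_corr = 0.3,
                         n_areas = 50,
                         date_start = "2008-01-01",
                         date_end = "2016-12-31") {
  date_start <- as.Date(date_start)
  date_end <- as.Date(date_end)
  if (is.na(date_start) || is.na(date_end) || date_end < date_start) {
    abort("`date_start`/`date_end` must define a non-empty date range.",
          class = "heatpm_invalid_config")
  }
  if (n_areas < 1) {
    abort("`n_areas` must be at least 1.", class = "heatpm_invalid_config")
  }
  if (temp_sd < 0 || pm_log_sd < 0) {
    abort("`temp_sd` and `pm_log_sd` must be non-negative.",
          class = "heatpm_invalid_config")
  }
  if (ar_coef < 0 || ar_coef >= 1) {
    abort("`ar_coef` must lie in [0, 1).", class = "heatpm_invalid_config")
  }
  if (abs(temp_pm_corr) >= 1) {
    abort("`temp_pm_corr` must lie in (-1, 1).",
          class = "heatpm_invalid_config")
  }
  structure(
    list(baseline_temp = baseline_temp, amplitude = amplitude,
         peak_day = peak_day, temp_sd = temp_sd, ar_coef = ar_coef,
         pm_log_mean = pm_log_mean, pm_log_sd = pm_log_sd,
         temp_pm_corr = temp_pm_corr, n_areas = as.integer(n_areas),
         date_start = date_start, date_end = date_end),
    class = "exposure_dgp"
  )
}

#' Hospitalization hazard data-generating process
#'
#' Defines the true per-person-day log-odds of hospitalization as a function
#' of the *windowed* analysis exposures (case-day maximum temperature `T`,
#' 3-day mean PM2.5 `P`):
#' `log-odds(T, P) = alpha + beta_T * T + beta_P * P + beta_TP * T * P`,
#' or an arbitrary smooth `nonlinear_f(T, P)` returning the log-odds when
#' supplied.  Because the hazard operates on the same windowed exposures the
#' analysis model uses, the conditional-logistic analysis is correctly
#' specified under the linear form and true parameters are recoverable.
#'
#' @param alpha Baseline log-odds.
#' @param beta_T Log-odds slope per degC.
#' @param beta_P Log-odds slope per ug/m3.
#' @param beta_TP Log-odds interaction per degC * ug/m3.
#' @param nonlinear_f Optional `function(T, P)` returning the log-odds,
#'   replacing the linear form.
#' @return A list of class `hazard_dgp`.
#' @seealso [simulate_events()], [true_effects()]
#' @export
hazard_dgp <- function(alpha = qlogis(1e-4),
                       beta_T = 0.05,
                       beta_P = 0.02,
                       beta_TP = 0.003,
                       nonlinear_f = NULL) {
  if (!is.null(nonlinear_f) && !is.function(nonlinear_f)) {
    abort("`nonlinear_f` must be NULL or a function(T, P).",
          class = "heatpm_invalid_config")
  }
  structure(
    list(alpha = alpha, beta_T = beta_T, beta_P = beta_P,
         beta_TP = beta_TP, nonlinear_f = nonlinear_f),
    class = "hazard_dgp"
  )
}

# evaluate the hazard's log-odds at windowed exposures
hazard_log_odds <- function(hazard, tmax, pm) {
  if (!is.null(hazard$nonlinear_f)) {
    return(hazard$nonlinear_f(tmax, pm))
  }
  hazard$alpha + hazard$beta_T * tmax + hazard$beta_P * pm +
    hazard$beta_TP * tmax * pm
}

#' Seasonal mean temperature curve
#'
#' @param doy Day-of-year (1-366).
#' @param dgp An [exposure_dgp()].
#' @return Seasonal mean daily maximum temperature (degC).
#' @export
seasonal_mean_temp <- function(doy, dgp = exposure_dgp()) {
  dgp$baseline_temp +
    dgp$amplitude * cos(2 * pi * (doy - dgp$peak_day) / 365.25)
}

#' Simulate area-day exposure series
#'
#' Generates one contiguous daily record per (area, date) over the DGP's
#' date range.  Temperature is the seasonal sinusoid plus a stationary AR(1)
#' deviation; PM2.5 is `exp(pm_log_mean + pm_log_sd * z)` where `z` mixes
#' the standardized same-day temperature deviation (weight `temp_pm_corr`)
#' with independent noise.
#'
#' @param dgp An [exposure_dgp()].
#' @param seed Integer seed; identical `(dgp, seed)` give identical output.
#' @return A tibble with columns `area_id`, `date`, `tmax` (degC) and
#'   `pm25` (ug/m3), ordered by area then date.
#' @examples
#' ex <- simulate_exposures(exposure_dgp(n_areas = 2, date_end = "2008-03-01"),
#'                          seed = 1)
#' head(ex)
#' @export
simulate_exposures <- function(dgp = exposure_dgp(), seed = 1) {
  stopifnot(inherits(dgp, "exposure_dgp"))
  set.seed(as.integer(seed))
  dates <- seq(dgp$date_start, dgp$date_end, by = "day")
  n_days <- length(dates)
  n_areas <- dgp$n_areas
  seas <- seasonal_mean_temp(date_yday(dates), dgp)

  # AR(1) deviations, stationary start: innovation SD temp_sd*sqrt(1-ar^2),
  # first draw at the stationary SD
  innov_sd <- dgp$temp_sd * sqrt(1 - dgp$ar_coef^2)
  eps <- matrix(rnorm(n_days * n_areas, sd = innov_sd), n_days, n_areas)
  if (n_days >= 1) eps[1, ] <- rnorm(n_areas, sd = dgp$temp_sd)
  dev <- apply(eps, 2, function(e) {
    as.numeric(stats::filter(e, dgp$ar_coef, method = "recursive"))
  })
  dev <- matrix(dev, n_days, n_areas)

  # log-PM innovation correlated with the standardized temperature deviation
  dstd <- if (dgp$temp_sd > 0) dev / dgp$temp_sd else dev * 0
  u <- matrix(rnorm(n_days * n_areas), n_days, n_areas)
  z <- dgp$temp_pm_corr * dstd + sqrt(1 - dgp$temp_pm_corr^2) * u
  pm <- exp(dgp$pm_log_mean + dgp$pm_log_sd * z)

  tibble(
    area_id = rep(seq_len(n_areas), each = n_days),
    date = rep(dates, times = n_areas),
    tmax = as.numeric(seas + dev),
    pm25 = as.numeric(pm)
  ) |>
    arrange(.data$area_id, .data$date)
}

#' Simulate first hospitalization events
#'
#' Assigns each person uniformly to an area, evaluates the hazard's daily
#' event probability at that area-day's *windowed* exposures (case-day
#' `tmax`, `pm_window_days`-day mean PM2.5; days without full window
#' coverage cannot be event days), and emits each person's **first** event
#' only, mirroring a first-event case definition.
#'
#' @param exposures Exposure tibble from [simulate_exposures()].
#' @param hazard A [hazard_dgp()].
#' @param n_persons Number of persons at risk.
#' @param seed Integer seed.
#' @param p_primary Probability that the diagnosis is in primary position
#'   (default 0.532).
#' @param window A [window_spec()] used to window the hazard's exposures.
#' @return A tibble with one row per person experiencing an event:
#'   `person_id`, `area_id`, `admission_date`, `primary_dx` (logical),
#'   ordered by `person_id`.  A warning of class
#'   `heatpm_rare_outcome_violated` is raised when the median daily event
#'   probability reaches 0.5.
#' @export
simulate_events <- function(exposures, hazard = hazard_dgp(),
                            n_persons = 1000, seed = 1,
                            p_primary = 0.532,
                            window = window_spec()) {
  stopifnot(inherits(hazard, "hazard_dgp"))
  stopifnot_cols(exposures, c("area_id", "date", "tmax", "pm25"),
                 "`exposures`")
  if (n_persons < 1) {
    abort("`n_persons` must be at least 1.", class = "heatpm_invalid_config")
  }
  set.seed(as.integer(seed))

  w <- add_exposure_windows(exposures, window)
  valid <- !is.na(w$tmax_w) & !is.na(w$pm25_w)
  p <- numeric(nrow(w))
  p[valid] <- plogis(hazard_log_odds(hazard, w$tmax_w[valid],
                                     w$pm25_w[valid]))
  if (any(valid) && median(p[valid]) >= 0.5) {
    warn(paste("Median daily event probability is >= 0.5; the rare-outcome",
               "assumption behind OR-based interaction summaries is",
               "violated."),
         class = "heatpm_rare_outcome_violated")
  }

  area_ids <- sort(unique(w$area_id))
  person_area <- sample(area_ids, n_persons, replace = TRUE)
  u <- runif(n_persons)

  # per area, cdf of the first-event day: F_t = 1 - prod_{s<=t}(1 - p_s);
  # one uniform per person inverts it exactly
  w_split <- split(seq_len(nrow(w)), w$area_id)
  out <- vector("list", length(area_ids))
  for (k in seq_along(area_ids)) {
    rows <- w_split[[as.character(area_ids[k])]]
    Fk <- 1 - exp(cumsum(log1p(-p[rows])))
    persons <- which(person_area == area_ids[k])
    if (!length(persons)) next
    pos <- findInterval(u[persons], Fk) + 1L
    hit <- pos <= length(rows)
    if (!any(hit)) next
    out[[k]] <- tibble(
      person_id = persons[hit],
      area_id = area_ids[k],
      admission_date = w$date[rows[pos[hit]]]
    )
  }
  ev <- bind_rows(out)
  if (nrow(ev) == 0) {
    return(tibble(person_id = integer(), area_id = integer(),
                  admission_date = as.Date(character()),
                  primary_dx = logical()))
  }
  ev <- arrange(ev, .data$person_id)
  ev$primary_dx <- rbinom(nrow(ev), 1, p_primary) == 1
  ev
}

#' Closed-form true effect quantities of a linear hazard
#'
#' For a hazard in linear form (or with an evaluable `nonlinear_f`), computes
#' the true odds ratios of the joint-exposure contrast grid and the relative
#' excess risk due to interaction, all referenced to `(t0, p0)`:
#' `OR_ab = exp(logodds(T_a, P_b) - logodds(T_0, P_0))` and
#' `RERI = OR11 - OR10 - OR01 + 1`.  The baseline `alpha` cancels.
#'
#' @param hazard A [hazard_dgp()].
#' @param contrast A [contrast_spec()].
#' @return A one-row tibble with `or10` (temperature alone), `or01` (PM2.5
#'   alone), `or11` (joint) and `reri`.
#' @examples
#' h <- hazard_dgp(beta_T = 0.01, beta_P = 0.002, beta_TP = 0)
#' true_effects(h, contrast_spec(29.6, 36.9, 8.9, 16.1))
#' @export
true_effects <- function(hazard, contrast) {
  stopifnot(inherits(hazard, "hazard_dgp"), inherits(contrast, "contrast_spec"))
  lo <- function(t, p) hazard_log_odds(hazard, t, p)
  base <- lo(contrast$t0, contrast$p0)
  or10 <- exp(lo(contrast$t1, contrast$p0) - base)
  or01 <- exp(lo(contrast$t0, contrast$p1) - base)
  or11 <- exp(lo(contrast$t1, contrast$p1) - base)
  tibble(or10 = or10, or01 = or01, or11 = or11,
         reri = or11 - or10 - or01 + 1)
}
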