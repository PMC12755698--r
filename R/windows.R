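#' Exposure window specification
#'
#' The analysis exposures attached to every person-day: the `temp_window_days`
#' trailing mean of daily maximum temperature (default 1, i.e. the case-day
#' value) and the `pm_window_days` trailing mean of PM2.5 (default 3: the
#' index day and the two preceding days).
#'
#' @param temp_window_days Temperature window length in days (>= 1).
#' @param pm_window_days PM2.5 window length in days (>= 1).
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(temp_window_days = 1, pm_window_days = 3) {
  if (temp_window_days < 1 || pm_window_days < 1) {
    abort("Window lengths must be >= 1 day.", class = "heatpm_invalid_config")
  }
  structure(list(temp_window_days = as.integer(temp_window_days),
                 pm_window_days = as.integer(pm_window_days)),
            class = "window_spec")
}

#' Trailing window mean
#'
#' Mean of the `k` consecutive values ending at each position.  The first
#' `k - 1` positions, where the window is incomplete, are `NA` -- the
#' missing-coverage signal callers use to drop a day.
#'
#' @param x Numeric vector, one value per consecutive day.
#' @param k Window length in days.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' window_mean(c(6, 9, 12), 3)  # NA NA 9
#' @export
window_mean <- function(x, k) {
  k <- as.integer(k)
  if (k < 1) abort("`k` must be >= 1.")
  if (k == 1) return(as.numeric(x))
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 1))
}

#' Attach windowed analysis exposures to an exposure series
#'
#' Adds `tmax_w` and `pm25_w`, the trailing window means of `tmax` and
#' `pm25`, computed within each area.  Errors if any area's dates are not
#' contiguous (windows would silently span gaps otherwise).
#'
#' @param exposures Tibble with `area_id`, `date`, `tmax`, `pm25`.
#' @param window A [window_spec()].
#' @return The input tibble, ordered by (area, date), with `tmax_w` and
#'   `pm25_w` columns appended (`NA` where window coverage is incomplete).
#' @export
add_exposure_windows <- function(exposures, window = window_spec()) {
  stopifnot(inherits(window, "window_spec"))
  stopifnot_cols(exposures, c("area_id", "date", "tmax", "pm25"),
                 "`exposures`")
  out <- exposures |>
    arrange(.data$area_id, .data$date) |>
    group_by(.data$area_id) |>
    mutate(
      .gap = c(1L, diff(as.integer(.data$date))),
      tmax_w = window_mean(.data$tmax, window$temp_window_days),
      pm25_w = window_mean(.data$pm25, window$pm_window_days)
    ) |>
    ungroup()
  if (any(out$.gap != 1L)) {
    abort("Exposure dates must be contiguous within each area.",
          class = "heatpm_invalid_input")
  }
  select(out, -".gap")
}

#' Percentile trimming threshold
#'
#' Empirical quantile of the pooled case- and referent-day 3-day PM2.5
#' values, with linear interpolation between order statistics
#' (`stats::quantile()` type 7).
#'
#' @param values Numeric vector of exposure values.
#' @param q Quantile in (0, 1] (default 0.95; the sensitivity analysis
#'   uses 0.99).
#' @return The threshold, in the units of `values`.
#' @examples
#' trim_threshold(1:100, 0.95)  # 95.05
#' @export
trim_threshold <- function(values, q = 0.95) {
  values <- values[!is.na(values)]
  if (!length(values)) {
    abort("Cannot compute a trimming threshold from no values.",
          class = "heatpm_invalid_input")
  }
  if (q <= 0 || q > 1) abort("`q` must lie in (0, 1].")
  quantile(values, q, names = FALSE, type = 7)
}

#' Trim person-days with extreme windowed PM2.5
#'
#' Removes person-days whose windowed PM2.5 exceeds `threshold`.  A matched
#' set whose *case* day is removed is dropped entirely (a case-less stratum
#' contributes nothing to the conditional likelihood), as is any set left
#' with zero referents.  Counts of every category are recorded in the
#' `"trim_log"` attribute.
#'
#' @param sets Long-format matched-set tibble from [build_matched_sets()]
#'   (columns `set_id`, `is_case`, `pm25_w`, ...).
#' @param threshold Trimming threshold (ug/m3), e.g. from
#'   [trim_threshold()].
#' @return The trimmed tibble, with attributes `trim_log` (a tibble of drop
#'   counts by reason) and `trim_threshold`.
#' @export
apply_trim <- function(sets, threshold) {
  stopifnot_cols(sets, c("set_id", "is_case", "pm25_w"), "`sets`")
  over <- sets$pm25_w > threshold
  case_trimmed_sets <- unique(sets$set_id[over & sets$is_case == 1L])
  in_dead_set <- sets$set_id %in% case_trimmed_sets

  n_trim <- sum(over)
  n_caseless <- sum(in_dead_set & !over)

  kept <- sets[!over & !in_dead_set, , drop = FALSE]
  ref_counts <- kept |>
    group_by(.data$set_id) |>
    summarise(n_ref = sum(.data$is_case == 0L), .groups = "drop")
  empty_sets <- ref_counts$set_id[ref_counts$n_ref == 0L]
  n_empty <- sum(kept$set_id %in% empty_sets)
  kept <- kept[!kept$set_id %in% empty_sets, , drop = FALSE]

  log <- tibble(
    reason = c("pm_above_threshold", "set_dropped_case_trimmed",
               "set_dropped_no_referents_after_trim", "retained"),
    n_rows = c(n_trim, n_caseless, n_empty, nrow(kept))
  )
  attr(kept, "trim_log") <- log
  attr(kept, "trim_threshold") <- threshold
  kept
}

#' Compute the pooled trimming threshold and trim in one step
#'
#' @param sets Matched-set tibble with windowed PM2.5 attached.
#' @param quantile Trimming quantile (default 0.95).
#' @return As [apply_trim()]; the computed threshold is in the
#'   `trim_threshold` attribute.
#' @export
trim_extreme_pm <- function(sets, quantile = 0.95) {
  thr <- trim_threshold(sets$pm25_w, quantile)
  apply_trim(sets, thr)
}
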