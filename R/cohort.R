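#' Select case days from event records
#'
#' Reduces event records to one case per person: the earliest admission in
#' the record.  Persons whose earliest event falls outside the warm season
#' (June-September) are excluded -- later warm-season events are subsequent
#' events, never cases.
#'
#' @param events Tibble with `person_id`, `area_id`, `admission_date`, and
#'   optionally further columns (carried through).
#' @return A tibble of case days: `person_id`, `area_id`, `case_date`, plus
#'   carried columns; at most one row per person.
#' @export
select_cases <- function(events) {
  stopifnot_cols(events, c("person_id", "area_id", "admission_date"),
                 "`events`")
  events |>
    arrange(.data$person_id, .data$admission_date) |>
    distinct(.data$person_id, .keep_all = TRUE) |>
    filter(is_warm_season(.data$admission_date)) |>
    rename(case_date = "admission_date")
}

#' Bidirectional time-stratified referent days
#'
#' All other days in the case day's calendar month and year that share its
#' day of week, in ascending order -- the time-stratified referent scheme.
#' A weekday occurs 4 or 5 times in a month, so there are always 3 or 4
#' referents, before and/or after the case day.
#'
#' @param case_date A single `Date` (or string coercible to one).
#' @return A `Date` vector of 3 or 4 referent days.
#' @examples
#' referent_days(as.Date("2016-07-15"))
#' @export
referent_days <- function(case_date) {
  case_date <- as.Date(case_date)
  if (length(case_date) != 1 || is.na(case_date)) {
    abort("`case_date` must be a single valid date.")
  }
  cand <- case_date + seq(-28L, 28L, by = 7L)
  same_month <- date_month(cand) == date_month(case_date) &
    date_year(cand) == date_year(case_date)
  sort(cand[same_month & cand != case_date])
}

#' Build matched case-crossover sets with windowed exposures
#'
#' For every case day, forms the stratum of the case plus its same-month
#' same-weekday referent days, attaches windowed analysis exposures
#' ([add_exposure_windows()]), and drops person-days without full exposure
#' coverage.  Sets whose case day lacks coverage, and sets left with zero
#' referents, are dropped whole; all drop counts are recorded in the
#' `"design_log"` attribute.
#'
#' @param cases Case-day tibble from [select_cases()].
#' @param exposures Area-day exposure tibble.
#' @param window A [window_spec()].
#' @return Long-format analysis tibble: `set_id`, `person_id`, `area_id`,
#'   `date`, `is_case` (0/1), `tmax_w`, `pm25_w`, ordered by set then date,
#'   with attribute `design_log` holding the person-day accounting.
#' @export
build_matched_sets <- function(cases, exposures, window = window_spec()) {
  stopifnot_cols(cases, c("person_id", "area_id", "case_date"), "`cases`")
  w <- add_exposure_windows(exposures, window)

  cases <- cases |>
    arrange(.data$person_id) |>
    mutate(set_id = dplyr::row_number())
  offs <- seq(-28L, 28L, by = 7L)
  n <- nrow(cases)
  long <- tibble(
    set_id = rep(cases$set_id, each = length(offs)),
    person_id = rep(cases$person_id, each = length(offs)),
    area_id = rep(cases$area_id, each = length(offs)),
    case_date = rep(cases$case_date, each = length(offs)),
    date = rep(cases$case_date, each = length(offs)) + rep(offs, times = n)
  ) |>
    filter(date_month(.data$date) == date_month(.data$case_date),
           date_year(.data$date) == date_year(.data$case_date)) |>
    mutate(is_case = as.integer(.data$date == .data$case_date)) |>
    left_join(select(w, "area_id", "date", "tmax_w", "pm25_w"),
              by = c("area_id", "date"))

  covered <- !is.na(long$tmax_w) & !is.na(long$pm25_w)
  dead_sets <- unique(long$set_id[long$is_case == 1L & !covered])
  in_dead <- long$set_id %in% dead_sets

  n_missing <- sum(!covered)
  n_caseless <- sum(in_dead & covered)

  kept <- long[covered & !in_dead, , drop = FALSE]
  ref_counts <- kept |>
    group_by(.data$set_id) |>
    summarise(n_ref = sum(.data$is_case == 0L), .groups = "drop")
  empty_sets <- ref_counts$set_id[ref_counts$n_ref == 0L]
  n_empty <- sum(kept$set_id %in% empty_sets)
  kept <- kept[!kept$set_id %in% empty_sets, , drop = FALSE]

  out <- kept |>
    select("set_id", "person_id", "area_id", "date", "is_case",
           "tmax_w", "pm25_w") |>
    arrange(.data$set_id, .data$date)
  log <- tibble(
    reason = c("candidate_person_days", "missing_exposure_coverage",
               "set_dropped_case_uncovered", "set_dropped_no_referents",
               "retained"),
    n_rows = c(nrow(long), n_missing, n_caseless, n_empty, nrow(out))
  )
  if (length(dead_sets) || length(empty_sets)) {
    inform(sprintf(
      "Dropped %d matched set(s): %d with uncovered case day, %d with no valid referents.",
      length(dead_sets) + length(empty_sets), length(dead_sets),
      length(empty_sets)))
  }
  attr(out, "design_log") <- log
  out
}
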