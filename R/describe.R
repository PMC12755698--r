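#' Descriptive cohort summary
#'
#' Counts and percentages of case characteristics (diagnosis position, when
#' available) and exposure means/SDs on case and referent days, formatted
#' the way descriptive cohort tables conventionally present them
#' (percentages to one decimal, half-up).
#'
#' @param cases Case-day tibble (optionally with a `primary_dx` column).
#' @param analysis Long-format analysis tibble with `is_case`, `tmax_w`,
#'   `pm25_w`.
#' @return Object of class `cc_cohort_summary`: list with `n_cases`,
#'   `categories` (category, n, pct) and `exposures` (exposure, day_type,
#'   mean, sd).
#' @export
describe_cohort <- function(cases, analysis) {
  if (is.null(cases) || !nrow(cases)) {
    abort("Empty cohort: no cases to describe.",
          class = "heatpm_empty_cohort")
  }
  stopifnot_cols(analysis, c("is_case", "tmax_w", "pm25_w"), "`analysis`")
  n_cases <- nrow(cases)
  categories <- tibble(category = character(), n = integer(),
                       pct = numeric())
  if ("primary_dx" %in% names(cases)) {
    n_prim <- sum(cases$primary_dx)
    categories <- tibble(
      category = c("primary_dx", "secondary_dx"),
      n = c(n_prim, n_cases - n_prim),
      pct = percent_halfup(c(n_prim, n_cases - n_prim), n_cases)
    )
  }
  exposures <- analysis |>
    mutate(day_type = ifelse(.data$is_case == 1L, "case", "referent")) |>
    group_by(.data$day_type) |>
    summarise(
      tmax_mean = mean(.data$tmax_w), tmax_sd = sd(.data$tmax_w),
      pm25_mean = mean(.data$pm25_w), pm25_sd = sd(.data$pm25_w),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-"day_type", names_to = c("exposure", ".value"),
                        names_sep = "_")
  structure(list(n_cases = n_cases, categories = categories,
                 exposures = exposures),
            class = "cc_cohort_summary")
}

#' @export
print.cc_cohort_summary <- function(x, ...) {
  cat("<cc_cohort_summary>", x$n_cases, "cases\n")
  if (nrow(x$categories)) print(x$categories)
  print(x$exposures)
  invisible(x)
}
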