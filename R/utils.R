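#' Numerically stable log-sum-exp
#'
#' @param x Numeric vector.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Percentage with half-up rounding
#'
#' Computes `100 * n / total` rounded *half up* (so 53.15 -> 53.2, not
#' banker's rounding) to a fixed number of decimals, matching the one-decimal
#' presentation convention of descriptive cohort tables.
#'
#' @param n Numerator count (vectorised).
#' @param total Denominator count.
#' @param digits Decimal places to keep (default 1).
#' @return Numeric vector of percentages.
#' @examples
#' percent_halfup(60053, 112969)  # 53.2
#' percent_halfup(25910, 112969)  # 22.9
#' @export
percent_halfup <- function(n, total, digits = 1) {
  if (any(total <= 0)) abort("`total` must be positive.")
  x <- 100 * n / total
  f <- 10^digits
  floor(x * f + 0.5 + 1e-12) / f
}

# month (1-12) and ISO weekday (1 = Monday ... 7 = Sunday) of a Date
date_month <- function(d) as.POSIXlt(d)$mon + 1L
date_wday <- function(d) {
  w <- as.POSIXlt(d)$wday # 0 = Sunday
  ifelse(w == 0L, 7L, w)
}
date_year <- function(d) as.POSIXlt(d)$year + 1900L
date_yday <- function(d) as.POSIXlt(d)$yday + 1L

is_warm_season <- function(d) date_month(d) %in% 6:9

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
}
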