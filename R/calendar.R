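#' Gregorian leap-year predicate
#'
#' @param year integer vector of calendar years.
#' @return logical vector.
#' @export
is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
}

#' Number of days in a calendar year
#'
#' @param year integer vector of calendar years.
#' @return 365 or 366 per element.
#' @export
days_in_year <- function(year) {
  ifelse(is_leap_year(year), 366L, 365L)
}

#' Calendar-day index on the fixed 366-slot calendar
#'
#' Maps each date to a slot 1..366 where Feb-29 is always slot 60 and
#' Mar-1 is always slot 61, so a given month-day occupies the same slot in
#' every year. Threshold climatologies are indexed by this slot.
#'
#' @param dates a `Date` vector.
#' @return integer vector in 1..366.
#' @export
calendar_day_index <- function(dates) {
  stopifnot(inherits(dates, "Date"))
  lt <- as.POSIXlt(dates)
  yday <- lt$yday + 1L            # 1-based day of year
  leap <- is_leap_year(lt$year + 1900L)
  # in non-leap years shift everything from Mar-1 onwards past the empty
  # Feb-29 slot
  yday + as.integer(!leap & yday >= 60L)
}

#' Circular window of calendar-day slots
#'
#' Slots within `halfwidth` of `center` on the 366-day wheel (wraps across
#' the year boundary).
#'
#' @param center slot in 1..366.
#' @param halfwidth non-negative integer.
#' @return integer vector of 2*halfwidth + 1 slots.
#' @keywords internal
calendar_window <- function(center, halfwidth) {
  ((center - halfwidth - 1L + 0:(2L * halfwidth)) %% 366L) + 1L
}

#' All dates of a span of calendar years
#' @keywords internal
year_span_dates <- function(start_year, end_year) {
  seq(as.Date(sprintf("%d-01-01", start_year)),
      as.Date(sprintf("%d-12-31", end_year)), by = "day")
}

#' Year component of a Date vector
#' @keywords internal
date_year <- function(dates) as.POSIXlt(dates)$year + 1900L

#' Month component of a Date vector
#' @keywords internal
date_month <- function(dates) as.POSIXlt(dates)$mon + 1L

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
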