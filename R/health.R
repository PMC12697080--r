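#' Daily deaths from an annual total
#'
#' Annual deaths divided by the number of days in the year (365, or 366 in
#' Gregorian leap years).
#'
#' @param annual_deaths non-negative count.
#' @param year calendar year (decides 365 vs 366).
#' @return deaths per day.
#' @export
daily_deaths <- function(annual_deaths, year) {
  if (any(annual_deaths < 0))
    stop("domain error: annual_deaths must be >= 0", call. = FALSE)
  annual_deaths / days_in_year(year)
}

#' Heatwave-attributable annual mortality
#'
#' `heatwave_days x death_daily x (RR - 1) / RR`: the expected daily death
#' count on heatwave days times the attributable fraction `(RR-1)/RR`,
#' cumulated over the year's heatwave days.
#'
#' @param heatwave_days days classified as heatwave in the year (>= 0).
#' @param death_daily community daily death count (>= 0).
#' @param rr relative risk of all-cause mortality on heatwave days (> 0).
#'   The package-wide default is the pooled estimate 1.20 with 95% CI
#'   (1.02, 1.41); an `rr < 1` yields a negative (protective) value, which
#'   is permitted but flagged with a warning.
#' @return attributable deaths per year.
#' @export
attributable_mortality <- function(heatwave_days, death_daily, rr = 1.20) {
  if (any(rr <= 0)) stop("domain error: rr must be > 0", call. = FALSE)
  if (any(heatwave_days < 0) || any(death_daily < 0))
    stop("domain error: heatwave_days and death_daily must be >= 0",
         call. = FALSE)
  if (any(rr < 1))
    warning("rr < 1: attributable mortality is negative (protective)",
            call. = FALSE)
  heatwave_days * death_daily * (rr - 1) / rr
}

#' Country-year heatwave mortality burden
#'
#' Aggregates station heatwave days to each country (mean HWF over the
#' country's stations by default, or the sum), combines them with that
#' country-year's daily death count and the relative risk, and propagates
#' the RR confidence interval.
#'
#' @param indices yearly-indices data.frame (several stations row-bound;
#'   needs `station_id`, `year`, `hwf`).
#' @param catalogue station catalogue mapping `station_id` to `country`.
#' @param demography data.frame `country`, `year`, `annual_deaths`,
#'   `population`.
#' @param rr point relative risk.
#' @param rr_ci length-2 vector, lower and upper RR bounds.
#' @param aggregate `"mean"` (default) or `"sum"` of station HWF per
#'   country.
#' @param scenario label copied into the output.
#' @return data.frame, one row per country-year: `country`, `year`,
#'   `scenario`, `heatwave_days`, `death_daily`, `rr`, `attributable`,
#'   `attributable_low`, `attributable_high`.
#' @export
country_burden <- function(indices, catalogue, demography,
                           rr = 1.20, rr_ci = c(1.02, 1.41),
                           aggregate = c("mean", "sum"),
                           scenario = "historical") {
  aggregate <- match.arg(aggregate)
  i <- match(indices$station_id, catalogue$station_id)
  if (anyNA(i))
    stop("configuration error: unmapped station(s): ",
         paste(unique(indices$station_id[is.na(i)]), collapse = ", "),
         call. = FALSE)
  indices$country <- catalogue$country[i]
  agg_fun <- if (aggregate == "mean") mean else sum
  hw <- stats::aggregate(hwf ~ country + year, data = indices, FUN = agg_fun)
  names(hw)[names(hw) == "hwf"] <- "heatwave_days"
  j <- match(paste(hw$country, hw$year),
             paste(demography$country, demography$year))
  if (anyNA(j))
    stop("configuration error: demography missing for ",
         paste(unique(paste(hw$country, hw$year)[is.na(j)]), collapse = ", "),
         call. = FALSE)
  hw$death_daily <- daily_deaths(demography$annual_deaths[j], hw$year)
  hw$rr <- rr
  hw$attributable <- attributable_mortality(hw$heatwave_days, hw$death_daily, rr)
  hw$attributable_low <-
    attributable_mortality(hw$heatwave_days, hw$death_daily, rr_ci[1])
  hw$attributable_high <-
    attributable_mortality(hw$heatwave_days, hw$death_daily, rr_ci[2])
  hw <- hw[order(hw$country, hw$year), ]
  hw <- cbind(hw[, c("country", "year")], scenario = scenario,
              hw[, c("heatwave_days", "death_daily", "rr", "attributable",
                     "attributable_low", "attributable_high")])
  rownames(hw) <- NULL
  hw
}

#' Regional annual totals of attributable mortality
#'
#' Sums country burdens per year; the region total equals the sum of its
#' country columns by construction.
#'
#' @param burden data.frame from [country_burden()].
#' @return data.frame `year`, `scenario`, `attributable`,
#'   `attributable_low`, `attributable_high`.
#' @export
region_totals <- function(burden) {
  out <- stats::aggregate(
    cbind(attributable, attributable_low, attributable_high) ~ year + scenario,
    data = burden, FUN = sum)
  out[order(out$year), ]
}
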