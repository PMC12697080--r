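#' Configuration for the synthetic temperature-series generator
#'
#' Defaults describe a Central-Asia-like continental climate: a strong
#' seasonal cycle peaking in mid-July, a secular warming trend of 0.04 degC
#' per year (~0.4 degC/decade, the rate regional reanalyses report for the
#' area), AR(1) day-to-day weather noise, and a small number of multi-day
#' summer heat episodes injected each year. The pseudo-GCM parameters add a
#' warm mean bias and inflate variability, the miscalibration the
#' mean-variance correction removes.
#'
#' @param n_stations number of stations (desk-scale default 20; the real
#'   network emulated has 700 locations).
#' @param start_year,end_year inclusive span of the reference record.
#' @param baseline_mean annual-mean daily maximum temperature, degC.
#' @param seasonal_amplitude half-range of the seasonal Tmax cycle, degC.
#' @param trend linear warming trend, degC per year.
#' @param ar1_coeff lag-1 autocorrelation of daily noise, in `[0, 1)`.
#' @param noise_sd stationary standard deviation of daily noise, degC.
#' @param episode_rate expected number of injected heat episodes per warm
#'   season (Poisson).
#' @param episode_boost temperature added on episode days, degC.
#' @param gcm_bias additive mean bias of the pseudo-GCM, degC.
#' @param gcm_var_inflation multiplicative inflation of pseudo-GCM
#'   anomalies about the reference mean (> 0).
#' @param seed integer RNG seed (mandatory; every generator is
#'   deterministic given it).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_stations = 20L,
                             start_year = 1959L, end_year = 2021L,
                             baseline_mean = 18, seasonal_amplitude = 17,
                             trend = 0.04, ar1_coeff = 0.7, noise_sd = 3,
                             episode_rate = 2, episode_boost = 6,
                             gcm_bias = 2, gcm_var_inflation = 1.3,
                             seed = 1L) {
  cfg <- list(n_stations = as.integer(n_stations),
              start_year = as.integer(start_year),
              end_year = as.integer(end_year),
              baseline_mean = baseline_mean,
              seasonal_amplitude = seasonal_amplitude,
              trend = trend, ar1_coeff = ar1_coeff, noise_sd = noise_sd,
              episode_rate = episode_rate, episode_boost = episode_boost,
              gcm_bias = gcm_bias, gcm_var_inflation = gcm_var_inflation,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$end_year < cfg$start_year)
    stop("configuration error: end_year < start_year", call. = FALSE)
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop("configuration error: noise_sd must be > 0", call. = FALSE)
  if (cfg$gcm_var_inflation <= 0)
    stop("configuration error: gcm_var_inflation must be > 0", call. = FALSE)
  if (cfg$ar1_coeff < 0 || cfg$ar1_coeff >= 1)
    stop("configuration error: ar1_coeff must be in [0, 1)", call. = FALSE)
  if (is.na(cfg$seed)) stop("configuration error: seed required", call. = FALSE)
  invisible(cfg)
}

# Country centroids used to label stations (lon, lat); five CA countries.
.ca_centroids <- data.frame(
  country = c("KAZ", "UZB", "TKM", "KGZ", "TJK"),
  lon = c(67.0, 64.0, 58.0, 74.5, 71.0),
  lat = c(48.0, 41.5, 39.0, 41.5, 38.5)
)

#' Generate a station catalogue over a bounding box
#'
#' Stations are scattered uniformly over the box and labelled with the
#' nearest of five Central-Asian country centroids, so catalogue membership
#' is deterministic given coordinates.
#'
#' @param n_stations number of stations.
#' @param bbox named numeric `c(lon_min, lon_max, lat_min, lat_max)`;
#'   default covers Central Asia.
#' @param seed integer seed.
#' @return data.frame with `station_id`, `lon`, `lat`, `country`.
#' @export
station_catalogue <- function(n_stations = 20L,
                              bbox = c(lon_min = 46, lon_max = 87,
                                       lat_min = 35, lat_max = 55),
                              seed = 1L) {
  stopifnot(n_stations >= 1)
  with_seed(seed, {
    lon <- stats::runif(n_stations, bbox[["lon_min"]], bbox[["lon_max"]])
    lat <- stats::runif(n_stations, bbox[["lat_min"]], bbox[["lat_max"]])
  })
  d2 <- outer(lon, .ca_centroids$lon, "-")^2 + outer(lat, .ca_centroids$lat, "-")^2
  country <- .ca_centroids$country[max.col(-d2)]
  data.frame(station_id = sprintf("ST%03d", seq_len(n_stations)),
             lon = lon, lat = lat, country = country,
             stringsAsFactors = FALSE)
}

# Deterministic seasonal shape on the 366-slot calendar, peaking mid-July
# (slot 197).
.seasonal_cycle <- function(slot, amplitude) {
  amplitude * cos(2 * pi * (slot - 197) / 366)
}

# Deterministic integer sub-seed for station/member streams; kept < 2^31.
.derive_seed <- function(seed, key) {
  (as.numeric(seed) * 7919 + sum(utf8ToInt(as.character(key))) * 104729) %% 2147483629
}

#' Generate a reference ("pseudo-reanalysis") daily series
#'
#' Builds Tmax as baseline + sinusoidal seasonal cycle + linear trend +
#' AR(1) noise, then injects multi-day heat episodes (runs of 3-7 days,
#' `episode_boost` degC) in the warm half-year (May-Sep). Tmin is Tmax
#' minus a seasonally varying diurnal range bounded below at 1 degC, so
#' `tmax >= tmin` holds by construction. Ground truth for
#' parameter-recovery tests is attached as attributes: `true_trend` and an
#' `episodes` table (year, start, end, boost).
#'
#' @param spec one row of a [station_catalogue()] (list or data.frame row);
#'   only `station_id` is used by the generator.
#' @param cfg a [synthetic_config()].
#' @return a [daily_series()] spanning `start_year`..`end_year`.
#' @export
generate_reference_series <- function(spec, cfg) {
  validate_synthetic_config(cfg)
  sid <- if (is.list(spec) || is.data.frame(spec)) spec$station_id else as.character(spec)
  dates <- year_span_dates(cfg$start_year, cfg$end_year)
  n <- length(dates)
  slot <- calendar_day_index(dates)
  yrs <- date_year(dates)
  frac <- as.numeric(dates - dates[1]) / 365.25

  det <- cfg$baseline_mean + .seasonal_cycle(slot, cfg$seasonal_amplitude) +
    cfg$trend * frac

  with_seed(.derive_seed(cfg$seed, sid), {
    innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar1_coeff^2)
    eps <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                    cfg$ar1_coeff, method = "recursive"))
    dtr <- pmax(1, 11 + 2 * cos(2 * pi * (slot - 197) / 366) +
                     stats::rnorm(n, 0, 1))
    # injected heat episodes, warm half-year only (May 1 - Sep 15)
    boost <- numeric(n)
    ep <- list()
    for (y in cfg$start_year:cfg$end_year) {
      k <- stats::rpois(1, cfg$episode_rate)
      if (k == 0) next
      warm <- which(yrs == y & slot >= calendar_day_index(as.Date("2000-05-01")) &
                      slot <= calendar_day_index(as.Date("2000-09-15")))
      for (j in seq_len(k)) {
        dur <- sample(3:7, 1)
        s <- sample(seq_len(length(warm) - dur + 1L), 1)
        idx <- warm[s:(s + dur - 1L)]
        boost[idx] <- pmax(boost[idx], cfg$episode_boost)
        ep[[length(ep) + 1L]] <- data.frame(
          year = y, start = dates[idx[1]], end = dates[idx[dur]],
          boost = cfg$episode_boost)
      }
    }
  })
  tmax <- det + eps + boost
  out <- daily_series(dates, tmax, tmax - dtr, station_id = sid)
  attr(out, "true_trend") <- cfg$trend
  attr(out, "episodes") <- if (length(ep)) do.call(rbind, ep) else
    data.frame(year = integer(), start = as.Date(character()),
               end = as.Date(character()), boost = numeric())
  out
}

#' Generate a model ("pseudo-GCM") daily series from a reference
#'
#' Over the reference span the model is an affine distortion of the
#' reference plus noise independent of it:
#' `model = mu_ref + gcm_var_inflation * (ref - mu_ref) + gcm_bias + e`.
#' The noise `e` (sd `noise_sd`, AR(1) with `ar1_coeff`) is shared between
#' Tmax and Tmin on each day so the diurnal range stays positive. Beyond
#' the reference's last year the series is extended by continuing the
#' deterministic recipe (seasonal cycle + trend, optionally a different
#' `future_trend` emulating an emission scenario) with fresh noise, then
#' applying the same distortion. Ground truth is attached as attributes
#' `true_bias` and `true_inflation`.
#'
#' @param ref a gap-free reference [daily_series()].
#' @param cfg a [synthetic_config()] (supplies bias, inflation, noise, and
#'   the deterministic recipe used for the extension).
#' @param end_year last year of the model series (default: reference end).
#' @param future_trend degC/year applied after the reference's last year
#'   (default `cfg$trend`).
#' @param member integer distinguishing ensemble members' noise streams.
#' @return a [daily_series()] covering `start_year(ref)`..`end_year`.
#' @export
generate_gcm_series <- function(ref, cfg, end_year = NULL,
                                future_trend = NULL, member = 1L) {
  validate_synthetic_config(cfg)
  ref_years <- date_year(ref$date)
  ref_end <- max(ref_years)
  if (is.null(end_year)) end_year <- ref_end
  if (is.null(future_trend)) future_trend <- cfg$trend
  if (end_year < ref_end) stop("end_year precedes reference end", call. = FALSE)

  mu_ref <- mean(ref$tmax)
  tmax_base <- ref$tmax
  tmin_base <- ref$tmin
  dates <- ref$date

  if (end_year > ref_end) {
    ext_dates <- year_span_dates(ref_end + 1L, end_year)
    slot <- calendar_day_index(ext_dates)
    frac0 <- as.numeric(ext_dates - ref$date[1]) / 365.25
    frac_ref_end <- as.numeric(ref$date[length(ref$date)] - ref$date[1]) / 365.25
    det <- cfg$baseline_mean + .seasonal_cycle(slot, cfg$seasonal_amplitude) +
      cfg$trend * frac_ref_end + future_trend * (frac0 - frac_ref_end)
    with_seed(.derive_seed(cfg$seed, paste0(station_id(ref), "-ext-", member,
                                            "-", future_trend)), {
      innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar1_coeff^2)
      eps <- as.numeric(stats::filter(stats::rnorm(length(ext_dates), 0, innov_sd),
                                      cfg$ar1_coeff, method = "recursive"))
      dtr <- pmax(1, 11 + 2 * cos(2 * pi * (slot - 197) / 366) +
                       stats::rnorm(length(ext_dates), 0, 1))
    })
    tmax_base <- c(tmax_base, det + eps)
    tmin_base <- c(tmin_base, det + eps - dtr)
    dates <- c(dates, ext_dates)
  }

  with_seed(.derive_seed(cfg$seed, paste0(station_id(ref), "-gcm-", member)), {
    innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar1_coeff^2)
    e <- as.numeric(stats::filter(stats::rnorm(length(dates), 0, innov_sd),
                                  cfg$ar1_coeff, method = "recursive"))
  })
  g <- cfg$gcm_var_inflation
  tmax <- mu_ref + g * (tmax_base - mu_ref) + cfg$gcm_bias + e
  tmin <- mu_ref + g * (tmin_base - mu_ref) + cfg$gcm_bias + e
  out <- daily_series(dates, tmax, tmin,
                      station_id = station_id(ref), validate = FALSE)
  attr(out, "true_bias") <- cfg$gcm_bias
  attr(out, "true_inflation") <- cfg$gcm_var_inflation
  out
}

#' Generate a demographic table (annual deaths and population)
#'
#' Emulates a UN-style country-year table: population follows logistic
#' growth toward a carrying capacity, the crude death rate declines slowly,
#' and deaths = population x rate x (1 + small lognormal noise), so deaths
#' are positive and follow a smooth secular trajectory.
#'
#' @param countries character vector of country labels.
#' @param years integer vector of calendar years.
#' @param seed integer seed.
#' @return data.frame `country`, `year`, `annual_deaths`, `population`.
#' @export
generate_demography <- function(countries, years, seed = 1L) {
  if (length(countries) == 0 || length(years) == 0)
    stop("configuration error: countries and years must be nonempty",
         call. = FALSE)
  years <- sort(as.integer(years))
  out <- vector("list", length(countries))
  for (i in seq_along(countries)) {
    cty <- countries[i]
    with_seed(.derive_seed(seed, paste0("demog-", cty)), {
      p0 <- stats::runif(1, 3e6, 20e6)       # mid-20th-century population
      cap <- p0 * stats::runif(1, 2.5, 4.5)  # carrying capacity
      k <- stats::runif(1, 0.03, 0.06)
      t0 <- stats::runif(1, 1990, 2030)
      rate0 <- stats::runif(1, 7, 10) / 1000 # crude death rate, per year
      decline <- stats::runif(1, 0.0005, 0.002)
      noise <- stats::rnorm(length(years), 0, 0.02)
    })
    pop <- cap / (1 + ((cap - p0) / p0) * exp(-k * (years - min(years))))
    rate <- pmax(4 / 1000, rate0 - decline * (years - min(years)) / 10)
    deaths <- pop * rate * exp(noise)
    out[[i]] <- data.frame(country = cty, year = years,
                           annual_deaths = round(deaths),
                           population = round(pop),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write catalogue / demography CSVs
#' @param x data.frame as returned by [station_catalogue()] or
#'   [generate_demography()].
#' @param path file path.
#' @export
write_table_csv <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path)
  invisible(path)
}
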