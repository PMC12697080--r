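#' Calendar-day percentile threshold climatology
#'
#' For each of the 366 calendar-day slots, the threshold is the q-th
#' percentile (linear interpolation between order statistics, `type = 7`)
#' of all base-period values whose calendar-day slot lies within
#' `window_halfwidth` slots of the target on the 366-day wheel, pooled
#' across all base years. The window wraps across the year boundary; the
#' Feb-29 slot is served by the leap-year values that fall in its window.
#'
#' @param series a [daily_series()].
#' @param variable `"tmax"` or `"tmin"`.
#' @param base_start,base_end inclusive base-period years; default the full
#'   span of `series`.
#' @param q percentile in (0, 100); 90 gives the TX90/TN90 thresholds.
#' @param window_halfwidth half-width of the centered window in days
#'   (default 7, i.e. a 15-day window).
#' @return a `threshold_climatology`: list with `variable`, `base_start`,
#'   `base_end`, `q`, `window_halfwidth` and `thresholds` (366 values, degC).
#' @export
calendar_day_percentile <- function(series, variable = c("tmax", "tmin"),
                                    base_start = NULL, base_end = NULL,
                                    q = 90, window_halfwidth = 7L) {
  variable <- match.arg(variable)
  if (q <= 0 || q >= 100) stop("q must be in (0, 100)", call. = FALSE)
  yrs <- date_year(series$date)
  if (is.null(base_start)) base_start <- min(yrs)
  if (is.null(base_end)) base_end <- max(yrs)
  if (base_start < min(yrs) || base_end > max(yrs))
    stop("data error: base period ", base_start, "-", base_end,
         " not covered by series", call. = FALSE)
  keep <- yrs >= base_start & yrs <= base_end
  x <- series[[variable]][keep]
  slot <- calendar_day_index(series$date[keep])
  groups <- split(x, factor(slot, levels = 1:366))
  thr <- vapply(1:366, function(t) {
    pool <- unlist(groups[calendar_window(t, window_halfwidth)],
                   use.names = FALSE)
    if (length(pool) == 0)
      stop("data error: empty window for calendar day ", t, call. = FALSE)
    stats::quantile(pool, q / 100, type = 7, names = FALSE)
  }, numeric(1))
  structure(list(variable = variable, base_start = base_start,
                 base_end = base_end, q = q,
                 window_halfwidth = as.integer(window_halfwidth),
                 thresholds = thr),
            class = "threshold_climatology")
}

#' @export
print.threshold_climatology <- function(x, ...) {
  cat(sprintf("<threshold_climatology> %s p%g, base %d-%d, +/-%d-day window\n",
              x$variable, x$q, x$base_start, x$base_end, x$window_halfwidth))
  invisible(x)
}

# threshold for each date in `dates`
.threshold_for <- function(clim, dates) clim$thresholds[calendar_day_index(dates)]

#' Warm-day (or warm-night) percentage for one year
#'
#' 100 x (days of `year` whose value strictly exceeds that calendar day's
#' threshold) / (days in `year`). With `variable = "tmax"` and a 90th
#' percentile climatology this is TX90p; with `"tmin"`, TN90p.
#'
#' @param series a [daily_series()].
#' @param clim a [calendar_day_percentile()] climatology.
#' @param year calendar year, must lie within the series.
#' @return percentage in `[0, 100]`.
#' @export
warm_day_fraction <- function(series, clim, year) {
  yrs <- date_year(series$date)
  sel <- yrs == year
  if (!any(sel))
    stop("range error: year ", year, " outside series", call. = FALSE)
  v <- series[[clim$variable]][sel]
  100 * mean(v > .threshold_for(clim, series$date[sel]))
}

#' Detect heatwave events
#'
#' A heatwave is a maximal run of consecutive days with Tmax strictly above
#' that calendar day's threshold, lasting at least `min_duration` days.
#' Runs are found over the whole series so an event crossing Dec-31 is not
#' split; each event is attributed to the year containing its start date.
#'
#' @param series a [daily_series()].
#' @param clim a Tmax threshold climatology.
#' @param year if non-NULL, keep only events starting in that year.
#' @param min_duration minimum run length in days (default 3, the
#'   ETCCDI/ClimPACT heatwave-aspects convention).
#' @return data.frame with `start_date`, `end_date`, `duration`, `peak`
#'   (degC), `mean_intensity` (mean Tmax over event days, degC). Zero rows
#'   when no run qualifies.
#' @export
detect_heatwaves <- function(series, clim, year = NULL, min_duration = 3L) {
  if (min_duration < 1) stop("min_duration must be >= 1", call. = FALSE)
  if (clim$variable != "tmax")
    stop("heatwave detection requires a tmax climatology", call. = FALSE)
  exceed <- series$tmax > .threshold_for(clim, series$date)
  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  if (!any(keep)) {
    ev <- data.frame(start_date = as.Date(character()),
                     end_date = as.Date(character()),
                     duration = integer(), peak = numeric(),
                     mean_intensity = numeric())
  } else {
    s <- starts[keep]; e <- ends[keep]
    ev <- data.frame(
      start_date = series$date[s], end_date = series$date[e],
      duration = e - s + 1L,
      peak = mapply(function(a, b) max(series$tmax[a:b]), s, e),
      mean_intensity = mapply(function(a, b) mean(series$tmax[a:b]), s, e))
  }
  if (!is.null(year))
    ev <- ev[date_year(ev$start_date) == year, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Yearly heatwave and warm-day indices for one year
#'
#' * `hwn` - number of discrete heatwave events starting in the year
#' * `hwf` - total days in those events (days/year)
#' * `hwd` - duration of the longest event (0 if none)
#' * `hwm` - heatwave magnitude: mean Tmax over all event days (degC;
#'    0 when no event, matching the "no heatwave" severity row)
#' * `hwa` - heatwave amplitude: hottest Tmax within any event (degC;
#'    `NA` when no event)
#' * `tx90p` / `tn90p` - warm-day / warm-night percentages
#'
#' @param series a [daily_series()].
#' @param clim_tx,clim_tn Tmax / Tmin threshold climatologies.
#' @param year calendar year.
#' @param min_duration minimum event length in days.
#' @return one-row data.frame with columns `station_id`, `year`, `tx90p`,
#'   `tn90p`, `hwn`, `hwf`, `hwd`, `hwm`, `hwa`.
#' @export
yearly_indices <- function(series, clim_tx, clim_tn, year, min_duration = 3L) {
  compute_yearly_indices(series, clim_tx, clim_tn, years = year,
                         min_duration = min_duration)
}

#' Yearly indices for many years at once
#'
#' Batch form of [yearly_indices()]: exceedances and event runs are
#' computed once over the whole series.
#'
#' @inheritParams yearly_indices
#' @param years years to report; default all complete years in the series.
#' @return data.frame, one row per year.
#' @export
compute_yearly_indices <- function(series, clim_tx, clim_tn, years = NULL,
                                   min_duration = 3L) {
  yrs_all <- date_year(series$date)
  if (is.null(years)) years <- sort(unique(yrs_all))
  ev <- detect_heatwaves(series, clim_tx, min_duration = min_duration)
  ev_year <- date_year(ev$start_date)
  # Tmax over each event's days, grouped by attribution year
  out <- lapply(years, function(y) {
    if (!any(yrs_all == y))
      stop("range error: year ", y, " outside series", call. = FALSE)
    evy <- ev[ev_year == y, , drop = FALSE]
    if (nrow(evy)) {
      day_vals <- unlist(mapply(function(a, b) {
        series$tmax[series$date >= a & series$date <= b]
      }, evy$start_date, evy$end_date, SIMPLIFY = FALSE))
      hwm <- mean(day_vals); hwa <- max(day_vals)
    } else {
      hwm <- 0; hwa <- NA_real_
    }
    data.frame(station_id = station_id(series), year = y,
               tx90p = warm_day_fraction(series, clim_tx, y),
               tn90p = warm_day_fraction(series, clim_tn, y),
               hwn = nrow(evy),
               hwf = if (nrow(evy)) sum(evy$duration) else 0L,
               hwd = if (nrow(evy)) max(evy$duration) else 0L,
               hwm = hwm, hwa = hwa,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a tidy indices CSV
#'
#' One row per station-year; missing `hwa` (no-event years) is written as
#' an empty field.
#'
#' @param x data.frame from [compute_yearly_indices()] (possibly several
#'   stations row-bound).
#' @param path file path.
#' @export
write_indices_csv <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, na = "")
  invisible(path)
}
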