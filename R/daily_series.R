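#' Construct a daily temperature series
#'
#' The atom of all index computation: one location's dated, gap-free daily
#' record of maximum and minimum near-surface temperature in degrees
#' Celsius.
#'
#' @param dates strictly increasing, gap-free `Date` vector.
#' @param tmax,tmin numeric vectors (degC), same length as `dates`, with
#'   `tmax >= tmin` elementwise.
#' @param station_id scalar character identifier.
#' @param validate set `FALSE` to skip invariant checks (used internally for
#'   bias-corrected output, where the affine map can in principle produce
#'   isolated `tmax < tmin` days).
#' @return a `daily_series`: a `data.frame` with columns `date`, `tmax`,
#'   `tmin` and a `station_id` attribute.
#' @export
daily_series <- function(dates, tmax, tmin, station_id = "station",
                         validate = TRUE) {
  stopifnot(inherits(dates, "Date"))
  if (length(tmax) != length(dates) || length(tmin) != length(dates))
    stop("tmax/tmin must match dates in length", call. = FALSE)
  if (validate) {
    d <- as.integer(diff(dates))
    if (length(d) && any(d != 1L))
      stop("dates must be strictly increasing and gap-free", call. = FALSE)
    if (anyNA(tmax) || anyNA(tmin))
      stop("tmax/tmin must be finite", call. = FALSE)
    if (any(tmax < tmin))
      stop("tmax < tmin on ", sum(tmax < tmin), " day(s)", call. = FALSE)
  }
  out <- data.frame(date = dates, tmax = as.numeric(tmax),
                    tmin = as.numeric(tmin))
  attr(out, "station_id") <- as.character(station_id)
  class(out) <- c("daily_series", "data.frame")
  out
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> station %s: %d days, %s .. %s\n",
              attr(x, "station_id"), nrow(x),
              format(x$date[1]), format(x$date[nrow(x)])))
  invisible(x)
}

#' Station identifier of a daily series
#' @param x a `daily_series`.
#' @export
station_id <- function(x) attr(x, "station_id")

#' Restrict a daily series to a span of calendar years
#'
#' @param x a `daily_series`.
#' @param start_year,end_year inclusive year bounds.
#' @export
window_years <- function(x, start_year, end_year) {
  yr <- date_year(x$date)
  keep <- yr >= start_year & yr <= end_year
  if (!any(keep))
    stop("series has no days in ", start_year, "-", end_year, call. = FALSE)
  daily_series(x$date[keep], x$tmax[keep], x$tmin[keep],
               station_id = station_id(x), validate = FALSE)
}

#' Write / read a per-station daily CSV
#'
#' Columns: `date` (ISO-8601), `tmax_c`, `tmin_c`.
#'
#' @param x a `daily_series`.
#' @param path file path.
#' @export
write_daily_series_csv <- function(x, path) {
  dt <- data.table::data.table(date = format(x$date, "%Y-%m-%d"),
                               tmax_c = x$tmax, tmin_c = x$tmin)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_daily_series_csv
#' @param station_id identifier attached to the series read from `path`.
#' @export
read_daily_series_csv <- function(path, station_id = NULL) {
  dt <- data.table::fread(path)
  if (!all(c("date", "tmax_c", "tmin_c") %in% names(dt)))
    stop("expected columns date, tmax_c, tmin_c in ", path, call. = FALSE)
  if (is.null(station_id))
    station_id <- sub("\\.csv$", "", basename(path))
  daily_series(as.Date(dt$date), dt$tmax_c, dt$tmin_c,
               station_id = station_id)
}
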