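# Independent oracles and tiny fixture builders shared across the suite.
# These deliberately re-derive results by the most literal route possible
# (day-by-day scans, full enumeration, manual order-statistic
# interpolation) so they stay independent of the implementation they check.

# daily series over consecutive days starting at `start`
make_series <- function(tmax, start = "2001-01-01", tmin = tmax - 10,
                        station_id = "TOY") {
  d0 <- as.Date(start)
  daily_series(seq(d0, by = "day", length.out = length(tmax)),
               tmax, tmin, station_id = station_id)
}

# threshold climatology with explicit per-slot thresholds
manual_clim <- function(thresholds, variable = "tmax") {
  if (length(thresholds) == 1) thresholds <- rep(thresholds, 366)
  structure(list(variable = variable, base_start = NA, base_end = NA,
                 q = 90, window_halfwidth = 0L,
                 thresholds = thresholds),
            class = "threshold_climatology")
}

# literal day-by-day heatwave scanner: walks the exceedance vector once,
# closing an event whenever the run breaks
naive_scanner <- function(tmax, thr, min_duration) {
  exceed <- tmax > thr
  events <- list()
  run_start <- NA
  for (i in seq_along(exceed)) {
    if (exceed[i] && is.na(run_start)) run_start <- i
    closing <- !is.na(run_start) && (!exceed[i] || i == length(exceed))
    if (closing) {
      run_end <- if (exceed[i]) i else i - 1L
      if (run_end - run_start + 1L >= min_duration)
        events[[length(events) + 1L]] <- c(start = run_start, end = run_end)
      run_start <- NA
    }
  }
  if (length(events) == 0)
    return(data.frame(start = integer(), end = integer(),
                      duration = integer(), peak = numeric(),
                      mean_intensity = numeric()))
  ev <- as.data.frame(do.call(rbind, events))
  ev$duration <- ev$end - ev$start + 1L
  ev$peak <- mapply(function(a, b) max(tmax[a:b]), ev$start, ev$end)
  ev$mean_intensity <- mapply(function(a, b) mean(tmax[a:b]), ev$start, ev$end)
  ev
}

# manual type-7 percentile: linear interpolation between order statistics
brute_percentile <- function(x, q) {
  x <- sort(x)
  h <- (length(x) - 1) * q / 100
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

# all permutations of 1..n (used for the exact Mann-Kendall null at n <= 7)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

mk_s_statistic <- function(y) {
  n <- length(y)
  s <- 0L
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) s <- s + sign(y[j] - y[i])
  s
}
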