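test_that("percentile of a constant series is the constant", {
  s <- make_series(rep(20, 365 * 2))
  clim <- calendar_day_percentile(s, "tmax")
  expect_length(clim$thresholds, 366L)
  expect_true(all(clim$thresholds == 20))
})

test_that("windowed threshold matches a brute-force pooled percentile", {
  set.seed(21)
  # two non-leap base years so every slot carries exactly two values
  s <- make_series(rnorm(365 * 2, 25, 5), start = "2001-01-01")
  clim <- calendar_day_percentile(s, "tmax", q = 90, window_halfwidth = 2)
  slot <- calendar_day_index(s$date)
  for (target in c(15L, 100L, 197L, 320L)) {
    pool <- s$tmax[slot %in% ((target - 3L + 0:4) %% 366L + 1L)]
    expect_length(pool, 10L)
    expect_equal(clim$thresholds[target], brute_percentile(pool, 90))
  }
})

test_that("median threshold of a symmetric alternating series is the midline", {
  s <- make_series(20 + (-1)^(1:730), start = "2001-01-01")
  clim <- calendar_day_percentile(s, "tmax", q = 50, window_halfwidth = 7)
  expect_true(all(abs(clim$thresholds - 20) < 1e-12))
})

test_that("base period must be covered and q must be interior", {
  s <- make_series(rnorm(365), start = "2001-01-01")
  expect_error(calendar_day_percentile(s, "tmax", base_start = 2000),
               "base period")
  expect_error(calendar_day_percentile(s, "tmax", q = 0), "q must be")
})

test_that("warm-day fraction hits its 0 and 100 percent limits", {
  s <- make_series(rep(25, 365), start = "2001-01-01")
  expect_equal(warm_day_fraction(s, manual_clim(30), 2001), 0)
  expect_equal(warm_day_fraction(s, manual_clim(20), 2001), 100)
  expect_error(warm_day_fraction(s, manual_clim(20), 1999), "range error")
  # strict exceedance: equality does not count
  expect_equal(warm_day_fraction(s, manual_clim(25), 2001), 0)
})

test_that("detect_heatwaves reproduces the manual run-length examples", {
  s <- make_series(c(28, 29, 31, 32, 33, 31, 28, 31, 31, 28))
  clim <- manual_clim(30)
  ev <- detect_heatwaves(s, clim, min_duration = 3)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$start_date, s$date[3])
  expect_identical(ev$end_date, s$date[6])
  expect_identical(ev$duration, 4L)
  expect_equal(ev$peak, 33)
  expect_equal(ev$mean_intensity, 31.75)

  ev2 <- detect_heatwaves(s, clim, min_duration = 2)
  expect_identical(nrow(ev2), 2L)
  expect_identical(ev2$duration, c(4L, 2L))
  expect_identical(ev2$start_date[2], s$date[8])

  expect_identical(nrow(detect_heatwaves(make_series(rep(10, 10)), clim,
                                         min_duration = 3)), 0L)
})

test_that("events crossing Dec-31 are unsplit and attributed to the start year", {
  tmax <- rep(20, 20)
  tmax[14:18] <- 35  # Dec 29 .. Jan 2 given a Dec 16 start
  s <- make_series(tmax, start = "2001-12-16")
  ev <- detect_heatwaves(s, manual_clim(30), min_duration = 3)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$duration, 5L)
  ev_2001 <- detect_heatwaves(s, manual_clim(30), year = 2001,
                              min_duration = 3)
  expect_identical(nrow(ev_2001), 1L)
  expect_identical(nrow(detect_heatwaves(s, manual_clim(30), year = 2002,
                                         min_duration = 3)), 0L)
})

test_that("yearly indices match manual enumeration on toy series", {
  s <- make_series(c(28, 29, 31, 32, 33, 31, 28, 31, 31, 28))
  ctx <- manual_clim(30); ctn <- manual_clim(20, "tmin")
  y <- yearly_indices(s, ctx, ctn, 2001, min_duration = 3)
  expect_identical(y$hwn, 1L)
  expect_identical(y$hwf, 4L)
  expect_identical(y$hwd, 4L)
  expect_equal(y$hwm, 31.75)
  expect_equal(y$hwa, 33)
  expect_equal(y$tx90p, 60)  # 6 of 10 days above 30

  # no events: hwm recorded as 0, hwa missing
  s0 <- make_series(rep(10, 10))
  y0 <- yearly_indices(s0, ctx, ctn, 2001, min_duration = 3)
  expect_identical(c(y0$hwn, y0$hwf, y0$hwd), c(0L, 0L, 0L))
  expect_equal(y0$hwm, 0)
  expect_true(is.na(y0$hwa))

  # two events, durations 3 and 5
  tm <- rep(20, 20); tm[3:5] <- 33; tm[10:14] <- 35
  y2 <- yearly_indices(make_series(tm), ctx, ctn, 2001, min_duration = 3)
  expect_identical(c(y2$hwn, y2$hwf, y2$hwd), c(2L, 8L, 5L))
})

test_that("detector agrees exactly with the naive scanner (random series)", {
  set.seed(99)
  for (rep in 1:150) {
    tmax <- rnorm(365, 20, 5)
    thr <- rnorm(366, 22, 3)
    s <- make_series(tmax, start = "2001-01-01")
    clim <- manual_clim(thr)
    md <- sample(1:4, 1)
    ev <- detect_heatwaves(s, clim, min_duration = md)
    oracle <- naive_scanner(tmax, thr[calendar_day_index(s$date)], md)
    expect_identical(nrow(ev), nrow(oracle))
    if (nrow(ev)) {
      expect_identical(as.integer(ev$start_date - s$date[1]) + 1L,
                       as.integer(oracle$start))
      expect_identical(ev$duration, as.integer(oracle$duration))
      expect_equal(ev$peak, oracle$peak)
      expect_equal(ev$mean_intensity, oracle$mean_intensity)
    }
  }
})

test_that("index invariants hold on generated series", {
  cfg <- synthetic_config(start_year = 1991, end_year = 2010, seed = 13)
  s <- generate_reference_series(list(station_id = "ST001"), cfg)
  ctx <- calendar_day_percentile(s, "tmax")
  ctn <- calendar_day_percentile(s, "tmin")
  idx <- compute_yearly_indices(s, ctx, ctn, min_duration = 3)
  expect_true(all(idx$tx90p >= 0 & idx$tx90p <= 100))
  expect_true(all(idx$hwf >= idx$hwd))
  has <- idx$hwn > 0
  expect_true(all(idx$hwf[has] >= 3 * idx$hwn[has]))
  expect_true(all(idx$hwa[has] >= idx$hwm[has]))
  expect_true(all(xor(idx$hwn == 0, idx$hwf > 0)))
  expect_true(all(is.na(idx$hwa[!has])))

  # monotonicity in min_duration
  idx5 <- compute_yearly_indices(s, ctx, ctn, min_duration = 5)
  expect_true(all(idx5$hwn <= idx$hwn))
  expect_true(all(idx5$hwf <= idx$hwf))

  # raising all thresholds never increases exceedance-based indices
  ctx_up <- ctx; ctx_up$thresholds <- ctx$thresholds + 1
  idx_up <- compute_yearly_indices(s, ctx_up, ctn, min_duration = 3)
  expect_true(all(idx_up$tx90p <= idx$tx90p))
  expect_true(all(idx_up$hwn <= idx$hwn))
  expect_true(all(idx_up$hwf <= idx$hwf))
  expect_true(all(idx_up$hwd <= idx$hwd))
})

test_that("indices CSV round-trips with empty hwa fields", {
  idx <- data.frame(station_id = "A", year = 2001:2002,
                    tx90p = c(10, 12), tn90p = c(9, 11), hwn = c(0L, 2L),
                    hwf = c(0L, 7L), hwd = c(0L, 4L), hwm = c(0, 30),
                    hwa = c(NA, 35))
  p <- withr::local_tempfile(fileext = ".csv")
  write_indices_csv(idx, p)
  lines <- readLines(p)
  expect_match(lines[1], "tx90p,tn90p,hwn,hwf,hwd,hwm,hwa")
  expect_match(lines[2], ",$")  # missing hwa written as empty field
  back <- read.csv(p)
  expect_true(is.na(back$hwa[1]))
  expect_equal(back$hwa[2], 35)
})
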