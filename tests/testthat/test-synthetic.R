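spec1 <- list(station_id = "ST001")

test_that("generators are deterministic under the seed", {
  cfg <- synthetic_config(start_year = 1990, end_year = 1999, seed = 42)
  a <- generate_reference_series(spec1, cfg)
  b <- generate_reference_series(spec1, cfg)
  expect_identical(a, b)
  ga <- generate_gcm_series(a, cfg, end_year = 2005)
  gb <- generate_gcm_series(b, cfg, end_year = 2005)
  expect_identical(ga, gb)
  da <- generate_demography(c("KAZ", "UZB"), 2000:2010, seed = 9)
  db <- generate_demography(c("KAZ", "UZB"), 2000:2010, seed = 9)
  expect_identical(da, db)
  # different seeds diverge
  cfg2 <- synthetic_config(start_year = 1990, end_year = 1999, seed = 43)
  expect_false(identical(a$tmax, generate_reference_series(spec1, cfg2)$tmax))
})

test_that("reference series respects the calendar and tmax >= tmin", {
  cfg <- synthetic_config(start_year = 1998, end_year = 2003, seed = 5)
  s <- generate_reference_series(spec1, cfg)
  expect_true(all(s$tmax >= s$tmin))
  per_year <- table(format(s$date, "%Y"))
  expect_identical(as.integer(per_year[c("1998", "1999", "2001")]),
                   c(365L, 365L, 365L))
  expect_identical(as.integer(per_year[c("2000")]), 366L)  # leap
  expect_true(all(diff(s$date) == 1))
})

test_that("no-signal limit: yearly means are flat", {
  # endpoints of equal leapness; the seasonal-cycle mean over a 365- vs
  # 366-slot year differs at the 0.03 degC level by construction
  cfg <- synthetic_config(start_year = 1959, end_year = 2018, trend = 0,
                          noise_sd = 1e-9, episode_rate = 0, seed = 3)
  s <- generate_reference_series(spec1, cfg)
  yr <- as.integer(format(s$date, "%Y"))
  m1 <- mean(s$tmax[yr == 1959])
  m2 <- mean(s$tmax[yr == 2018])
  expect_lt(abs(m1 - m2), 1e-6)
})

test_that("injected trend is recovered by Sen's slope (Monte Carlo)", {
  n_seeds <- 100
  slopes <- ols <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    cfg <- synthetic_config(start_year = 1959, end_year = 2018,
                            trend = 0.05, seed = 1000 + k)
    s <- generate_reference_series(spec1, cfg)
    yr <- as.integer(format(s$date, "%Y"))
    ann <- tapply(s$tmax, yr, mean)
    slopes[k] <- sens_slope(as.numeric(ann))
    tt <- seq_along(ann)
    ols[k] <- unname(stats::coef(stats::lm(as.numeric(ann) ~ tt))[2])
  }
  ci <- mean(slopes) + c(-1.96, 1.96) * stats::sd(slopes) / sqrt(n_seeds)
  expect_gt(0.05, ci[1])
  expect_lt(0.05, ci[2])
  # OLS oracle agrees on average
  expect_lt(abs(mean(slopes) - mean(ols)), 0.005)
})

test_that("pseudo-GCM identity, bias and variance-inflation settings", {
  base <- synthetic_config(start_year = 1959, end_year = 2018, seed = 7)
  ref <- generate_reference_series(spec1, base)

  ident <- synthetic_config(start_year = 1959, end_year = 2018, seed = 7,
                            gcm_bias = 0, gcm_var_inflation = 1,
                            noise_sd = 1e-9)
  g0 <- generate_gcm_series(ref, ident)
  expect_equal(g0$tmax, ref$tmax, tolerance = 1e-6)
  expect_equal(g0$tmin, ref$tmin, tolerance = 1e-6)

  biased <- synthetic_config(start_year = 1959, end_year = 2018, seed = 7,
                             gcm_bias = 3)
  g3 <- generate_gcm_series(ref, biased)
  expect_lt(abs(mean(g3$tmax) - mean(ref$tmax) - 3), 0.1)
  expect_identical(attr(g3, "true_bias"), 3)

  infl <- synthetic_config(start_year = 1959, end_year = 2018, seed = 7,
                           gcm_bias = 0, gcm_var_inflation = 2,
                           noise_sd = 1e-9)
  g2 <- generate_gcm_series(ref, infl)
  expect_lt(abs(sd(g2$tmax) / sd(ref$tmax) - 2), 0.1)
})

test_that("pseudo-GCM extension continues past the reference", {
  cfg <- synthetic_config(start_year = 1990, end_year = 1999, seed = 2)
  ref <- generate_reference_series(spec1, cfg)
  g <- generate_gcm_series(ref, cfg, end_year = 2010, future_trend = 0.1)
  expect_identical(range(format(g$date, "%Y")), c("1990", "2010"))
  expect_true(all(diff(g$date) == 1))
  expect_error(generate_gcm_series(ref, cfg, end_year = 1995),
               "end_year")
})

test_that("demography table is well-formed and positive", {
  d <- generate_demography("KAZ", 2001:2003, seed = 1)
  expect_identical(nrow(d), 3L)
  for (s in c(1, 99, 12345)) {
    d <- generate_demography(c("KAZ", "UZB", "TJK"), 1950:2100, seed = s)
    expect_true(all(d$annual_deaths >= 0))
    expect_true(all(d$population > 0))
    expect_identical(nrow(d), 3L * 151L)
    expect_false(any(duplicated(d[, c("country", "year")])))
  }
  expect_error(generate_demography(character(), 2000), "nonempty")
})

test_that("station catalogue stays in the box with the five countries", {
  cat_ <- station_catalogue(200, seed = 4)
  expect_true(all(cat_$lon >= 46 & cat_$lon <= 87))
  expect_true(all(cat_$lat >= 35 & cat_$lat <= 55))
  expect_true(all(cat_$country %in% c("KAZ", "KGZ", "TJK", "TKM", "UZB")))
  expect_false(any(duplicated(cat_$station_id)))
})

test_that("config validation rejects bad settings", {
  expect_error(synthetic_config(start_year = 2000, end_year = 1999),
               "end_year")
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(gcm_var_inflation = 0), "inflation")
  expect_error(synthetic_config(ar1_coeff = 1), "ar1")
})

test_that("injected episodes are recovered by the heatwave detector", {
  # episode_boost 5 degC over noise_sd 1: the detector should find at
  # least 90% of injected episodes on average across seeds, at the
  # generator's stated 1959-2021 span (short spans let binomial noise in
  # the ~7% boosted share of a window pool push the 90th-percentile
  # threshold into the boost cluster)
  n_seeds <- 100
  rates <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    cfg <- synthetic_config(trend = 0, noise_sd = 1, episode_boost = 5,
                            seed = 5000 + k)
    s <- generate_reference_series(spec1, cfg)
    ep <- attr(s, "episodes")
    if (nrow(ep) == 0) { rates[k] <- NA; next }
    clim <- calendar_day_percentile(s, "tmax")
    ev <- detect_heatwaves(s, clim, min_duration = 3)
    hit <- mapply(function(a, b)
      any(ev$start_date <= b & ev$end_date >= a), ep$start, ep$end)
    rates[k] <- mean(hit)
  }
  expect_gte(mean(rates, na.rm = TRUE), 0.9)
})
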