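#' Default pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Defaults mirror the
#' emulated study design: a 1959-2021-style historical window, a near
#' future (2022-2051) and a far future (2071-2100), two pseudo-GCMs under
#' an intermediate and a high emission scenario, TX90/TN90 thresholds from
#' a 15-day window, 3-day minimum heatwave duration, RR = 1.20
#' (1.02, 1.41), IDW with four neighbours, and 0.1-degree display rasters.
#'
#' @param ... overrides for any field.
#' @return a named list (class `pipeline_config`).
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    n_stations = 20L,
    hist_start = 1962L, hist_end = 2021L,
    near_start = 2022L, near_end = 2051L,
    far_start = 2071L, far_end = 2100L,
    n_models = 2L,
    scenarios = c("SSP2-4.5", "SSP5-8.5"),
    # post-historical warming rates per scenario, degC/year
    scenario_trends = c(0.03, 0.06),
    baseline_mean = 18, seasonal_amplitude = 17, trend = 0.04,
    ar1_coeff = 0.7, noise_sd = 3, episode_rate = 2, episode_boost = 6,
    gcm_bias = 2, gcm_var_inflation = 1.3,
    q = 90, window_halfwidth = 7L, min_duration = 3L,
    rr = 1.20, rr_low = 1.02, rr_high = 1.41,
    idw_k = 4L, idw_power = 2, raster_cell = 0.1,
    bbox = c(lon_min = 46, lon_max = 87, lat_min = 35, lat_max = 55),
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm, call. = FALSE)
    cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a flat-key pipeline config file
#'
#' The file is a Debian-control-style ("flat key") text file: one
#' `Field: value` pair per line, comma-separated values for vector fields.
#' The seed is mandatory.
#'
#' @param path file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- read.dcf(path)
  if (nrow(raw) != 1) stop("config must have exactly one record", call. = FALSE)
  kv <- as.list(raw[1, ])
  if (is.null(kv$seed) || is.na(kv$seed))
    stop("configuration error: seed is mandatory in the config file",
         call. = FALSE)
  parsed <- list()
  for (nm in names(kv)) {
    v <- strsplit(kv[[nm]], ",[ ]*")[[1]]
    num <- suppressWarnings(as.numeric(v))
    parsed[[nm]] <- if (anyNA(num)) v else num
  }
  int_fields <- c("n_stations", "hist_start", "hist_end", "near_start",
                  "near_end", "far_start", "far_end", "n_models",
                  "window_halfwidth", "min_duration", "idw_k", "seed")
  for (nm in intersect(int_fields, names(parsed)))
    parsed[[nm]] <- as.integer(parsed[[nm]])
  if (!is.null(parsed$bbox))
    names(parsed$bbox) <- c("lon_min", "lon_max", "lat_min", "lat_max")
  do.call(default_pipeline_config, parsed)
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  flat <- vapply(unclass(cfg), function(v) paste(format(v, trim = TRUE),
                                                 collapse = ", "),
                 character(1))
  write.dcf(t(as.matrix(flat)), path)
  invisible(path)
}

.periods <- function(cfg) {
  list(historical = c(cfg$hist_start, cfg$hist_end),
       near = c(cfg$near_start, cfg$near_end),
       far = c(cfg$far_start, cfg$far_end))
}

.index_cols <- c("tx90p", "tn90p", "hwn", "hwf", "hwd", "hwm", "hwa")

#' Run the full analysis pipeline
#'
#' Executes: synthetic generation (catalogue, reference series, pseudo-GCM
#' members per scenario, demography) -> threshold climatologies (frozen on
#' the historical reference) -> yearly indices for the reference and for
#' each bias-corrected scenario ensemble over historical/near/far windows
#' -> per-month correction evaluation -> Mann-Kendall/Sen trend tables per
#' (index, period, scenario) -> regional severity classification ->
#' country mortality burdens -> IDW display rasters -> a JSON manifest.
#' All outputs are plain CSV (plus the manifest); reruns with the same
#' config and seed are byte-identical.
#'
#' @param cfg a [default_pipeline_config()] (or from
#'   [read_pipeline_config()]).
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg = default_pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(x, name, writer = write_table_csv) {
    p <- file.path(out_dir, name)
    writer(x, p)
    files <<- c(files, name)
    p
  }

  scfg <- synthetic_config(
    n_stations = cfg$n_stations, start_year = cfg$hist_start,
    end_year = cfg$hist_end, baseline_mean = cfg$baseline_mean,
    seasonal_amplitude = cfg$seasonal_amplitude, trend = cfg$trend,
    ar1_coeff = cfg$ar1_coeff, noise_sd = cfg$noise_sd,
    episode_rate = cfg$episode_rate, episode_boost = cfg$episode_boost,
    gcm_bias = cfg$gcm_bias, gcm_var_inflation = cfg$gcm_var_inflation,
    seed = cfg$seed)
  periods <- .periods(cfg)

  ## --- stage: generate -------------------------------------------------
  catalogue <- station_catalogue(cfg$n_stations, bbox = cfg$bbox,
                                 seed = cfg$seed)
  emit(catalogue, "stations.csv")
  refs <- lapply(seq_len(nrow(catalogue)), function(i)
    generate_reference_series(catalogue[i, ], scfg))
  names(refs) <- catalogue$station_id
  ref_long <- data.table::rbindlist(lapply(refs, function(s)
    data.table::data.table(station_id = station_id(s),
                           date = format(s$date, "%Y-%m-%d"),
                           tmax_c = s$tmax, tmin_c = s$tmin)))
  emit(ref_long, "reference_daily.csv",
       writer = function(x, p) data.table::fwrite(x, p))
  demog <- generate_demography(sort(unique(catalogue$country)),
                               cfg$hist_start:cfg$far_end, seed = cfg$seed)
  emit(demog, "demography.csv")

  ## --- stage: thresholds + reference indices ---------------------------
  clim_tx <- lapply(refs, calendar_day_percentile, variable = "tmax",
                    q = cfg$q, window_halfwidth = cfg$window_halfwidth)
  clim_tn <- lapply(refs, calendar_day_percentile, variable = "tmin",
                    q = cfg$q, window_halfwidth = cfg$window_halfwidth)
  ref_idx <- do.call(rbind, lapply(catalogue$station_id, function(sid)
    compute_yearly_indices(refs[[sid]], clim_tx[[sid]], clim_tn[[sid]],
                           min_duration = cfg$min_duration)))
  emit(ref_idx, "indices_reference_historical.csv",
       writer = write_indices_csv)

  ## --- stage: correct (pseudo-GCMs, bias correction, ensembling) -------
  ens_idx <- list(); eval_rows <- list()
  for (si in seq_along(cfg$scenarios)) {
    scen <- cfg$scenarios[si]
    corrected <- list()
    for (sid in catalogue$station_id) {
      members <- lapply(seq_len(cfg$n_models), function(m) {
        raw <- generate_gcm_series(refs[[sid]], scfg, end_year = cfg$far_end,
                                   future_trend = cfg$scenario_trends[si],
                                   member = m + 100L * si)
        px <- fit_bias_params(refs[[sid]], raw, "tmax")
        pn <- fit_bias_params(refs[[sid]], raw, "tmin")
        cor <- apply_bias_correction(apply_bias_correction(raw, px), pn)
        if (m == 1L && si == 1L) {
          raw_h <- window_years(raw, cfg$hist_start, cfg$hist_end)
          cor_h <- window_years(cor, cfg$hist_start, cfg$hist_end)
          eval_rows[[sid]] <<- evaluate_correction(refs[[sid]], raw_h, cor_h,
                                                   "tmax")
        }
        cor
      })
      corrected[[sid]] <- ensemble_mean(members)
    }
    for (per in names(periods)) {
      w <- periods[[per]]
      idx <- do.call(rbind, lapply(catalogue$station_id, function(sid) {
        s <- window_years(corrected[[sid]], w[1], w[2])
        compute_yearly_indices(s, clim_tx[[sid]], clim_tn[[sid]],
                               min_duration = cfg$min_duration)
      }))
      ens_idx[[paste(scen, per, sep = "|")]] <- idx
      emit(idx, sprintf("indices_ensemble_%s_%s.csv", gsub("[^A-Za-z0-9.-]", "", scen), per),
           writer = write_indices_csv)
    }
  }
  emit(do.call(rbind, eval_rows), "correction_evaluation.csv")

  ## --- stage: trends ----------------------------------------------------
  for (key in names(ens_idx)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    for (index in .index_cols) {
      tt <- trend_table(ens_idx[[key]], index)
      tt$period <- parts[2]; tt$scenario <- parts[1]
      emit(tt, sprintf("trends_%s_%s_%s.csv", index, parts[2],
                       gsub("[^A-Za-z0-9.-]", "", parts[1])))
    }
  }

  ## --- stage: severity --------------------------------------------------
  sev <- do.call(rbind, lapply(sort(unique(ref_idx$year)), function(y) {
    d <- ref_idx[ref_idx$year == y, ]
    rc <- regional_category(stats::setNames(d$hwm, d$station_id))
    data.frame(year = y, regional_category = as.character(rc$label),
               stringsAsFactors = FALSE)
  }))
  emit(sev, "severity_reference_historical.csv")

  ## --- stage: burden ----------------------------------------------------
  burdens <- list(
    country_burden(ref_idx, catalogue, demog, rr = cfg$rr,
                   rr_ci = c(cfg$rr_low, cfg$rr_high),
                   scenario = "reference-historical"))
  for (key in names(ens_idx)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    burdens[[key]] <- country_burden(
      ens_idx[[key]], catalogue, demog, rr = cfg$rr,
      rr_ci = c(cfg$rr_low, cfg$rr_high),
      scenario = paste(parts[1], parts[2], sep = "-"))
  }
  burden <- do.call(rbind, burdens)
  rownames(burden) <- NULL
  emit(burden, "burden_country_year.csv")
  emit(region_totals(burden), "burden_region_totals.csv")

  ## --- stage: rasterize -------------------------------------------------
  grid <- raster_spec(cfg$bbox[["lon_min"]], cfg$bbox[["lon_max"]],
                      cfg$bbox[["lat_min"]], cfg$bbox[["lat_max"]],
                      cell = cfg$raster_cell)
  mean_tx90p <- stats::aggregate(tx90p ~ station_id, data = ref_idx, FUN = mean)
  pts <- merge(catalogue, mean_tx90p, by = "station_id")
  r1 <- idw_interpolate(data.frame(lon = pts$lon, lat = pts$lat,
                                   value = pts$tx90p),
                        grid, k = cfg$idw_k, power = cfg$idw_power)
  emit(r1, "raster_mean_tx90p_reference.csv", writer = write_raster_csv)
  tt_hwf <- trend_table(ref_idx, "hwf")
  pts2 <- merge(catalogue, tt_hwf[, c("station_id", "slope")],
                by = "station_id")
  r2 <- idw_interpolate(data.frame(lon = pts2$lon, lat = pts2$lat,
                                   value = pts2$slope),
                        grid, k = cfg$idw_k, power = cfg$idw_power)
  emit(r2, "raster_hwf_trend_reference.csv", writer = write_raster_csv)
  display <- data.frame(
    raster = c("raster_mean_tx90p_reference", "raster_hwf_trend_reference"),
    signed = c(FALSE, TRUE))
  bounds <- rbind(clip_for_display(r1, signed = FALSE),
                  clip_for_display(r2, signed = TRUE))
  display$lower <- bounds[, 1]; display$upper <- bounds[, 2]
  emit(display, "display_bounds.csv")

  ## --- manifest ---------------------------------------------------------
  cfg_path <- file.path(out_dir, "config_used.dcf")
  write_pipeline_config(cfg, cfg_path)
  files <- c(files, "config_used.dcf")
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    decisions = c(
      "min_duration 3 days (ETCCDI/ClimPACT heatwave-aspects convention)",
      "15-day calendar-day percentile window, type-7 estimator, strict exceedance",
      "thresholds frozen on the historical reference for future periods",
      "monthly stratification of the mean-variance correction",
      "bias-correct each member, then equal-weight ensemble",
      "Sen's slope reported; no pre-whitening",
      "country heatwave days = mean station HWF",
      "IDW: k=4, power=2, planar degrees"),
    files = lapply(stats::setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
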