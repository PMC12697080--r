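#' Fit mean-variance bias-correction parameters per calendar month
#'
#' For each calendar month, pools all daily values of the overlap years and
#' records the reference mean/sd (`mu_o`, `sigma_o`) and model historical
#' mean/sd (`mu_m`, `sigma_m`). These four moments drive the affine
#' correction `x_hat = mu_o + (sigma_o / sigma_m) * (x - mu_m)`.
#'
#' @param ref,model [daily_series()] objects covering the overlap.
#' @param variable `"tmax"` or `"tmin"`.
#' @param overlap length-2 integer vector `c(start_year, end_year)`;
#'   default the intersection of the two series' spans.
#' @return a `bias_params` data.frame: one row per month with columns
#'   `month`, `mu_o`, `sigma_o`, `mu_m`, `sigma_m`; attributes `station_id`
#'   and `variable`.
#' @export
fit_bias_params <- function(ref, model, variable = c("tmax", "tmin"),
                            overlap = NULL) {
  variable <- match.arg(variable)
  ry <- date_year(ref$date); my <- date_year(model$date)
  if (is.null(overlap))
    overlap <- c(max(min(ry), min(my)), min(max(ry), max(my)))
  if (overlap[1] > overlap[2])
    stop("data error: empty overlap period", call. = FALSE)
  rsel <- ry >= overlap[1] & ry <= overlap[2]
  msel <- my >= overlap[1] & my <= overlap[2]
  rmon <- date_month(ref$date[rsel]); mmon <- date_month(model$date[msel])
  rv <- ref[[variable]][rsel]; mv <- model[[variable]][msel]
  out <- data.frame(month = 1:12, mu_o = NA_real_, sigma_o = NA_real_,
                    mu_m = NA_real_, sigma_m = NA_real_)
  for (m in 1:12) {
    o <- rv[rmon == m]; x <- mv[mmon == m]
    if (!length(o) || !length(x))
      stop("data error: no overlap days in month ", m, call. = FALSE)
    out$mu_o[m] <- mean(o); out$sigma_o[m] <- stats::sd(o)
    out$mu_m[m] <- mean(x); out$sigma_m[m] <- stats::sd(x)
    if (out$sigma_o[m] == 0 || out$sigma_m[m] == 0)
      stop("degenerate-data error: zero variance in month ", m, call. = FALSE)
  }
  attr(out, "station_id") <- station_id(ref)
  attr(out, "variable") <- variable
  class(out) <- c("bias_params", "data.frame")
  out
}

#' Apply the mean-variance correction
#'
#' Elementwise `x_hat = mu_o + (sigma_o / sigma_m) * (x - mu_m)`, each day
#' corrected with its calendar month's parameters. For a `daily_series`
#' the variable recorded in `params` is replaced by its corrected values;
#' for a bare numeric vector supply the month of each element.
#'
#' @param x a [daily_series()] or numeric vector.
#' @param params a [fit_bias_params()] table.
#' @param month for numeric `x`: integer month (1-12) per element
#'   (recycled); ignored for a `daily_series`.
#' @return object of the same shape as `x`, corrected.
#' @export
apply_bias_correction <- function(x, params, month = NULL) {
  UseMethod("apply_bias_correction")
}

.correct_values <- function(v, mon, params) {
  if (!all(mon %in% params$month))
    stop("configuration error: missing month parameters", call. = FALSE)
  i <- match(mon, params$month)
  if (any(params$sigma_m[i] <= 0))
    stop("configuration error: sigma_m must be > 0", call. = FALSE)
  params$mu_o[i] + (params$sigma_o[i] / params$sigma_m[i]) * (v - params$mu_m[i])
}

#' @export
apply_bias_correction.numeric <- function(x, params, month = NULL) {
  if (is.null(month)) {
    if (nrow(params) == 1L) month <- params$month
    else stop("configuration error: month required for numeric input",
              call. = FALSE)
  }
  .correct_values(x, rep_len(as.integer(month), length(x)), params)
}

#' @export
apply_bias_correction.daily_series <- function(x, params, month = NULL) {
  v <- attr(params, "variable")
  mon <- date_month(x$date)
  x[[v]] <- .correct_values(x[[v]], mon, params)
  # affine maps with different monthly parameters for tmax/tmin can, in
  # principle, cross; leave the series unvalidated
  attr(x, "corrected") <- c(attr(x, "corrected"), v)
  x
}

#' Mean bias of a model against a reference
#'
#' `mean(b - o)`; positive means the model is too warm.
#'
#' @param b model (raw or corrected) values, degC.
#' @param o reference values, degC; same length and dates as `b`.
#' @return scalar bias, degC.
#' @export
bias <- function(b, o) {
  if (length(b) != length(o) || length(b) < 1)
    stop("data error: b and o must have equal length >= 1", call. = FALSE)
  mean(b - o)
}

#' Root-mean-square error of a model against a reference
#'
#' `sqrt(mean((b - o)^2))`; always at least `|bias(b, o)|`.
#'
#' @inheritParams bias
#' @return scalar RMSE, degC.
#' @export
rmse <- function(b, o) {
  if (length(b) != length(o) || length(b) < 1)
    stop("data error: b and o must have equal length >= 1", call. = FALSE)
  sqrt(mean((b - o)^2))
}

#' Equal-weight ("one model, one vote") ensemble mean
#'
#' Unweighted elementwise mean of member series sharing dates and station.
#'
#' @param members list of [daily_series()] objects.
#' @return a [daily_series()].
#' @export
ensemble_mean <- function(members) {
  if (length(members) < 1) stop("data error: empty ensemble", call. = FALSE)
  d0 <- members[[1]]$date
  for (m in members[-1])
    if (length(m$date) != length(d0) || any(m$date != d0))
      stop("data error: ensemble members are not date-aligned", call. = FALSE)
  tmax <- rowMeans(do.call(cbind, lapply(members, `[[`, "tmax")))
  tmin <- rowMeans(do.call(cbind, lapply(members, `[[`, "tmin")))
  daily_series(d0, tmax, tmin, station_id = station_id(members[[1]]),
               validate = FALSE)
}

#' Raw-vs-corrected evaluation table
#'
#' Per calendar month, bias and RMSE of the raw and corrected model series
#' against the reference over an evaluation period.
#'
#' @param ref,raw,corrected [daily_series()] objects on identical dates.
#' @param variable `"tmax"` or `"tmin"`.
#' @param period optional `c(start_year, end_year)` restriction.
#' @return data.frame with `station_id`, `month`, `variable`, `bias_raw`,
#'   `bias_corrected`, `rmse_raw`, `rmse_corrected`.
#' @export
evaluate_correction <- function(ref, raw, corrected,
                                variable = c("tmax", "tmin"), period = NULL) {
  variable <- match.arg(variable)
  keep <- rep(TRUE, nrow(ref))
  if (!is.null(period)) {
    yr <- date_year(ref$date)
    keep <- yr >= period[1] & yr <= period[2]
  }
  mon <- date_month(ref$date[keep])
  o <- ref[[variable]][keep]; b0 <- raw[[variable]][keep]
  b1 <- corrected[[variable]][keep]
  do.call(rbind, lapply(1:12, function(m) {
    s <- mon == m
    data.frame(station_id = station_id(ref), month = m, variable = variable,
               bias_raw = bias(b0[s], o[s]),
               bias_corrected = bias(b1[s], o[s]),
               rmse_raw = rmse(b0[s], o[s]),
               rmse_corrected = rmse(b1[s], o[s]),
               stringsAsFactors = FALSE)
  }))
}
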