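#' Mann-Kendall trend test with Sen's slope
#'
#' Rank-based test for a monotone trend in a yearly series. The statistic
#' is `S = sum_{i<j} sign(y_j - y_i)`; its variance uses the standard tie
#' correction, the normal deviate applies a +/-1 continuity correction, and
#' the p-value is two-sided. Missing values are dropped (their time
#' positions are kept for the slope). A constant series returns `S = 0`,
#' `p = 1`, `slope = 0` rather than an error.
#'
#' @param y numeric vector of yearly index values (NAs allowed).
#' @param alpha significance level (default 0.05).
#' @return an `mk_test` list: `s_statistic`, `var_s`, `z`, `p_value`,
#'   `slope` (Sen's estimator, units of `y` per step), `significant`,
#'   `alpha`, `n`.
#' @export
mann_kendall <- function(y, alpha = 0.05) {
  x <- seq_along(y)
  ok <- !is.na(y)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 4)
    stop("insufficient data: Mann-Kendall needs n >= 4 non-missing values",
         call. = FALSE)
  s <- sum(sign(outer(y, y, "-"))[lower.tri(matrix(0, n, n))])
  ties <- table(y)
  t_i <- as.numeric(ties[ties > 1])
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(t_i * (t_i - 1) * (2 * t_i + 5))) / 18
  z <- if (var_s == 0) 0 else if (s > 0) (s - 1) / sqrt(var_s)
       else if (s < 0) (s + 1) / sqrt(var_s) else 0
  p <- 2 * stats::pnorm(-abs(z))
  slope <- if (var_s == 0 && s == 0 && length(unique(y)) == 1L) 0
           else sens_slope(y, x)
  structure(list(s_statistic = s, var_s = var_s, z = z, p_value = p,
                 slope = slope, significant = p < alpha, alpha = alpha,
                 n = n),
            class = "mk_test")
}

#' @export
print.mk_test <- function(x, ...) {
  cat(sprintf(
    "Mann-Kendall: S = %d, z = %.3f, p = %.4g, Sen slope = %.4g (%s at %g%%)\n",
    x$s_statistic, x$z, x$p_value, x$slope,
    if (x$significant) "significant" else "not significant", 100 * x$alpha))
  invisible(x)
}

#' Sen's slope estimator
#'
#' Median of all pairwise slopes `(y_j - y_i) / (x_j - x_i)`, `i < j`.
#'
#' @param y numeric values (NAs dropped pairwise with their positions).
#' @param x time positions (default `1..n`).
#' @return slope in units of `y` per unit of `x`.
#' @export
sens_slope <- function(y, x = seq_along(y)) {
  force(x)
  ok <- !is.na(y)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 2) stop("insufficient data: Sen's slope needs n >= 2", call. = FALSE)
  dy <- outer(y, y, "-"); dx <- outer(x, x, "-")
  lt <- lower.tri(dx)
  stats::median(dy[lt] / dx[lt])
}

#' Per-station trend table for a yearly-indices data frame
#'
#' Runs [mann_kendall()] on each station's series of one index column.
#'
#' @param indices data.frame from [compute_yearly_indices()] (several
#'   stations row-bound).
#' @param index column name, e.g. `"tx90p"` or `"hwf"`.
#' @param alpha significance level.
#' @return data.frame `station_id`, `index`, `n`, `slope`, `p_value`,
#'   `significant`. Stations with fewer than 4 non-missing years get NA
#'   results rather than an error.
#' @export
trend_table <- function(indices, index, alpha = 0.05) {
  do.call(rbind, lapply(split(indices, indices$station_id), function(d) {
    d <- d[order(d$year), ]
    y <- d[[index]]
    if (sum(!is.na(y)) < 4) {
      res <- data.frame(slope = NA_real_, p_value = NA_real_,
                        significant = NA)
    } else {
      mk <- mann_kendall(y, alpha = alpha)
      res <- data.frame(slope = mk$slope, p_value = mk$p_value,
                        significant = mk$significant)
    }
    cbind(data.frame(station_id = d$station_id[1], index = index,
                     n = sum(!is.na(y)), stringsAsFactors = FALSE), res)
  }))
}
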