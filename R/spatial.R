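#' Regular lon/lat grid specification
#'
#' @param lon_min,lon_max,lat_min,lat_max bounding box, degrees; should
#'   cover the station network.
#' @param cell cell size in degrees (default 0.1, the display resolution
#'   the pipeline emulates).
#' @return a `raster_spec` list with cell-center coordinate vectors.
#' @export
raster_spec <- function(lon_min, lon_max, lat_min, lat_max, cell = 0.1) {
  if (cell <= 0) stop("cell size must be > 0", call. = FALSE)
  structure(list(
    lon = seq(lon_min + cell / 2, lon_max, by = cell),
    lat = seq(lat_min + cell / 2, lat_max, by = cell),
    cell = cell, origin = c(lon = lon_min, lat = lat_min)
  ), class = "raster_spec")
}

#' Inverse-distance-weighted interpolation onto a grid
#'
#' Each cell takes the weighted mean of its `k` nearest stations with
#' weights `d^-power`; a cell coinciding with a station takes that
#' station's value exactly. Distances are planar in lon/lat degrees (the
#' display convention; no projection is applied).
#'
#' @param points data.frame with `lon`, `lat`, `value`.
#' @param grid a [raster_spec()].
#' @param k number of nearest stations per cell (default 4).
#' @param power inverse-distance exponent (default 2).
#' @return a `raster`: list with `lon`, `lat`, `values` (matrix
#'   `length(lat) x length(lon)`), `cell`.
#' @export
idw_interpolate <- function(points, grid, k = 4L, power = 2) {
  if (nrow(points) < k)
    stop("configuration error: fewer points (", nrow(points),
         ") than k (", k, ")", call. = FALSE)
  dup <- duplicated(points[, c("lon", "lat")])
  if (any(dup)) {
    full <- paste(points$lon, points$lat, points$value)
    if (any(duplicated(points[, c("lon", "lat")]) & !duplicated(full)))
      stop("duplicate coordinates with conflicting values", call. = FALSE)
    points <- points[!dup, , drop = FALSE]
  }
  cells <- expand.grid(lon = grid$lon, lat = grid$lat)
  # ncell x nstation squared distances
  d2 <- outer(cells$lon, points$lon, "-")^2 + outer(cells$lat, points$lat, "-")^2
  vals <- apply(d2, 1L, function(row) {
    nn <- order(row)[seq_len(k)]
    d <- sqrt(row[nn])
    if (d[1] == 0) return(points$value[nn[1]])
    w <- d^(-power)
    sum(w * points$value[nn]) / sum(w)
  })
  structure(list(lon = grid$lon, lat = grid$lat,
                 values = matrix(vals, nrow = length(grid$lat),
                                 ncol = length(grid$lon), byrow = TRUE),
                 cell = grid$cell),
            class = "raster")
}

#' Display bounds for a group of rasters
#'
#' Pools all finite cells of the rasters and returns colour-bar limits:
#' the 2nd and 98th percentiles, or for signed fields the symmetric range
#' `(-M, +M)` with `M = max(|p2|, |p98|)` so zero sits at the centre.
#' Percentiles use the same type-7 estimator as the threshold
#' climatologies.
#'
#' @param rasters a `raster` or list of `raster` objects.
#' @param signed `TRUE` for fields mixing negative and positive values.
#' @param probs the two pooled percentiles (default `c(0.02, 0.98)`).
#' @return numeric `c(lower, upper)`.
#' @export
clip_for_display <- function(rasters, signed = FALSE, probs = c(0.02, 0.98)) {
  if (inherits(rasters, "raster")) rasters <- list(rasters)
  v <- unlist(lapply(rasters, function(r) r$values), use.names = FALSE)
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("data error: no finite cells", call. = FALSE)
  p <- stats::quantile(v, probs, type = 7, names = FALSE)
  if (signed) {
    m <- max(abs(p))
    c(-m, m)
  } else p
}

#' Write a raster as a tidy lon/lat/value CSV
#'
#' @param r a `raster`.
#' @param path file path.
#' @export
write_raster_csv <- function(r, path) {
  dt <- data.table::data.table(
    lon = rep(r$lon, each = length(r$lat)),
    lat = rep(r$lat, times = length(r$lon)),
    value = as.vector(r$values))
  data.table::fwrite(dt, path)
  invisible(path)
}
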