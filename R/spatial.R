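# Core IDW evaluation: query points x data points, planar distance in
# degree coordinates. Queries coinciding with a data point (within eps)
# return that point's value exactly.
idw_values <- function(qx, qy, px, py, pz, power, eps = 1e-12) {
  out <- numeric(length(qx))
  for (i in seq_along(qx)) {
    d2 <- (qx[i] - px)^2 + (qy[i] - py)^2
    hit <- which(d2 <= eps^2)
    if (length(hit)) {
      out[i] <- pz[hit[1]]
    } else {
      w <- d2^(-power / 2)
      out[i] <- sum(w * pz) / sum(w)
    }
  }
  out
}

#' Inverse-distance-weighted interpolation
#'
#' Interpolates point observations onto a regular grid with
#' \eqn{\hat z(x) = \sum_i w_i z_i / \sum_i w_i}, \eqn{w_i = d(x, x_i)^{-p}}
#' using planar Euclidean distance on degree coordinates (the study region
#' spans about 1.3 degrees, where planar distortion is negligible; set
#' `haversine = TRUE` for great-circle metres). IDW is an exact, convex
#' interpolator: grid cells at sample locations reproduce the sample value
#' and every interpolated value lies within the input range.
#'
#' @param points data.frame with columns `lon`, `lat`, `value`.
#' @param grid optional list with `n_rows`, `n_cols`, `bbox`
#'   (`c(lon_min, lon_max, lat_min, lat_max)`); defaults to 100 x 100 over
#'   the points' bounding box padded by 5%.
#' @param power IDW power (default 2).
#' @param haversine use great-circle distance in metres instead of planar
#'   degrees.
#' @return a `spatial_field`: list with `values` (n_rows x n_cols matrix,
#'   row 1 = southernmost), `lon` and `lat` cell-centre coordinates,
#'   `origin`, `cell_size`, `power`, `points`.
#' @export
idw <- function(points, grid = NULL, power = 2, haversine = FALSE) {
  stopifnot(all(c("lon", "lat", "value") %in% names(points)))
  if (nrow(points) < 1) {
    invanet_error("invanet_invalid_argument", "need at least one point")
  }
  key <- paste(points$lon, points$lat)
  if (anyDuplicated(key)) {
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    agg <- tapply(points$value, key, function(v) length(unique(v)))
    if (any(agg > 1)) {
      invanet_error("invanet_duplicate_coordinates",
                    "duplicate coordinates with conflicting values")
    }
    points <- points[!duplicated(key), , drop = FALSE]
  }
  if (is.null(grid)) {
    pad <- function(rng) rng + c(-1, 1) * 0.05 * diff(rng)
    bbox <- c(pad(range(points$lon)), pad(range(points$lat)))
    grid <- list(n_rows = 100, n_cols = 100, bbox = bbox)
  }
  lon_seq <- seq(grid$bbox[1], grid$bbox[2], length.out = grid$n_cols)
  lat_seq <- seq(grid$bbox[3], grid$bbox[4], length.out = grid$n_rows)
  qx <- rep(lon_seq, times = grid$n_rows)
  qy <- rep(lat_seq, each = grid$n_cols)
  if (haversine) {
    vals <- vapply(seq_along(qx), function(i) {
      d <- haversine_m(qx[i], qy[i], points$lon, points$lat)
      hit <- which(d <= 1e-6)
      if (length(hit)) return(points$value[hit[1]])
      w <- d^(-power)
      sum(w * points$value) / sum(w)
    }, numeric(1))
  } else {
    vals <- idw_values(qx, qy, points$lon, points$lat, points$value, power)
  }
  structure(list(
    values = matrix(vals, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE),
    lon = lon_seq, lat = lat_seq,
    origin = c(grid$bbox[1], grid$bbox[3]),
    cell_size = c(diff(grid$bbox[1:2]) / (grid$n_cols - 1),
                  diff(grid$bbox[3:4]) / (grid$n_rows - 1)),
    power = power, points = points
  ), class = "spatial_field")
}

haversine_m <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  6371000 * 2 * asin(pmin(1, sqrt(a)))
}

#' @rdname idw
#' @param field a `spatial_field`.
#' @param lon,lat query coordinates.
#' @return `idw_query`: interpolated values at the query points.
#' @export
idw_query <- function(field, lon, lat) {
  idw_values(lon, lat, field$points$lon, field$points$lat,
             field$points$value, field$power)
}

#' Write a spatial field as an ESRI ASCII raster
#'
#' @param field a `spatial_field` from [idw()].
#' @param path output path.
#' @export
write_ascii_grid <- function(field, path) {
  hdr <- c(
    sprintf("ncols %d", ncol(field$values)),
    sprintf("nrows %d", nrow(field$values)),
    sprintf("xllcorner %.10g", field$origin[1]),
    sprintf("yllcorner %.10g", field$origin[2]),
    sprintf("cellsize %.10g", field$cell_size[1]),
    "NODATA_value -9999"
  )
  # ASCII grids list rows north to south
  rows <- apply(field$values[rev(seq_len(nrow(field$values))), , drop = FALSE],
                1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' North-south contrast of gene-category abundances
#'
#' Splits samples at a latitude (default: the median sample latitude) and
#' compares each abundance column between the northern and southern strata
#' with the Kruskal-Wallis test, reporting the median difference
#' (north minus south).
#'
#' @param values samples x categories numeric matrix.
#' @param lat per-sample latitude.
#' @param split_latitude boundary; samples strictly north of it form the
#'   northern stratum.
#' @return data.frame: category, median_north, median_south,
#'   median_difference, H, p_value.
#' @export
north_south_contrast <- function(values, lat, split_latitude = NULL) {
  v <- as.matrix(values)
  split_latitude <- split_latitude %||% stats::median(lat)
  north <- lat > split_latitude
  if (all(north) || !any(north)) {
    invanet_error("invanet_invalid_argument",
                  "all samples fall on one side of the split latitude")
  }
  strata <- factor(ifelse(north, "north", "south"), levels = c("north", "south"))
  if (is.null(colnames(v))) colnames(v) <- paste0("V", seq_len(ncol(v)))
  res <- lapply(colnames(v), function(cc) {
    z <- v[, cc]
    mn <- stats::median(z[north])
    ms <- stats::median(z[!north])
    if (length(unique(z)) == 1L) {
      return(data.frame(category = cc, median_north = mn, median_south = ms,
                        median_difference = mn - ms, H = 0, p_value = 1))
    }
    kt <- stats::kruskal.test(z, strata)
    data.frame(category = cc, median_north = mn, median_south = ms,
               median_difference = mn - ms, H = unname(kt$statistic),
               p_value = unname(kt$p.value))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
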