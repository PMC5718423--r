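#' Gridded geophysical context field (bathymetry or coast distance)
#'
#' Cell-centre registered values on an equal-angle grid. Bathymetry is
#' stored as positive depth in meters (elevation-style sources should be
#' negated on read); coast distance is non-negative kilometers.
#'
#' @param values numeric matrix (row 1 = northernmost row of cells);
#'   NA marks nodes without data (e.g. land)
#' @param grid a [grid_spec()]
#' @param quantity "bathymetry_m" or "coast_distance_km"
#' @return an object of class `context_grid`
#' @export
context_grid <- function(values, grid,
                         quantity = c("bathymetry_m", "coast_distance_km")) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  if (any(values < 0, na.rm = TRUE)) {
    stop(quantity, " must be non-negative (bathymetry is positive-down)")
  }
  structure(list(values = values, grid = grid, quantity = quantity,
                 node_registration = "cell_centre"),
            class = "context_grid")
}

#' @export
print.context_grid <- function(x, ...) {
  cat(sprintf("<context_grid> %s, %d x %d nodes (cell centres)\n",
              x$quantity, x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

# lat/lon of node centres for 0-based row/col indices
node_lat <- function(grid, row) grid$lat_max - (row + 0.5) * grid$cell_size_deg
node_lon <- function(grid, col) {
  normalize_lon(grid$lon_min + (col + 0.5) * grid$cell_size_deg)
}

#' Inverse-distance-weighted interpolation on a context grid
#'
#' Interpolates a context grid at arbitrary positions with weights
#' 1/d^power over the k nearest non-missing nodes (default: inverse
#' squared distance over the 4 nodes around the query, i.e. the enclosing
#' cell-centre quad). Distances are great-circle (haversine) meters. A
#' query within `eps_m` of a node returns that node's value exactly; a
#' query with no non-missing node in reach returns NA.
#'
#' @param grid a [context_grid()]
#' @param lat,lon query position(s), degrees; recycled to common length
#' @param power inverse-distance exponent (2 = inverse squared)
#' @param k number of nearest non-missing nodes to combine
#' @param eps_m node-coincidence tolerance, meters
#' @param max_half_width farthest node search reach, in grid cells: a
#'   query with no non-missing node within this many cells is outside
#'   the grid's coverage and returns NA rather than an interpolation
#'   across a large gap
#' @return numeric vector of interpolated values (NA where unresolvable)
#' @export
idw_interpolate <- function(grid, lat, lon, power = 2, k = 4L, eps_m = 1,
                            max_half_width = 3L) {
  stopifnot(inherits(grid, "context_grid"))
  g <- grid$grid
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n)
  lon <- normalize_lon(rep_len(lon, n))
  out <- rep(NA_real_, n)
  max_w <- max(ceiling(sqrt(k)), max_half_width)
  idx <- grid_index(lat, lon, g)
  for (i in seq_len(n)) {
    w <- 2L
    repeat {
      rows <- (idx$row[i] - w):(idx$row[i] + w)
      rows <- rows[rows >= 0 & rows < g$n_rows]
      # meridians converge poleward, so the nearest nodes can sit several
      # columns away: widen the column window by 1/cos(lat)
      wc <- min(ceiling(w / max(0.05, cos(lat[i] * pi / 180))),
                g$n_cols %/% 2)
      cols <- unique(((idx$col[i] - wc):(idx$col[i] + wc)) %% g$n_cols)
      rc <- expand.grid(row = rows, col = cols)
      v <- grid$values[cbind(rc$row + 1L, rc$col + 1L)]
      ok <- !is.na(v)
      if (sum(ok) >= k || w >= max_w) break
      w <- w + 1L
    }
    if (!any(ok)) next
    rc <- rc[ok, , drop = FALSE]
    v <- v[ok]
    d <- geosphere::distHaversine(
      cbind(lon[i], lat[i]),
      cbind(node_lon(g, rc$col), node_lat(g, rc$row)))
    o <- order(d)[seq_len(min(k, length(d)))]
    d <- d[o]; v <- v[o]
    if (d[1] < eps_m) {
      out[i] <- v[1]
    } else {
      wts <- 1 / d^power
      out[i] <- sum(wts * v) / sum(wts)
    }
  }
  out
}

#' Annotate matchups with bathymetry and coast distance
#'
#' Interpolates both context grids at every record's position by
#' inverse-squared-distance weighting, then applies the coastal QC flag.
#' Record count and order are preserved; positions unresolvable on a grid
#' get NA and an unknown coastal flag, counted in the report.
#'
#' @param matchups matchup (or observation) data.frame with `latitude`
#'   and `longitude`
#' @param bathy a [context_grid()] of bathymetry (m, positive down)
#' @param coast a [context_grid()] of coast distance (km)
#' @param power,k IDW parameters, see [idw_interpolate()]
#' @param bathy_threshold_m,coast_threshold_km coastal QC thresholds
#'   passed to [qc_flag_coastal()]
#' @return list with `matchups` (annotated, coastal flag set) and
#'   `report` (counts of missing annotations)
#' @export
annotate_matchups <- function(matchups, bathy, coast, power = 2, k = 4L,
                              bathy_threshold_m = 25,
                              coast_threshold_km = 1) {
  stopifnot(is.data.frame(matchups),
            inherits(bathy, "context_grid"),
            inherits(coast, "context_grid"))
  matchups$bathymetry_m <-
    idw_interpolate(bathy, matchups$latitude, matchups$longitude,
                    power = power, k = k)
  matchups$coast_distance_km <-
    idw_interpolate(coast, matchups$latitude, matchups$longitude,
                    power = power, k = k)
  matchups <- qc_flag_coastal(matchups,
                              bathy_threshold_m = bathy_threshold_m,
                              coast_threshold_km = coast_threshold_km)
  report <- list(
    n = nrow(matchups),
    n_missing_bathymetry = sum(is.na(matchups$bathymetry_m)),
    n_missing_coast_distance = sum(is.na(matchups$coast_distance_km)),
    n_unknown_coastal_flag = sum(is.na(matchups$coastal_flag))
  )
  list(matchups = matchups, report = report)
}

#' Read a gridded-CSV context fixture
#'
#' Same plain-text layout as [read_composite_csv()]: row-major,
#' north-to-south, no header. Elevation-style bathymetry sources (negative
#' below sea level) can be negated on read.
#'
#' @param path file path
#' @param grid the [grid_spec()] the file is on
#' @param quantity "bathymetry_m" or "coast_distance_km"
#' @param sentinel missing-value sentinel (default -999)
#' @param negate negate values on read (elevation -> depth)
#' @return a [context_grid()]
#' @export
read_context_csv <- function(path, grid, quantity, sentinel = -999,
                             negate = FALSE) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  m[m == sentinel] <- NA_real_
  if (negate) m <- -m
  context_grid(m, grid, quantity)
}
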