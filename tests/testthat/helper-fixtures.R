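# Small in-code fixtures and independent oracles shared across tests.

# a tiny global grid (cells of 180/n_rows degrees)
tiny_grid <- function(n_rows = 18L) grid_spec(n_rows, 2L * n_rows)

# constant-chlorophyll composite on a tiny grid
constant_field <- function(value = 0.5, n_rows = 18L) {
  g <- tiny_grid(n_rows)
  composite_field(matrix(value, g$n_rows, g$n_cols), g)
}

# write an observation CSV and return its path
write_obs_csv <- function(rows, path = tempfile(fileext = ".csv"),
                          header = "id,secchi_depth_m,latitude,longitude,day_of_year,year") {
  writeLines(c(header, rows), path)
  path
}

# independent haversine (angular form; the Earth radius cancels in IDW
# weight ratios, so only the central angle matters)
oracle_haversine <- function(lat1, lon1, lat2, lon2, R = 6378137) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# brute-force IDW over the k nearest non-missing nodes of a context grid,
# scanning every node of the grid
oracle_idw <- function(grid, lat, lon, power = 2, k = 4L) {
  g <- grid$grid
  rc <- expand.grid(row = 0:(g$n_rows - 1L), col = 0:(g$n_cols - 1L))
  v <- grid$values[cbind(rc$row + 1L, rc$col + 1L)]
  ok <- !is.na(v)
  rc <- rc[ok, ]; v <- v[ok]
  nl <- g$lat_max - (rc$row + 0.5) * g$cell_size_deg
  no <- g$lon_min + (rc$col + 0.5) * g$cell_size_deg
  d <- oracle_haversine(lat, lon, nl, no)
  o <- order(d)[seq_len(min(k, length(d)))]
  d <- d[o]; v <- v[o]
  if (d[1] < 1) return(v[1])
  w <- 1 / d^power
  sum(w * v) / sum(w)
}

# random points on a dyadic lattice (exactly representable as m / 2^20),
# so the exact-rational grid-index oracle below is truly exact
dyadic_points <- function(n, seed) {
  set.seed(seed)
  s <- 2^20
  lat <- sample.int(180 * s - 1L, n, replace = TRUE) / s - 90   # (-90, 90)
  lon <- sample.int(360 * s, n, replace = TRUE) / s - 180       # (-180, 180]
  lon[lon >= 180] <- lon[lon >= 180] - 360
  list(lat = lat, lon = lon)
}

# exact-rational cell search for the 4320 x 8640 grid (24 cells/degree):
# with lat = a / 2^20 exactly, (90 - lat) * 2^20 and its product with 24
# are exact integers below 2^53, so the floor is computed without any
# floating-point division
oracle_grid_index_exact <- function(lat, lon) {
  s <- 2^20
  Lr <- (90 - lat) * s        # exact integer by construction
  Lc <- (lon + 180) * s
  stopifnot(Lr == round(Lr), Lc == round(Lc))
  row <- (Lr * 24) %/% s
  col <- (Lc * 24) %/% s
  row <- pmin(row, 4319)
  col <- pmin(col, 8639)
  data.frame(row = as.integer(row), col = as.integer(col))
}
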