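#' Equal-angle global grid specification
#'
#' Describes the standard Level-3 equal-angle ("plate carree") layout:
#' row 0 is the northernmost row of cells, column 0 the westernmost, and
#' cells are square in degrees. The default 4320 x 8640 grid is the
#' ~4 km ocean-colour product grid.
#'
#' @param n_rows number of latitude rows (cell size = 180 / n_rows degrees)
#' @param n_cols number of longitude columns (cell size = 360 / n_cols)
#' @param lat_max latitude of the northern grid edge, degrees (default +90)
#' @param lon_min longitude of the western grid edge, degrees (default -180)
#' @return an object of class `grid_spec`
#' @export
grid_spec <- function(n_rows = 4320L, n_cols = 8640L,
                      lat_max = 90, lon_min = -180) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows > 0L, n_cols > 0L)
  cell_lat <- 180 / n_rows
  cell_lon <- 360 / n_cols
  if (abs(cell_lat - cell_lon) > 1e-9 * cell_lat) {
    stop("grid cells must be square in degrees: 180/n_rows must equal 360/n_cols")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         lat_max = lat_max, lon_min = lon_min,
         cell_size_deg = cell_lat),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %.6g deg (N edge %g, W edge %g)\n",
              x$n_rows, x$n_cols, x$cell_size_deg, x$lat_max, x$lon_min))
  invisible(x)
}

#' Normalise longitudes into [-180, 180)
#'
#' @param lon numeric vector of longitudes in degrees
#' @return longitudes wrapped into the half-open interval [-180, 180)
#' @export
normalize_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  # %% can return 360 for values a hair below a multiple of 360
  out[out >= 180] <- out[out >= 180] - 360
  out
}

#' Locate geographic points in an equal-angle grid
#'
#' Maps (lat, lon) to 0-based (row, col) cell indices with row 0 at the
#' northern edge. The south pole (lat = -90) sits on the edge of the last
#' row and is clamped into it; longitudes are wrapped into [-180, 180)
#' first.
#'
#' @param lat,lon numeric vectors, degrees; recycled to common length
#' @param grid a [grid_spec()]
#' @return data.frame with integer columns `row` and `col` (0-based)
#' @export
grid_index <- function(lat, lon, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n)
  lon <- normalize_lon(rep_len(lon, n))
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("non-finite coordinates")
  }
  if (any(lat < -90 | lat > 90)) stop("latitude out of [-90, 90]")
  cell <- grid$cell_size_deg
  row <- floor((grid$lat_max - lat) / cell)
  col <- floor((lon - grid$lon_min) / cell)
  # clamp points sitting exactly on the south/north edge or on the float
  # boundary of the last column into the grid
  row <- pmin(pmax(row, 0), grid$n_rows - 1L)
  col <- pmin(pmax(col, 0), grid$n_cols - 1L)
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Temporal composite period containing a date
#'
#' Level-3 composites tile each year independently: 1-day periods are the
#' days of the year; 8-day periods start on days 1, 9, 17, ... so that a
#' year always has 46 of them, the last one 5 or 6 days long.
#'
#' @param doy day of year (1..365/366)
#' @param year calendar year
#' @param length_days composite length, 1 or 8
#' @return list with `year`, `period_index` (0-based), `start_doy`,
#'   `end_doy`, `length_days`
#' @export
composite_period_for <- function(doy, year, length_days = 8L) {
  stopifnot(length(doy) == 1L, length(year) == 1L)
  length_days <- as.integer(length_days)
  if (!length_days %in% c(1L, 8L)) stop("length_days must be 1 or 8")
  ydays <- if (is_leap_year(year)) 366L else 365L
  doy <- as.integer(doy)
  if (doy < 1L || doy > ydays) stop("day_of_year out of range for year")
  if (length_days == 1L) {
    idx <- doy - 1L
    start <- doy
    end <- doy
  } else {
    idx <- (doy - 1L) %/% 8L
    start <- 8L * idx + 1L
    end <- min(start + 7L, ydays)
  }
  list(year = as.integer(year), period_index = idx,
       start_doy = start, end_doy = end, length_days = length_days)
}

#' Proleptic Gregorian leap-year test
#' @param year integer year(s)
#' @return logical
#' @export
is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

#' Gridded chlorophyll composite for one period
#'
#' @param values numeric matrix (n_rows x n_cols, row 1 = northernmost);
#'   missing pixels as `NA` or as `sentinel`
#' @param grid a [grid_spec()] consistent with `dim(values)`
#' @param period a period list as returned by [composite_period_for()],
#'   or NULL for period-less fixture fields
#' @param sentinel missing-value sentinel mapped to NA on construction
#' @return an object of class `composite_field`
#' @export
composite_field <- function(values, grid, period = NULL, sentinel = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop(sprintf("values is %d x %d but grid declares %d x %d",
                 nrow(values), ncol(values), grid$n_rows, grid$n_cols))
  }
  if (!is.null(sentinel)) values[values == sentinel] <- NA_real_
  if (any(values <= 0, na.rm = TRUE)) {
    stop("chlorophyll values must be positive where not missing")
  }
  structure(list(values = values, grid = grid, period = period),
            class = "composite_field")
}

#' @export
print.composite_field <- function(x, ...) {
  nv <- sum(!is.na(x$values))
  cat(sprintf("<composite_field> %d x %d, %d valid pixels (%.1f%%)\n",
              x$grid$n_rows, x$grid$n_cols, nv,
              100 * nv / length(x$values)))
  invisible(x)
}

#' Single-pixel chlorophyll extraction
#'
#' @param field a [composite_field()]
#' @param row,col 0-based cell indices
#' @return chlorophyll in mg m^-3, or NA for a missing pixel
#' @export
extract_single_pixel <- function(field, row, col) {
  stopifnot(inherits(field, "composite_field"))
  if (row < 0 || row >= field$grid$n_rows ||
      col < 0 || col >= field$grid$n_cols) {
    stop("pixel index out of bounds")
  }
  field$values[row + 1L, col + 1L]
}

#' Kernel chlorophyll extraction
#'
#' Averages the valid pixels of a (2 * half_width + 1) square kernel
#' centred on (row, col). The kernel truncates at the north/south grid
#' edges and wraps across the antimeridian in longitude.
#'
#' @param field a [composite_field()]
#' @param row,col 0-based centre indices
#' @param half_width kernel half width in pixels (1 gives the 3 x 3 kernel;
#'   0 reduces to single-pixel extraction)
#' @param min_valid minimum number of valid pixels required for a value
#' @param statistic "mean" (default) or "median" of the valid pixels
#' @return list with `value` (mg m^-3 or NA) and `n_valid`
#' @export
extract_kernel <- function(field, row, col, half_width = 1L, min_valid = 1L,
                           statistic = c("mean", "median")) {
  stopifnot(inherits(field, "composite_field"))
  statistic <- match.arg(statistic)
  g <- field$grid
  if (row < 0 || row >= g$n_rows || col < 0 || col >= g$n_cols) {
    stop("pixel index out of bounds")
  }
  rows <- (row - half_width):(row + half_width)
  rows <- rows[rows >= 0 & rows < g$n_rows]          # truncate at poles
  cols <- ((col - half_width):(col + half_width)) %% g$n_cols  # wrap lon
  vals <- field$values[rows + 1L, cols + 1L, drop = FALSE]
  ok <- !is.na(vals)
  n_valid <- sum(ok)
  value <- if (n_valid >= min_valid) {
    if (statistic == "mean") mean(vals[ok]) else stats::median(vals[ok])
  } else {
    NA_real_
  }
  list(value = value, n_valid = as.integer(n_valid))
}

#' In-memory composite source
#'
#' A composite source is a function(year, period_index, length_days) that
#' returns a [composite_field()] or NULL when no composite exists for the
#' period. This constructor wraps a named list of fields keyed
#' "year_periodindex" (e.g. "2014_21").
#'
#' @param fields named list of [composite_field()] objects
#' @return a composite-source function
#' @export
composite_source_memory <- function(fields) {
  stopifnot(is.list(fields))
  function(year, period_index, length_days) {
    fields[[paste0(year, "_", period_index)]]
  }
}

#' Constant ("climatology") composite source
#'
#' Returns the same field for every requested period; used with synthetic
#' worlds where one simulated field stands for the whole study window.
#'
#' @param field a [composite_field()]
#' @return a composite-source function
#' @export
composite_source_constant <- function(field) {
  stopifnot(inherits(field, "composite_field"))
  function(year, period_index, length_days) field
}

#' Match observations to composite chlorophyll
#'
#' Locates every observation in the composite grid, picks the composite
#' period containing its date, and extracts chlorophyll by single-pixel or
#' 3 x 3 kernel extraction. Observations whose pixel is missing, or whose
#' period has no composite, are kept in the table with `chl = NA` and
#' enumerated in the coverage report; nothing is dropped silently.
#'
#' @param observations data.frame in the observation schema (see
#'   [read_observations()])
#' @param source a composite-source function
#' @param grid the [grid_spec()] of the composites
#' @param mode "single" or "kernel3x3"
#' @param length_days composite length, 1 or 8
#' @param min_valid kernel minimum valid-pixel count
#' @return list with `matchups` (data.frame, one row per observation, in
#'   input order) and `coverage` (counts and unmatched ids)
#' @export
build_matchups <- function(observations, source, grid,
                           mode = c("single", "kernel3x3"),
                           length_days = 8L, min_valid = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(observations), is.function(source),
            inherits(grid, "grid_spec"))
  n <- nrow(observations)
  chl <- rep(NA_real_, n)
  n_valid <- rep(0L, n)
  no_composite <- rep(FALSE, n)
  if (n > 0) {
    idx <- grid_index(observations$latitude, observations$longitude, grid)
    for (i in seq_len(n)) {
      per <- composite_period_for(observations$day_of_year[i],
                                  observations$year[i], length_days)
      field <- source(per$year, per$period_index, length_days)
      if (is.null(field)) {
        no_composite[i] <- TRUE
        next
      }
      if (!identical(field$grid$n_rows, grid$n_rows) ||
          !identical(field$grid$n_cols, grid$n_cols)) {
        stop("composite source returned a field on a different grid")
      }
      if (mode == "single") {
        chl[i] <- extract_single_pixel(field, idx$row[i], idx$col[i])
        n_valid[i] <- as.integer(!is.na(chl[i]))
      } else {
        k <- extract_kernel(field, idx$row[i], idx$col[i],
                            half_width = 1L, min_valid = min_valid)
        chl[i] <- k$value
        n_valid[i] <- k$n_valid
      }
    }
  }
  matchups <- observations
  matchups$chl <- chl
  matchups$n_valid_kernel <- n_valid
  matchups$zsd_sat <- NA_real_
  if (is.null(matchups$bathymetry_m)) matchups$bathymetry_m <- NA_real_
  if (is.null(matchups$coast_distance_km)) matchups$coast_distance_km <- NA_real_
  matchups$extraction_mode <- mode
  matched <- !is.na(chl)
  coverage <- list(
    n = n,
    n_matched = sum(matched),
    n_unmatched = sum(!matched),
    n_no_composite = sum(no_composite),
    n_missing_pixel = sum(!matched & !no_composite),
    unmatched_ids = observations$record_id[!matched]
  )
  list(matchups = matchups, coverage = coverage)
}

#' Read a gridded-CSV composite fixture
#'
#' Plain-text fixture format for composite fields: a row-major,
#' north-to-south numeric CSV with no header, one grid row per line.
#'
#' @param path file path
#' @param grid the [grid_spec()] the file is on
#' @param sentinel missing-value sentinel (default -999)
#' @param period optional period list
#' @return a [composite_field()]
#' @export
read_composite_csv <- function(path, grid, sentinel = -999, period = NULL) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  composite_field(m, grid, period = period, sentinel = sentinel)
}

#' Write a composite field as a gridded CSV
#' @param field a [composite_field()]
#' @param path file path
#' @param sentinel value written for missing pixels
#' @export
write_composite_csv <- function(field, path, sentinel = -999) {
  m <- field$values
  m[is.na(m)] <- sentinel
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
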