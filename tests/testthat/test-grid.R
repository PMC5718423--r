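test_that("grid_index places corner and pole points correctly", {
  g <- grid_spec(180L, 360L)
  expect_equal(grid_index(89.5, -179.5, g), data.frame(row = 0L, col = 0L))
  # south pole clamps into the last row
  expect_equal(grid_index(-90, 179.99, g), data.frame(row = 179L, col = 359L))
  expect_error(grid_index(91, 0, g), "latitude")
})

test_that("grid_index matches the exact-rational cell-boundary oracle", {
  g <- grid_spec(4320L, 8640L)
  pts <- dyadic_points(1000L, seed = 42)
  got <- grid_index(pts$lat, pts$lon, g)
  want <- oracle_grid_index_exact(pts$lat, pts$lon)
  expect_identical(got, want)
})

test_that("8-day periods partition leap and non-leap years into 46", {
  for (year in c(2014L, 2016L)) {
    ydays <- if (is_leap_year(year)) 366L else 365L
    per <- vapply(seq_len(ydays), function(d) {
      composite_period_for(d, year, 8L)$period_index
    }, integer(1))
    expect_equal(sort(unique(per)), 0:45)
    # each day lies inside its period's span
    for (d in c(1L, 8L, 9L, 360L, ydays)) {
      p <- composite_period_for(d, year, 8L)
      expect_true(p$start_doy <= d && d <= p$end_doy)
    }
    last <- composite_period_for(ydays, year, 8L)
    expect_equal(last$start_doy, 361L)
    expect_equal(last$end_doy, ydays)
  }
  expect_equal(composite_period_for(1, 2014, 8)$period_index, 0L)
  expect_equal(composite_period_for(9, 2014, 8)$period_index, 1L)
  expect_equal(composite_period_for(170, 2014, 1)$period_index, 169L)
  expect_error(composite_period_for(366, 2015, 8), "out of range")
})

test_that("pixel and kernel extraction handle sentinels, edges and wrap", {
  g <- tiny_grid()
  v <- matrix(0.5, g$n_rows, g$n_cols)
  v[3, 5] <- NA
  f <- composite_field(v, g)
  expect_equal(extract_single_pixel(f, 0L, 0L), 0.5)
  expect_true(is.na(extract_single_pixel(f, 2L, 4L)))
  expect_error(extract_single_pixel(f, g$n_rows, 0L), "out of bounds")
  # constant 3x3 block
  k <- extract_kernel(f, 10L, 10L)
  expect_equal(k$value, 0.5)
  expect_equal(k$n_valid, 9L)
  # single survivor at min_valid = 1
  v2 <- matrix(NA_real_, g$n_rows, g$n_cols)
  v2[10, 10] <- 0.4
  f2 <- composite_field(v2, g)
  k2 <- extract_kernel(f2, 9L, 9L, min_valid = 1L)
  expect_equal(k2$value, 0.4)
  expect_equal(k2$n_valid, 1L)
  expect_true(is.na(extract_kernel(f2, 9L, 9L, min_valid = 2L)$value))
  # half_width 0 reduces to single-pixel extraction
  k0 <- extract_kernel(f, 3L, 3L, half_width = 0L)
  expect_equal(k0$value, extract_single_pixel(f, 3L, 3L))
  expect_equal(k0$n_valid, 1L)
  # kernel truncates at the pole row and wraps across the antimeridian
  kp <- extract_kernel(f, 0L, 0L)
  expect_equal(kp$n_valid, 6L)
  set.seed(11)
  v3 <- matrix(ifelse(runif(g$n_rows * g$n_cols) < 0.4, NA,
                      runif(g$n_rows * g$n_cols, 0.1, 2)),
               g$n_rows, g$n_cols)
  f3 <- composite_field(v3, g)
  # mixed block equals brute-force sum/count over enumerated valid cells
  rows <- 7:9; cols <- c(g$n_cols, 1, 2)  # centre col 0 wraps west
  cells <- v3[rows, cols]
  k3 <- extract_kernel(f3, 7L, 0L)
  expect_equal(k3$n_valid, sum(!is.na(cells)))
  if (k3$n_valid > 0) {
    expect_equal(k3$value, sum(cells, na.rm = TRUE) / sum(!is.na(cells)))
  }
})

test_that("build_matchups conserves records and reports coverage", {
  g <- tiny_grid()
  v <- matrix(0.5, g$n_rows, g$n_cols)
  idx <- grid_index(10, 10, g)
  v[idx$row + 1L, idx$col + 1L] <- NA  # obs2 sits on a missing pixel
  f <- composite_field(v, g)
  obs <- data.frame(
    record_id = c("a", "b", "c"),
    secchi_depth_m = c(5, 6, 7),
    latitude = c(50, 10, -30), longitude = c(-40, 10, 100),
    day_of_year = c(10L, 20L, 30L), year = c(2014L, 2014L, 2014L),
    coastal_flag = NA, notes = "", stringsAsFactors = FALSE
  )
  src <- composite_source_constant(f)
  bm <- build_matchups(obs, src, g)
  expect_equal(nrow(bm$matchups), 3L)
  expect_equal(bm$coverage$n_matched, 2L)
  expect_equal(bm$coverage$unmatched_ids, "b")
  expect_equal(bm$coverage$n_missing_pixel, 1L)
  # absent composite -> unmatched via the no-composite path
  src2 <- composite_source_memory(list("2014_1" = f))
  bm2 <- build_matchups(obs, src2, g)  # only doy 10 (period 1) matches
  expect_equal(bm2$coverage$n_no_composite, 2L)
  expect_equal(bm2$coverage$n_matched, 1L)
})

test_that("8-day composites match at least as many records as nested 1-day", {
  g <- tiny_grid()
  set.seed(5)
  base <- matrix(runif(g$n_rows * g$n_cols, 0.1, 1), g$n_rows, g$n_cols)
  # daily fields: random dropouts; the 8-day field is their valid union
  daily <- lapply(1:8, function(d) {
    v <- base
    v[runif(length(v)) < 0.5] <- NA
    composite_field(v, g)
  })
  eight <- compose_eight_day(daily)
  obs <- data.frame(
    record_id = sprintf("o%02d", 1:40),
    secchi_depth_m = 5,
    latitude = runif(40, -80, 80), longitude = runif(40, -170, 170),
    day_of_year = sample(1:8, 40, replace = TRUE), year = 2014L,
    coastal_flag = NA, notes = "", stringsAsFactors = FALSE
  )
  src1 <- function(year, period_index, length_days) daily[[period_index + 1L]]
  src8 <- composite_source_constant(eight)
  n1 <- build_matchups(obs, src1, g, length_days = 1L)$coverage$n_matched
  n8 <- build_matchups(obs, src8, g, length_days = 8L)$coverage$n_matched
  expect_gte(n8, n1)
})

test_that("gridded-CSV composites round-trip through the sentinel", {
  g <- tiny_grid(6L)
  v <- matrix(runif(g$n_rows * g$n_cols, 0.1, 1), g$n_rows, g$n_cols)
  v[2, 3] <- NA
  f <- composite_field(v, g)
  path <- tempfile(fileext = ".csv")
  write_composite_csv(f, path)
  f2 <- read_composite_csv(path, g)
  expect_equal(f2$values, f$values)
})
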