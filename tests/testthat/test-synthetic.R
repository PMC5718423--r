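test_that("chlorophyll field is seeded, positive and moment-faithful", {
  sc <- scenario_config(seed = 11, chl_n_rows = 90L)
  f1 <- simulate_chl_field(sc)
  f2 <- simulate_chl_field(sc)
  expect_identical(f1$values, f2$values)          # bit-identical per seed
  expect_true(all(f1$values > 0))
  lf <- log10(f1$values)
  se <- sd(lf) / sqrt(length(lf))
  expect_lt(abs(mean(lf) - sc$chl_log10_mean), 3 * se + 1e-9)
  expect_equal(sd(lf), sc$chl_log10_sd, tolerance = 1e-9)
  # a different seed gives a different field
  f3 <- simulate_chl_field(scenario_config(seed = 12, chl_n_rows = 90L))
  expect_false(identical(f1$values, f3$values))
  # degenerate variance collapses to a constant field
  f0 <- simulate_chl_field(scenario_config(seed = 11, chl_n_rows = 90L,
                                           chl_log10_sd = 0))
  expect_true(all(f0$values == 10^sc$chl_log10_mean))
})

test_that("smoothing induces spatial autocorrelation", {
  sc_sm <- scenario_config(seed = 13, chl_n_rows = 90L,
                           correlation_length_cells = 4)
  sc_wn <- scenario_config(seed = 13, chl_n_rows = 90L,
                           correlation_length_cells = 0)
  lag1 <- function(f) {
    v <- log10(f$values)
    cor(as.vector(v[-1, ]), as.vector(v[-nrow(v), ]))
  }
  expect_gt(lag1(simulate_chl_field(sc_sm)), 0.8)
  expect_lt(abs(lag1(simulate_chl_field(sc_wn))), 0.1)
})

test_that("coastline distance matches an independent geometric computation", {
  sc <- scenario_config(seed = 14)
  set.seed(99)
  lat <- runif(100, 30, 60)
  lon <- runif(100, -45, -10.1)
  d <- coast_distance_km(lat, lon, sc$coastline)
  # oracle: minimum haversine distance to a densely sampled coastline
  lats <- seq(20, 70, by = 0.005)
  clons <- sc$coastline$lon_c + 0 * lats
  want <- vapply(seq_along(lat), function(i) {
    min(oracle_haversine(lat[i], lon[i], lats, clons, R = 6371008.8)) / 1000
  }, numeric(1))
  expect_equal(d, want, tolerance = 1e-3)
  # a point on the coastline is at distance zero
  expect_equal(coast_distance_km(45, sc$coastline$lon_c, sc$coastline), 0)
})

test_that("sinusoidal coastline distance agrees with the polyline oracle", {
  coastline <- list(lon_c = -10, amplitude = 2, wavelength = 30, lat0 = 30)
  set.seed(98)
  lat <- runif(30, 32, 58)
  lon <- runif(30, -30, -14)
  d <- coast_distance_km(lat, lon, coastline, lat_range = c(20, 70))
  lats <- seq(20, 70, by = 0.005)
  clons <- coastline$lon_c + 2 * sin(2 * pi * (lats - 30) / 30)
  want <- vapply(seq_along(lat), function(i) {
    min(oracle_haversine(lat[i], lon[i], lats, clons, R = 6371008.8)) / 1000
  }, numeric(1))
  expect_equal(d, want, tolerance = 1e-2)
})

test_that("bathymetry deepens monotonically away from the coast", {
  sc <- scenario_config(seed = 15, bathy_n_rows = 180L, coast_n_rows = 180L)
  grids <- simulate_coast(sc)
  g <- grids$bathy$grid
  row <- grid_index(45.2, -20, g)$row + 1L
  lons <- node_lon(g, 0:(g$n_cols - 1L))
  shelf <- which(lons > -20 & lons < -10.4)  # ocean, approaching the coast
  b <- grids$bathy$values[row, shelf]
  d <- grids$coast$values[row, shelf]
  # moving east toward the coast: distance and depth both fall, together
  expect_true(all(diff(d) < 0))
  expect_true(all(diff(b) < 0))
  expect_true(all(b < sc$abyssal_depth_m))
  expect_true(all(b > 0))
  # the land side holds no values
  expect_true(is.na(grids$bathy$values[
    cbind(1, which(node_lon(grids$bathy$grid,
                            0:(grids$bathy$grid$n_cols - 1L)) > 0)[1])]))
})

test_that("observations are deterministic, on the ocean side, and truthful", {
  sc <- scenario_config(seed = 16, n_observations = 120L)
  f <- simulate_chl_field(sc)
  o1 <- simulate_observations(sc, f)
  o2 <- simulate_observations(sc, f)
  expect_identical(o1$observations, o2$observations)
  obs <- o1$observations
  expect_true(all(obs$secchi_depth_m > 0))
  expect_true(all(coast_distance_km(obs$latitude, obs$longitude,
                                    sc$coastline) > 0))
  # truth table is consistent: observed = true * noise, noise log-normal
  lr <- log10(obs$secchi_depth_m) - log10(o1$truth$true_zsd)
  expect_lt(abs(sd(lr) - sc$sigma_log10), 0.05)
  # contamination flag matches the coastal reach
  expect_equal(o1$truth$contaminated, o1$truth$coast_km < sc$coastal_km)
})

test_that("noise-free, uncontaminated observations equal the pixel conversion", {
  sc <- scenario_config(seed = 17, sigma_log10 = 0, alpha = 1,
                        n_observations = 60L)
  f <- simulate_chl_field(sc)
  o <- simulate_observations(sc, f)
  idx <- grid_index(o$observations$latitude, o$observations$longitude, f$grid)
  chl <- f$values[cbind(idx$row + 1L, idx$col + 1L)]
  expect_equal(o$observations$secchi_depth_m,
               as.numeric(chl_to_zsd(chl, sc$true_model)))
})

test_that("all-coastal contamination halves transparency as configured", {
  sc <- scenario_config(seed = 18, sigma_log10 = 0, alpha = 0.5,
                        coastal_km = 1e5, n_observations = 50L)
  f <- simulate_chl_field(sc)
  o <- simulate_observations(sc, f)
  expect_true(all(o$truth$contaminated))
  idx <- grid_index(o$observations$latitude, o$observations$longitude, f$grid)
  chl <- f$values[cbind(idx$row + 1L, idx$col + 1L)]
  open_pred <- as.numeric(chl_to_zsd(chl, sc$true_model))
  expect_equal(o$observations$secchi_depth_m, 0.5 * open_pred)
})

test_that("daily fields compose into their valid-union mean", {
  sc <- scenario_config(seed = 19, chl_n_rows = 36L)
  base <- simulate_chl_field(sc)
  df <- simulate_daily_fields(sc, base)
  expect_length(df$daily, 8L)
  e <- df$eight_day
  # valid wherever any day is valid
  any_valid <- Reduce(`|`, lapply(df$daily, function(f) !is.na(f$values)))
  expect_equal(!is.na(e$values), any_valid)
  # spot-check the mean at a few pixels against direct enumeration
  set.seed(1)
  for (j in 1:20) {
    r <- sample(36, 1); c <- sample(72, 1)
    vals <- vapply(df$daily, function(f) f$values[r, c], numeric(1))
    if (any(!is.na(vals))) {
      expect_equal(e$values[r, c], mean(vals, na.rm = TRUE))
    }
  }
})
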