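test_that("log-space correlation matches the direct covariance formula", {
  # exact log-log line with negative slope
  chl <- 10^seq(-1, 1, length.out = 10)
  depth <- 10^(1 - 0.5 * log10(chl))
  r1 <- log_correlation(depth, chl)
  expect_equal(r1$r, -1)
  # fixed pairs against the textbook formula
  set.seed(21)
  d <- 10^rnorm(10, 1, 0.3)
  c <- 10^rnorm(10, -0.5, 0.4)
  res <- log_correlation(d, c)
  x <- log10(d); y <- log10(c)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  expect_equal(res$n, 10L)
  # missing chlorophyll pairs are dropped and counted
  c2 <- c; c2[3] <- NA
  expect_equal(log_correlation(d, c2)$n_dropped, 1L)
  # degenerate inputs
  expect_error(log_correlation(d, rep(0.5, 10)), "zero variance")
  expect_error(log_correlation(d[1:2], c[1:2]), "at least 3")
})

test_that("regression recovers an exact line and the identity line", {
  x <- c(2, 5, 8, 10, 14, 20)
  y <- 1.64 * x - 1.88
  reg <- suppressWarnings(fit_regression(x, y))
  expect_equal(reg$slope, 1.64, tolerance = 1e-12)
  expect_equal(reg$intercept, -1.88, tolerance = 1e-12)
  p <- suppressWarnings(predict_with_ci(reg, 10))
  expect_equal(p$fit, 14.52, tolerance = 1e-12)
  expect_equal(p$upr - p$lwr, 0, tolerance = 1e-9)
  reg2 <- suppressWarnings(fit_regression(x, x))
  expect_equal(reg2$slope, 1, tolerance = 1e-12)
  expect_equal(reg2$intercept, 0, tolerance = 1e-12)
  expect_equal(diff(reg2$slope_ci_95), 0, tolerance = 1e-9)
  expect_error(fit_regression(rep(3, 5), 1:5), "zero variance")
})

test_that("non-positive pairs are dropped and counted, not silently lost", {
  x <- c(1, 2, 3, -4, 5)
  y <- c(2, 4, 6, 8, -1)
  reg <- suppressWarnings(fit_regression(x, y, drop_nonpositive = TRUE))
  expect_equal(reg$n, 3L)
  expect_equal(reg$n_dropped_nonpositive, 2L)
  expect_equal(sum(reg$used), 3L)
  # OLS residuals sum to zero with an intercept
  set.seed(31)
  xr <- runif(50, 1, 30)
  yr <- 2 + 1.5 * xr + rnorm(50)
  regr <- fit_regression(xr, yr)
  expect_lt(abs(sum(regr$residuals)), 1e-9 * 50 * mean(abs(yr)))
})

test_that("prediction interval matches the closed-form t expression", {
  set.seed(32)
  x <- runif(20, 2, 25)
  y <- 1.6 * x - 2 + rnorm(20, 0, 2)
  reg <- fit_regression(x, y)
  x0 <- c(5, mean(x), 22)
  p <- predict_with_ci(reg, x0)
  # independent closed form: t * s * sqrt(1/n + (x0 - xbar)^2 / Sxx)
  n <- length(x)
  xbar <- mean(x)
  Sxx <- sum((x - xbar)^2)
  b <- sum((x - xbar) * (y - mean(y))) / Sxx
  a <- mean(y) - b * xbar
  s <- sqrt(sum((y - a - b * x)^2) / (n - 2))
  tq <- qt(0.975, n - 2)
  fit0 <- a + b * x0
  half <- tq * s * sqrt(1 / n + (x0 - xbar)^2 / Sxx)
  expect_equal(p$fit, fit0, tolerance = 1e-10)
  expect_equal(p$upr - p$lwr, 2 * half, tolerance = 1e-10)
  # the mean-response interval is narrowest at xbar
  widths <- predict_with_ci(reg, seq(min(x), max(x), length.out = 50))
  wmin <- which.min(widths$upr - widths$lwr)
  expect_lt(abs(widths$x0[wmin] - xbar), diff(range(x)) / 49 + 1e-9)
  # the prediction interval is wider than the mean-response interval
  pp <- predict_with_ci(reg, x0, interval = "prediction")
  expect_true(all(pp$upr - pp$lwr > p$upr - p$lwr))
})

test_that("slope CI coverage is near nominal on simulated matchups", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(2000 + s)
    x <- runif(500, 2, 30)
    y <- 1.64 * x - 1.88 + rnorm(500, 0, 2)
    ci <- fit_regression(x, y)$slope_ci_95
    if (ci[1] <= 1.64 && 1.64 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("residual partition conserves counts and keeps geography", {
  m <- data.frame(
    record_id = sprintf("r%d", 1:6),
    latitude = 1:6, longitude = -(1:6),
    bathymetry_m = c(10, 50, 100, 4000, 30, 2000),
    coast_distance_km = c(0.5, 2, 10, 300, 5, 100),
    coastal_flag = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  x <- c(2, 5, 8, 10, 14, 20)
  # collinear except one displaced point
  y <- 1.5 * x + 1
  y[3] <- y[3] + 3
  reg <- fit_regression(x, y)
  part <- partition_residuals(reg, m)
  expect_equal(nrow(part$records), 6L)
  cnt <- part$counts
  expect_equal(cnt$n_positive + cnt$n_negative + cnt$n_zero, 6L)
  expect_gt(part$records$residual[3], 0)
  expect_equal(part$records$latitude, m$latitude)
  # all-collinear data give all-zero residuals
  reg0 <- suppressWarnings(fit_regression(x, 1.5 * x + 1))
  part0 <- partition_residuals(reg0, m)
  expect_equal(part0$counts$n_zero, 6L)
  # GeoJSON export round-trips the feature count and properties
  path <- tempfile(fileext = ".geojson")
  write_residuals_geojson(part$records, path)
  gj <- jsonlite::read_json(path)
  expect_equal(length(gj$features), 6L)
  expect_equal(gj$features[[3]]$properties$sign, "positive")
})

test_that("stratification lands every record in exactly one bin", {
  set.seed(33)
  rec <- data.frame(
    bathymetry_m = runif(200, 0, 100),
    coast_distance_km = c(runif(190, 0, 50), rep(NA, 10)),
    residual = rnorm(200)
  )
  st <- stratify(rec, "bathymetry_m", seq(0, 100, by = 10))
  expect_equal(sum(st$n), 200L)
  # counts match direct enumeration per right-open bin
  direct <- vapply(1:10, function(b) {
    sum(rec$bathymetry_m >= (b - 1) * 10 & rec$bathymetry_m < b * 10)
  }, integer(1))
  expect_equal(st$n, direct)
  # missing stratification values are reported separately
  st2 <- stratify(rec, "coast_distance_km", c(0, 1, 20, Inf))
  expect_equal(sum(st2$n), 190L)
  expect_equal(attr(st2, "n_missing"), 10L)
  # coastal-threshold edges give two strata; empty bins are n = 0
  st3 <- stratify(data.frame(bathymetry_m = 50, residual = 1),
                  "bathymetry_m", c(0, 25, Inf))
  expect_equal(st3$n, c(0L, 1L))
  expect_error(stratify(rec, "bathymetry_m", c(0, 0, 10)),
               "strictly increasing")
})
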