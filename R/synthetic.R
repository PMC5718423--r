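#' Synthetic-world scenario configuration
#'
#' Bundles every parameter of the seeded synthetic world used to exercise
#' the matchup pipeline end to end: a log-normal, spatially autocorrelated
#' chlorophyll field; a meridional (optionally sinusoidal) coastline with
#' derived coast-distance and bathymetry grids; and vessel-track Secchi
#' observations whose true transparency follows the bio-optical model,
#' degraded by multiplicative log-normal observer noise and a coastal
#' optical-contamination factor. The seed fully determines every draw.
#'
#' @param seed integer RNG seed
#' @param chl_n_rows chlorophyll grid rows (global equal-angle; 180 = 1 deg)
#' @param chl_log10_mean,chl_log10_sd mean and sd of log10(chl mg m^-3)
#' @param correlation_length_cells Gaussian smoothing length of the
#'   log-chlorophyll field, in grid cells
#' @param bathy_n_rows,coast_n_rows context-grid resolutions (global rows)
#' @param region study box: named vector lat_min, lat_max, lon_min, lon_max
#' @param coastline list: `lon_c` (deg, coast meridian), `amplitude` (deg,
#'   0 = straight), `wavelength` (deg lat), `lat0` (phase origin)
#' @param abyssal_depth_m,shelf_scale_km bathymetry profile
#'   depth = abyssal * (1 - exp(-coast_km / shelf_scale))
#' @param true_model the [bio_optical_model()] generating true Secchi depths
#' @param sigma_log10 observer noise sd on log10(depth)
#' @param alpha coastal transparency multiplier in (0, 1]
#' @param coastal_km contamination reach from the coast, km
#' @param n_observations,n_routes observation count and vessel routes
#' @param coastal_route_fraction fraction of routes confined to a
#'   near-coast band (shipping concentrates near coasts, which is what
#'   puts observations inside the contamination reach)
#' @param coastal_band_deg longitudinal width of that near-coast band,
#'   degrees
#' @param years calendar years observations are drawn from
#' @param cloud_fraction per-day missing-pixel probability for daily fields
#' @return an object of class `scenario_config`
#' @export
scenario_config <- function(seed = 1L,
                            chl_n_rows = 180L,
                            chl_log10_mean = -0.7,
                            chl_log10_sd = 0.35,
                            correlation_length_cells = 3,
                            bathy_n_rows = 360L,
                            coast_n_rows = 720L,
                            region = c(lat_min = 30, lat_max = 60,
                                       lon_min = -45, lon_max = -5),
                            coastline = list(lon_c = -10, amplitude = 0,
                                             wavelength = 30, lat0 = 30),
                            abyssal_depth_m = 4000,
                            shelf_scale_km = 30,
                            true_model = default_bio_optical_model(),
                            sigma_log10 = 0.1,
                            alpha = 0.6,
                            coastal_km = 20,
                            n_observations = 500L,
                            n_routes = 10L,
                            coastal_route_fraction = 0.4,
                            coastal_band_deg = 0.5,
                            years = 2013:2016,
                            cloud_fraction = 0.3) {
  stopifnot(chl_log10_sd >= 0, sigma_log10 >= 0,
            alpha > 0, alpha <= 1, coastal_km >= 0,
            inherits(true_model, "bio_optical_model"))
  structure(as.list(environment()), class = "scenario_config")
}

# reflective padding + separable Gaussian smoothing; longitude is
# circular, latitude reflects at the poles
smooth_field <- function(z, sd_cells) {
  if (sd_cells <= 0) return(z)
  r <- max(1L, ceiling(3 * sd_cells))
  w <- stats::dnorm(-r:r, sd = sd_cells)
  w <- w / sum(w)
  # longitude (columns): circular convolution, row by row
  z <- t(apply(z, 1, function(x) {
    as.numeric(stats::filter(x, w, circular = TRUE))
  }))
  # latitude (rows): reflect-pad, convolve, trim
  zp <- rbind(z[r:1, , drop = FALSE], z, z[nrow(z):(nrow(z) - r + 1), , drop = FALSE])
  zp <- apply(zp, 2, function(x) {
    as.numeric(stats::filter(x, w, circular = FALSE))
  })
  zp[(r + 1):(r + nrow(z)), , drop = FALSE]
}

#' Simulate a spatially autocorrelated chlorophyll composite
#'
#' Draws a white-noise field, smooths it with a Gaussian kernel of the
#' configured correlation length (circular in longitude, reflected in
#' latitude), standardises it to the configured log10 mean and sd, and
#' exponentiates, so values are log-normal, positive, and spatially
#' coherent. With sd = 0 the field is constant at 10^mean. Deterministic
#' per seed.
#'
#' @param config a [scenario_config()]
#' @return a [composite_field()]
#' @export
simulate_chl_field <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  g <- grid_spec(config$chl_n_rows, 2L * config$chl_n_rows)
  set.seed(config$seed)
  if (config$chl_log10_sd == 0) {
    lf <- matrix(config$chl_log10_mean, g$n_rows, g$n_cols)
  } else {
    z <- matrix(stats::rnorm(g$n_rows * g$n_cols), g$n_rows, g$n_cols)
    z <- smooth_field(z, config$correlation_length_cells)
    z <- (z - mean(z)) / stats::sd(z)
    lf <- config$chl_log10_mean + config$chl_log10_sd * z
  }
  composite_field(10^lf, g)
}

#' Simulate daily fields whose union composes an 8-day composite
#'
#' Fixture helper for the 1-day vs 8-day comparison: each daily field is
#' the base field perturbed by independent log-normal day-to-day noise
#' and masked by independent per-pixel "cloud" dropouts, so the 8-day
#' composite (the mean over valid days) is valid wherever any day is.
#'
#' @param config a [scenario_config()]
#' @param base a [composite_field()] (e.g. from [simulate_chl_field()])
#' @param n_days days in the composite window (default 8)
#' @param daily_sigma_log10 day-to-day variability on log10(chl)
#' @return list with `daily` (list of composite_field) and `eight_day`
#'   (their valid-union mean composite)
#' @export
simulate_daily_fields <- function(config, base, n_days = 8L,
                                  daily_sigma_log10 = 0.05) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(base, "composite_field"))
  set.seed(config$seed + 7L)
  g <- base$grid
  daily <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    v <- base$values *
      10^matrix(stats::rnorm(length(base$values), 0, daily_sigma_log10),
                g$n_rows, g$n_cols)
    mask <- matrix(stats::runif(length(v)) < config$cloud_fraction,
                   g$n_rows, g$n_cols)
    v[mask] <- NA_real_
    daily[[d]] <- composite_field(v, g)
  }
  list(daily = daily, eight_day = compose_eight_day(daily))
}

#' Compose daily composites into a multi-day composite
#'
#' Per-pixel arithmetic mean over the days with a valid value (the
#' valid-pixel union): the composite is missing only where every day is.
#'
#' @param daily list of [composite_field()] objects on one grid
#' @return a [composite_field()]
#' @export
compose_eight_day <- function(daily) {
  stopifnot(length(daily) >= 1L)
  g <- daily[[1]]$grid
  sum_v <- matrix(0, g$n_rows, g$n_cols)
  n_v <- matrix(0L, g$n_rows, g$n_cols)
  for (f in daily) {
    ok <- !is.na(f$values)
    sum_v[ok] <- sum_v[ok] + f$values[ok]
    n_v <- n_v + ok
  }
  out <- sum_v / n_v
  out[n_v == 0L] <- NA_real_
  composite_field(out, g)
}

# longitude of the synthetic coastline at given latitudes
coastline_lon <- function(coastline, lat) {
  coastline$lon_c + coastline$amplitude *
    sin(2 * pi * (lat - coastline$lat0) / coastline$wavelength)
}

#' Great-circle distance to the synthetic coastline
#'
#' For the straight (amplitude 0) coastline the distance to the coastal
#' meridian has the cross-track closed form R * asin(cos(lat) *
#' sin(lon_c - lon)); a sinusoidal coastline is handled by minimising the
#' haversine distance over a densely sampled coastline polyline. Points on
#' the land side (east of the coastline) get negative distance so callers
#' can mask land.
#'
#' @param lat,lon positions, degrees
#' @param coastline coastline list from [scenario_config()]
#' @param lat_range latitude span over which a sinusoidal coastline is
#'   sampled
#' @param step_deg sampling step for the sinusoidal case
#' @return signed distance in km (positive = ocean side)
#' @export
coast_distance_km <- function(lat, lon, coastline,
                              lat_range = c(-90, 90), step_deg = 0.02) {
  R <- 6371.0088  # mean Earth radius, km
  if (coastline$amplitude == 0) {
    dlam <- (coastline$lon_c - lon) * pi / 180
    s <- cos(lat * pi / 180) * sin(dlam)
    s <- pmin(pmax(s, -1), 1)
    R * asin(s)
  } else {
    lats <- seq(lat_range[1], lat_range[2], by = step_deg)
    verts <- cbind(coastline_lon(coastline, lats), lats)  # lon, lat
    sgn <- ifelse(lon <= coastline_lon(coastline, lat), 1, -1)
    d <- vapply(seq_along(lat), function(i) {
      min(geosphere::distHaversine(c(lon[i], lat[i]), verts, r = R * 1000))
    }, numeric(1)) / 1000
    sgn * d
  }
}

#' Simulate bathymetry and coast-distance context grids
#'
#' Evaluates the coastline distance at every grid node, masks the land
#' side as missing, and derives bathymetry as a monotone shelf profile
#' saturating at the abyssal depth: depth = abyssal * (1 -
#' exp(-coast_km / shelf_scale)).
#'
#' @param config a [scenario_config()]
#' @return list with `bathy` and `coast` ([context_grid()] objects)
#' @export
simulate_coast <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  make_grid <- function(n_rows, quantity) {
    g <- grid_spec(n_rows, 2L * n_rows)
    lats <- node_lat(g, 0:(g$n_rows - 1L))
    lons <- node_lon(g, 0:(g$n_cols - 1L))
    d <- outer(lats, lons, function(la, lo) {
      coast_distance_km(la, lo, config$coastline)
    })
    d[d < 0] <- NA_real_   # land side
    if (quantity == "coast_distance_km") {
      context_grid(d, g, "coast_distance_km")
    } else {
      depth <- config$abyssal_depth_m * (1 - exp(-d / config$shelf_scale_km))
      context_grid(depth, g, "bathymetry_m")
    }
  }
  list(bathy = make_grid(config$bathy_n_rows, "bathymetry_m"),
       coast = make_grid(config$coast_n_rows, "coast_distance_km"))
}

#' Simulate vessel-track Secchi observations with ground truth
#'
#' Draws straight vessel routes through the ocean side of the study box,
#' places observations along them, and generates each observation's true
#' Secchi depth from the local chlorophyll pixel through the true
#' bio-optical model, multiplied by the contamination factor `alpha`
#' within `coastal_km` of the coast, then perturbed by multiplicative
#' log-normal observer noise. Points landing on the land side of the
#' coastline are skipped and counted. Deterministic per seed.
#'
#' @param config a [scenario_config()]
#' @param chl_field the [composite_field()] the satellite "sees" (truth
#'   uses the same pixel values, so the noise-free pipeline closes exactly)
#' @return list: `observations` (S1-schema data.frame), `truth`
#'   (data.frame: record_id, true_chl, true_zsd, contaminated, coast_km,
#'   bathymetry_m), `n_skipped`
#' @export
simulate_observations <- function(config, chl_field) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(chl_field, "composite_field"))
  set.seed(config$seed + 1L)
  r <- config$region
  n <- config$n_observations
  per_route <- ceiling(n / config$n_routes)
  lat <- lon <- numeric(0)
  lon_hi <- min(coastline_lon(config$coastline,
                              seq(r["lat_min"], r["lat_max"], by = 0.5))) - 0.02
  # a fixed share of routes hugs the coast (coastal shipping), which is
  # what places observations inside the contamination reach; the rest
  # cross the open-ocean part of the box
  n_coastal <- round(config$coastal_route_fraction * config$n_routes)
  for (k in seq_len(config$n_routes)) {
    lon_lo <- if (k <= n_coastal) lon_hi - config$coastal_band_deg else r["lon_min"]
    p1 <- c(stats::runif(1, r["lat_min"], r["lat_max"]),
            stats::runif(1, lon_lo, lon_hi))
    p2 <- c(stats::runif(1, r["lat_min"], r["lat_max"]),
            stats::runif(1, lon_lo, lon_hi))
    t <- seq(0, 1, length.out = per_route)
    lat <- c(lat, p1[1] + t * (p2[1] - p1[1]))
    lon <- c(lon, p1[2] + t * (p2[2] - p1[2]))
  }
  lat <- lat[seq_len(n)]
  lon <- lon[seq_len(n)]
  coast_km <- coast_distance_km(lat, lon, config$coastline)
  keep <- coast_km > 0   # ocean side only
  n_skipped <- sum(!keep)
  lat <- lat[keep]; lon <- lon[keep]; coast_km <- coast_km[keep]
  m <- sum(keep)
  year <- sample(config$years, m, replace = TRUE)
  doy <- sample.int(365L, m, replace = TRUE)
  idx <- grid_index(lat, lon, chl_field$grid)
  true_chl <- chl_field$values[cbind(idx$row + 1L, idx$col + 1L)]
  contaminated <- coast_km < config$coastal_km
  factor <- ifelse(contaminated, config$alpha, 1)
  true_zsd <- as.numeric(chl_to_zsd(true_chl, config$true_model)) * factor
  noise <- if (config$sigma_log10 > 0) {
    10^stats::rnorm(m, 0, config$sigma_log10)
  } else rep(1, m)
  observed <- true_zsd * noise
  id <- sprintf("syn%05d", seq_len(m))
  observations <- data.frame(
    record_id = id,
    secchi_depth_m = observed,
    latitude = lat,
    longitude = lon,
    day_of_year = doy,
    year = year,
    coastal_flag = NA,
    notes = "",
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    record_id = id,
    true_chl = true_chl,
    true_zsd = true_zsd,
    contaminated = contaminated,
    coast_km = coast_km,
    bathymetry_m = config$abyssal_depth_m *
      (1 - exp(-coast_km / config$shelf_scale_km)),
    stringsAsFactors = FALSE
  )
  list(observations = observations, truth = truth, n_skipped = n_skipped)
}

#' Simulate a complete synthetic world
#'
#' Convenience wrapper: chlorophyll field, context grids and observations
#' from one [scenario_config()].
#'
#' @param config a [scenario_config()]
#' @return list: `chl_field`, `bathy`, `coast`, `observations`, `truth`,
#'   `n_skipped`, `config`
#' @export
simulate_world <- function(config) {
  chl_field <- simulate_chl_field(config)
  coast <- simulate_coast(config)
  obs <- simulate_observations(config, chl_field)
  list(chl_field = chl_field, bathy = coast$bathy, coast = coast$coast,
       observations = obs$observations, truth = obs$truth,
       n_skipped = obs$n_skipped, config = config)
}
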