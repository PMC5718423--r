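#' Log-space correlation between Secchi depth and chlorophyll
#'
#' Pearson correlation between log10(Secchi depth) and log10(chlorophyll)
#' with a two-sided p-value from the t transform. Pairs with missing
#' chlorophyll are dropped and counted. In open-ocean optics this
#' correlation is negative: more pigment, less transparency.
#'
#' @param secchi_depths in-situ Secchi depths, m, positive
#' @param chls matched chlorophyll, mg m^-3, positive or NA
#' @param log_chl take log10 of chlorophyll (default); FALSE correlates
#'   log10(depth) against linear chlorophyll
#' @return list of class `secchi_correlation`: `r`, `n`, `p_value`,
#'   `n_dropped`
#' @export
log_correlation <- function(secchi_depths, chls, log_chl = TRUE) {
  stopifnot(length(secchi_depths) == length(chls))
  keep <- is.finite(secchi_depths) & is.finite(chls)
  n_dropped <- sum(!keep)
  d <- secchi_depths[keep]
  c <- chls[keep]
  if (length(d) < 3L) stop("need at least 3 complete pairs, got ", length(d))
  if (any(d <= 0) || any(c <= 0)) stop("depths and chlorophyll must be positive")
  x <- log10(d)
  y <- if (log_chl) log10(c) else c
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), n = length(d),
                 p_value = ct$p.value, n_dropped = n_dropped),
            class = "secchi_correlation")
}

#' @export
print.secchi_correlation <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d, p = %.3g; %d pairs dropped)\n",
              x$r, x$n, x$p_value, x$n_dropped))
  invisible(x)
}

#' Ordinary least-squares validation regression
#'
#' Fits y = a + b x with an intercept, the working regression of the
#' validation: by convention x is the seafarer Secchi depth and y the
#' satellite-estimated Secchi depth, both in linear meters, so the slope
#' reads as "satellite over seafarer". An extrapolated log-polynomial can
#' produce non-positive satellite depths; `drop_nonpositive` removes pairs
#' with a non-positive value on either axis before fitting (counted, never
#' silent). A log10-log10 working scale is available.
#'
#' @param x predictor values (default reading: seafarer Secchi depth, m)
#' @param y response values (default: satellite-estimated Secchi depth, m)
#' @param drop_nonpositive drop pairs with x <= 0 or y <= 0
#' @param scale "linear" (default) or "log10" working scale
#' @param x_name,y_name axis labels carried into reports
#' @return object of class `secchi_regression`: slope, intercept,
#'   slope_ci_95, p_value, n, residual_sd, the working-scale data and
#'   residuals, `used` (logical index into the input pairs), and the
#'   underlying `lm` fit
#' @export
fit_regression <- function(x, y, drop_nonpositive = TRUE,
                           scale = c("linear", "log10"),
                           x_name = "seafarer Zsd (m)",
                           y_name = "satellite Zsd (m)") {
  scale <- match.arg(scale)
  stopifnot(length(x) == length(y))
  used <- is.finite(x) & is.finite(y)
  n_missing <- sum(!used)
  if (drop_nonpositive || scale == "log10") {
    used <- used & x > 0 & y > 0
  }
  n_nonpositive <- sum(is.finite(x) & is.finite(y)) - sum(used)
  xw <- x[used]; yw <- y[used]
  if (scale == "log10") { xw <- log10(xw); yw <- log10(yw) }
  if (length(xw) < 3L) stop("need at least 3 usable pairs, got ", length(xw))
  if (stats::sd(xw) == 0) stop("zero variance in x: regression undefined")
  fit <- stats::lm(yw ~ xw)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    slope_ci_95 = unname(ci["xw", ]),
    intercept_ci_95 = unname(ci["(Intercept)", ]),
    p_value = sm$coefficients["xw", "Pr(>|t|)"],
    n = length(xw),
    residual_sd = sm$sigma,
    x = xw, y = yw,
    residuals = unname(stats::residuals(fit)),
    used = used,
    n_dropped_missing = n_missing,
    n_dropped_nonpositive = n_nonpositive,
    scale = scale, x_name = x_name, y_name = y_name,
    lm_fit = fit
  ), class = "secchi_regression")
}

#' @export
print.secchi_regression <- function(x, ...) {
  cat(sprintf("%s ~ %s [%s scale]\n", x$y_name, x$x_name, x$scale))
  cat(sprintf("  b = %.3f (95%% CI %.3f-%.3f, p = %.3g), intercept = %.3f\n",
              x$slope, x$slope_ci_95[1], x$slope_ci_95[2], x$p_value,
              x$intercept))
  cat(sprintf("  n = %d, residual sd = %.3f (%d missing, %d non-positive dropped)\n",
              x$n, x$residual_sd, x$n_dropped_missing, x$n_dropped_nonpositive))
  invisible(x)
}

#' Predict from the validation regression with a 95% interval
#'
#' Point prediction a + b x0 with a t-based 95% interval: by default the
#' confidence interval of the mean response, optionally the wider
#' prediction interval for a single new observation.
#'
#' @param reg a [fit_regression()] result
#' @param x0 predictor value(s) on the regression's working scale
#' @param interval "confidence" (mean response, default) or "prediction"
#' @return data.frame with `x0`, `fit`, `lwr`, `upr`
#' @export
predict_with_ci <- function(reg, x0, interval = c("confidence", "prediction")) {
  interval <- match.arg(interval)
  stopifnot(inherits(reg, "secchi_regression"))
  p <- stats::predict(reg$lm_fit, newdata = data.frame(xw = x0),
                      interval = interval, level = 0.95)
  data.frame(x0 = x0, fit = p[, "fit"], lwr = p[, "lwr"], upr = p[, "upr"])
}

#' Partition regression residuals by sign, keeping geography
#'
#' Every pair used in the fit becomes a residual record carrying its
#' position, bathymetry and coast distance, so the sign pattern can be
#' mapped: open-ocean records above the line, optically contaminated
#' coastal records below it.
#'
#' @param reg a [fit_regression()] result
#' @param matchups the annotated matchup data.frame the regression was
#'   fitted from (same row order as the x/y vectors passed to
#'   [fit_regression()])
#' @param tol |residual| <= tol counts as zero
#' @return list with `records` (data.frame: record_id, lat, lon,
#'   bathymetry_m, coast_distance_km, coastal_flag, residual, sign) and
#'   `counts` (n_positive, n_negative, n_zero)
#' @export
partition_residuals <- function(reg, matchups, tol = 1e-12) {
  stopifnot(inherits(reg, "secchi_regression"),
            nrow(matchups) == length(reg$used))
  m <- matchups[reg$used, , drop = FALSE]
  res <- reg$residuals
  sgn <- ifelse(abs(res) <= tol, "zero",
                ifelse(res > 0, "positive", "negative"))
  records <- data.frame(
    record_id = m$record_id,
    latitude = m$latitude,
    longitude = m$longitude,
    bathymetry_m = m$bathymetry_m,
    coast_distance_km = m$coast_distance_km,
    coastal_flag = m$coastal_flag,
    residual = res,
    sign = sgn,
    stringsAsFactors = FALSE
  )
  counts <- list(n_positive = sum(sgn == "positive"),
                 n_negative = sum(sgn == "negative"),
                 n_zero = sum(sgn == "zero"),
                 n = length(sgn))
  list(records = records, counts = counts)
}

#' Stratify records by bathymetry or coast distance
#'
#' Bins records into right-open intervals [e_i, e_{i+1}) of a context
#' variable and summarises a value column per bin (n, median,
#' interquartile range). Records with a missing stratification variable
#' are reported separately, never lost; empty bins appear with n = 0.
#'
#' @param records data.frame (residual records or matchups)
#' @param variable "bathymetry_m" or "coast_distance_km"
#' @param bin_edges strictly increasing edges; use Inf to close the top
#' @param value name of the column to summarise (default "residual")
#' @return data.frame with bin_lo, bin_hi, n, median, iqr and an
#'   attribute `n_missing`
#' @export
stratify <- function(records, variable, bin_edges, value = "residual") {
  stopifnot(is.data.frame(records), variable %in% names(records),
            value %in% names(records))
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  v <- records[[variable]]
  val <- records[[value]]
  missing <- is.na(v)
  bin <- findInterval(v[!missing], bin_edges, rightmost.closed = FALSE,
                      left.open = FALSE)
  in_range <- bin >= 1 & bin < length(bin_edges)
  nb <- length(bin_edges) - 1L
  out <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1],
                    n = 0L, median = NA_real_, iqr = NA_real_)
  vv <- val[!missing][in_range]
  bb <- bin[in_range]
  for (b in seq_len(nb)) {
    sel <- bb == b
    out$n[b] <- sum(sel)
    if (any(sel)) {
      out$median[b] <- stats::median(vv[sel])
      out$iqr[b] <- stats::IQR(vv[sel])
    }
  }
  attr(out, "n_missing") <- sum(missing)
  attr(out, "n_out_of_range") <- sum(!in_range)
  out
}

#' Export residual records as GeoJSON points
#'
#' Mapping hand-off: one Point feature per residual record with residual,
#' sign, bathymetry and coast distance as properties.
#'
#' @param records residual records from [partition_residuals()]
#' @param path output path
#' @export
write_residuals_geojson <- function(records, path) {
  features <- lapply(seq_len(nrow(records)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(records$longitude[i],
                                      records$latitude[i])),
      properties = list(
        record_id = records$record_id[i],
        residual = records$residual[i],
        sign = records$sign[i],
        bathymetry_m = records$bathymetry_m[i],
        coast_distance_km = records$coast_distance_km[i]
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
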