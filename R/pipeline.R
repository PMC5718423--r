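#' Declarative configuration of a full matchup run
#'
#' @param observations observation data.frame (see [read_observations()])
#'   or a path to an observation CSV
#' @param composite_source a composite-source function (see
#'   [composite_source_memory()]) supplying chlorophyll fields
#' @param grid the [grid_spec()] of the composites
#' @param model the [bio_optical_model()] used for conversion, or a path
#'   to a serialised model file
#' @param bathy,coast [context_grid()] objects for annotation (optional;
#'   without them records keep NA context and an unknown coastal flag)
#' @param mode chlorophyll extraction, "single" or "kernel3x3"
#' @param length_days composite length, 1 or 8
#' @param exclude_coastal drop QC-flagged coastal records before the
#'   statistics (default FALSE: flag, don't drop)
#' @param qc_bathy_threshold_m,qc_coast_threshold_km coastal QC
#'   thresholds (see [qc_flag_coastal()])
#' @param drop_nonpositive drop non-positive satellite depths before the
#'   regression
#' @param scale regression working scale, "linear" or "log10"
#' @param orientation which variable is the regression response:
#'   "seafarer_on_satellite" (default; residuals then live on the
#'   observed in-situ axis, so coastal optical contamination shows as
#'   negative residuals) or "satellite_on_seafarer" (the
#'   "satellite over seafarer" slope reading)
#' @param predict_at predictor depths (m) at which to report the
#'   response-depth prediction with its 95% confidence interval
#' @param strat_edges_bathy,strat_edges_coast bin edges for the residual
#'   stratifications
#' @param out_dir directory for intermediate tables and the manifest
#'   (NULL = in-memory only)
#' @return an object of class `run_config`
#' @export
run_config <- function(observations, composite_source, grid, model,
                       bathy = NULL, coast = NULL,
                       mode = c("single", "kernel3x3"),
                       length_days = 8L,
                       exclude_coastal = FALSE,
                       qc_bathy_threshold_m = 25,
                       qc_coast_threshold_km = 1,
                       drop_nonpositive = TRUE,
                       scale = c("linear", "log10"),
                       orientation = c("seafarer_on_satellite",
                                       "satellite_on_seafarer"),
                       predict_at = 10,
                       strat_edges_bathy = c(0, 25, Inf),
                       strat_edges_coast = c(0, 1, 20, Inf),
                       out_dir = NULL) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  orientation <- match.arg(orientation)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full matchup-validation pipeline
#'
#' Executes the stage sequence read -> matchup -> convert -> annotate ->
#' statistics under one configuration, logging record counts in and out
#' of every stage. The result manifest carries the coverage report, the
#' QC report, the correlation, the regression with its slope CI, the
#' predictions with confidence intervals, the residual sign partition and
#' the stratified residual summaries. With `out_dir` set, intermediate
#' tables (matchups, residual records, strata) and the manifest JSON are
#' written for stage-level inspection. Deterministic given config and
#' inputs.
#'
#' @param config a [run_config()]
#' @return list of class `run_result`: `manifest` (counts, warnings,
#'   statistics), `matchups` (annotated table), `correlation`,
#'   `regression`, `predictions`, `residuals`, `strata`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  manifest <- list(stages = list(), warnings = character())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  # --- read ---------------------------------------------------------
  obs <- config$observations
  rejects <- NULL
  if (is.character(obs)) {
    rd <- read_observations(obs)
    obs <- rd$observations
    rejects <- rd$rejects
    note("read", n_in = nrow(obs) + nrow(rejects), n_accepted = nrow(obs),
         n_rejected = nrow(rejects))
  } else {
    note("read", n_in = nrow(obs), n_accepted = nrow(obs), n_rejected = 0L)
  }
  if (nrow(obs) == 0L) stop("pipeline stage 'read': no usable observations")

  model <- config$model
  if (is.character(model)) model <- read_bio_optical_model(model)

  # --- matchup ------------------------------------------------------
  bm <- build_matchups(obs, config$composite_source, config$grid,
                       mode = config$mode, length_days = config$length_days)
  matchups <- bm$matchups
  note("matchup", n_in = nrow(obs), n_matched = bm$coverage$n_matched,
       n_unmatched = bm$coverage$n_unmatched,
       n_no_composite = bm$coverage$n_no_composite)
  manifest$coverage <- bm$coverage

  # --- convert ------------------------------------------------------
  has_chl <- !is.na(matchups$chl)
  zsd <- chl_to_zsd(matchups$chl[has_chl], model)
  matchups$zsd_sat[has_chl] <- as.numeric(zsd)
  n_extrap <- sum(attr(zsd, "extrapolated"))
  if (n_extrap > 0) {
    manifest$warnings <- c(manifest$warnings, sprintf(
      "%d conversions outside the model's valid chlorophyll range", n_extrap))
  }
  note("convert", n_in = nrow(matchups), n_converted = sum(has_chl),
       n_extrapolated = n_extrap)

  # --- annotate -----------------------------------------------------
  if (!is.null(config$bathy) && !is.null(config$coast)) {
    an <- annotate_matchups(matchups, config$bathy, config$coast,
                            bathy_threshold_m = config$qc_bathy_threshold_m,
                            coast_threshold_km = config$qc_coast_threshold_km)
    matchups <- an$matchups
    manifest$qc <- an$report
    if (an$report$n_unknown_coastal_flag > 0) {
      manifest$warnings <- c(manifest$warnings, sprintf(
        "%d records with unknown coastal flag", an$report$n_unknown_coastal_flag))
    }
    note("annotate", n_in = nrow(matchups), n_out = nrow(matchups),
         n_missing_bathymetry = an$report$n_missing_bathymetry,
         n_missing_coast_distance = an$report$n_missing_coast_distance)
  } else {
    note("annotate", n_in = nrow(matchups), n_out = nrow(matchups),
         skipped = TRUE)
  }

  # --- statistics ---------------------------------------------------
  stat_records <- matchups
  if (config$exclude_coastal) {
    drop <- !is.na(stat_records$coastal_flag) & stat_records$coastal_flag
    stat_records <- stat_records[!drop, , drop = FALSE]
  }
  correlation <- log_correlation(stat_records$secchi_depth_m,
                                 stat_records$chl)
  if (config$orientation == "seafarer_on_satellite") {
    regression <- fit_regression(
      stat_records$zsd_sat, stat_records$secchi_depth_m,
      drop_nonpositive = config$drop_nonpositive, scale = config$scale,
      x_name = "satellite Zsd (m)", y_name = "seafarer Zsd (m)")
  } else {
    regression <- fit_regression(
      stat_records$secchi_depth_m, stat_records$zsd_sat,
      drop_nonpositive = config$drop_nonpositive, scale = config$scale,
      x_name = "seafarer Zsd (m)", y_name = "satellite Zsd (m)")
  }
  predictions <- predict_with_ci(regression, config$predict_at)
  part <- partition_residuals(regression, stat_records)
  strata <- list(
    bathymetry = stratify(part$records, "bathymetry_m",
                          config$strat_edges_bathy),
    coast_distance = stratify(part$records, "coast_distance_km",
                              config$strat_edges_coast)
  )
  note("stats", n_in = nrow(stat_records), n_regressed = regression$n,
       n_dropped_missing = regression$n_dropped_missing,
       n_dropped_nonpositive = regression$n_dropped_nonpositive)

  manifest$statistics <- list(
    correlation = list(r = correlation$r, n = correlation$n,
                       p_value = correlation$p_value),
    regression = list(slope = regression$slope,
                      intercept = regression$intercept,
                      slope_ci_95 = regression$slope_ci_95,
                      p_value = regression$p_value,
                      n = regression$n,
                      residual_sd = regression$residual_sd,
                      scale = regression$scale),
    predictions = predictions,
    residual_counts = part$counts
  )

  result <- structure(
    list(manifest = manifest, matchups = matchups, rejects = rejects,
         correlation = correlation, regression = regression,
         predictions = predictions, residuals = part, strata = strata),
    class = "run_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(matchups, file.path(config$out_dir, "matchups.csv"),
                     row.names = FALSE)
    utils::write.csv(part$records,
                     file.path(config$out_dir, "residuals.csv"),
                     row.names = FALSE)
    utils::write.csv(strata$bathymetry,
                     file.path(config$out_dir, "strata_bathymetry.csv"),
                     row.names = FALSE)
    utils::write.csv(strata$coast_distance,
                     file.path(config$out_dir, "strata_coast_distance.csv"),
                     row.names = FALSE)
    write_residuals_geojson(part$records,
                            file.path(config$out_dir, "residuals.geojson"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  result
}

#' @export
print.run_result <- function(x, ...) {
  s <- x$manifest$statistics
  cat("<run_result>\n")
  cat(sprintf("  matchup coverage: %d / %d\n",
              x$manifest$coverage$n_matched, x$manifest$coverage$n))
  cat(sprintf("  log-space correlation: r = %.3f (n = %d)\n",
              s$correlation$r, s$correlation$n))
  cat(sprintf("  regression [%s]: b = %.3f (95%% CI %.3f-%.3f), intercept = %.3f, n = %d\n",
              s$regression$scale, s$regression$slope,
              s$regression$slope_ci_95[1], s$regression$slope_ci_95[2],
              s$regression$intercept, s$regression$n))
  for (i in seq_len(nrow(x$predictions))) {
    cat(sprintf("  prediction at x = %g: %.2f m (%.2f-%.2f, 95%% CI)\n",
                x$predictions$x0[i], x$predictions$fit[i],
                x$predictions$lwr[i], x$predictions$upr[i]))
  }
  cat(sprintf("  residuals: %d positive, %d negative, %d zero\n",
              x$residuals$counts$n_positive, x$residuals$counts$n_negative,
              x$residuals$counts$n_zero))
  invisible(x)
}

#' Simulate a synthetic world and run the pipeline over it
#'
#' One-call closed loop for testing and acceptance: builds the world from
#' a [scenario_config()], wraps its chlorophyll field as a constant
#' composite source, and runs [run_pipeline()] with the scenario's own
#' bio-optical model.
#'
#' @param scenario a [scenario_config()]
#' @param ... overrides passed to [run_config()] (e.g. `scale`,
#'   `exclude_coastal`, `out_dir`)
#' @return list with `world` (from [simulate_world()]) and `result`
#'   (from [run_pipeline()])
#' @export
run_scenario <- function(scenario, ...) {
  world <- simulate_world(scenario)
  config <- run_config(
    observations = world$observations,
    composite_source = composite_source_constant(world$chl_field),
    grid = world$chl_field$grid,
    model = scenario$true_model,
    bathy = world$bathy,
    coast = world$coast,
    ...
  )
  list(world = world, result = run_pipeline(config))
}
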