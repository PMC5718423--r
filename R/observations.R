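#' Read citizen-science Secchi observations
#'
#' Reads a comma-separated table of seafarer Secchi-disk measurements:
#' depth (m), position (decimal degrees), date (day of year and year) and
#' a record id. Column names are matched case-insensitively and can be
#' remapped through `dialect`. Rows that fail validation (non-positive or
#' non-finite depth, coordinates out of range, day of year inconsistent
#' with the calendar, year before the study period) are routed to a
#' rejects table with a reason, never silently dropped; input order is
#' preserved.
#'
#' @param path path to a CSV file with a header row
#' @param dialect named character vector mapping the canonical column
#'   names `id`, `secchi_depth_m`, `latitude`, `longitude`,
#'   `day_of_year`, `year` to the file's column names
#' @param min_year earliest acceptable year (study programme start)
#' @return list with `observations` (accepted rows, schema below) and
#'   `rejects` (failed rows plus a `reason` column). Observation columns:
#'   `record_id`, `secchi_depth_m`, `latitude`, `longitude`
#'   (normalised to [-180, 180)), `day_of_year`, `year`, `coastal_flag`
#'   (NA until QC), `notes`.
#' @export
read_observations <- function(path, dialect = NULL, min_year = 2013L) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  canonical <- c(id = "id", secchi_depth_m = "secchi_depth_m",
                 latitude = "latitude", longitude = "longitude",
                 day_of_year = "day_of_year", year = "year")
  if (!is.null(dialect)) canonical[names(dialect)] <- dialect
  have <- tolower(names(raw))
  # accept our own output schema back: record_id stands in for id
  if (!tolower(canonical["id"]) %in% have && "record_id" %in% have &&
      !("id" %in% names(dialect))) {
    canonical["id"] <- "record_id"
  }
  pos <- match(tolower(canonical), have)
  if (anyNA(pos)) {
    stop("missing required column(s): ",
         paste(canonical[is.na(pos)], collapse = ", "))
  }
  notes_col <- match("notes", have)

  n <- nrow(raw)
  empty_obs <- data.frame(
    record_id = character(), secchi_depth_m = numeric(),
    latitude = numeric(), longitude = numeric(),
    day_of_year = integer(), year = integer(),
    coastal_flag = logical(), notes = character(),
    stringsAsFactors = FALSE
  )
  if (n == 0L) {
    warning("no data rows in ", path)
    return(list(observations = empty_obs,
                rejects = cbind(empty_obs[0, 1:6], reason = character())))
  }

  id <- raw[[pos[1]]]
  depth <- suppressWarnings(as.numeric(raw[[pos[2]]]))
  lat <- suppressWarnings(as.numeric(raw[[pos[3]]]))
  lon <- suppressWarnings(as.numeric(raw[[pos[4]]]))
  doy <- suppressWarnings(as.numeric(raw[[pos[5]]]))
  year <- suppressWarnings(as.numeric(raw[[pos[6]]]))
  notes <- if (!is.na(notes_col)) raw[[notes_col]] else rep("", n)

  reason <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  flag(is.na(depth), "unparseable depth")
  flag(!is.na(depth) & (!is.finite(depth) | depth <= 0), "nonpositive depth")
  flag(is.na(lat) | is.na(lon), "unparseable position")
  flag(!is.na(lat) & (lat < -90 | lat > 90), "latitude out of range")
  flag(!is.na(lon) & !is.finite(lon), "longitude out of range")
  flag(is.na(doy) | is.na(year), "unparseable date")
  ok_int <- !is.na(doy) & !is.na(year) & doy == round(doy) & year == round(year)
  flag(!is.na(doy) & !is.na(year) & !ok_int, "non-integer date fields")
  ydays <- ifelse(is_leap_year(year), 366L, 365L)
  flag(ok_int & (doy < 1 | doy > ydays), "day_of_year out of range for year")
  flag(ok_int & year < min_year, "year before study period")

  keep <- is.na(reason)
  obs <- data.frame(
    record_id = id[keep],
    secchi_depth_m = depth[keep],
    latitude = lat[keep],
    longitude = normalize_lon(lon[keep]),
    day_of_year = as.integer(doy[keep]),
    year = as.integer(year[keep]),
    coastal_flag = rep(NA, sum(keep)),
    notes = notes[keep],
    stringsAsFactors = FALSE
  )
  rejects <- data.frame(
    record_id = id[!keep], secchi_depth_m = raw[[pos[2]]][!keep],
    latitude = raw[[pos[3]]][!keep], longitude = raw[[pos[4]]][!keep],
    day_of_year = raw[[pos[5]]][!keep], year = raw[[pos[6]]][!keep],
    reason = reason[!keep], stringsAsFactors = FALSE
  )
  list(observations = obs, rejects = rejects)
}

#' Write observations back to CSV
#'
#' Writes the observation schema (including the `coastal_flag` column if
#' set) so that a read/write/read cycle round-trips all fields.
#'
#' @param observations observation data.frame
#' @param path output path
#' @export
write_observations <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Coastal optical-contamination QC flag
#'
#' In shallow or near-shore water, resuspended sediment and river-borne
#' dissolved organic matter reduce transparency independently of
#' phytoplankton, so records there are flagged — not removed — for the
#' validation statistics. A record is coastal when bathymetry < 25 m OR
#' distance to the nearest coast < 1 km; both inequalities are strict, so
#' values exactly at threshold count as open ocean. A missing predictor
#' leaves the flag unknown (NA) unless the other one already triggers it.
#'
#' @param observations observation or matchup data.frame, or a single
#'   record as a one-row data.frame
#' @param bathymetry_m water depth(s), m positive down; defaults to the
#'   `bathymetry_m` column
#' @param coast_distance_km distance(s) to the nearest coast, km; defaults
#'   to the `coast_distance_km` column
#' @param bathy_threshold_m,coast_threshold_km flag thresholds
#' @return `observations` with `coastal_flag` set (TRUE/FALSE/NA)
#' @export
qc_flag_coastal <- function(observations,
                            bathymetry_m = observations$bathymetry_m,
                            coast_distance_km = observations$coast_distance_km,
                            bathy_threshold_m = 25,
                            coast_threshold_km = 1) {
  stopifnot(is.data.frame(observations))
  n <- nrow(observations)
  bathy <- rep_len(if (is.null(bathymetry_m)) NA_real_ else bathymetry_m, n)
  coast <- rep_len(if (is.null(coast_distance_km)) NA_real_ else coast_distance_km, n)
  # NA | TRUE is TRUE: one triggering predictor decides even if the other
  # is missing; NA | FALSE stays unknown
  observations$coastal_flag <- (bathy < bathy_threshold_m) |
    (coast < coast_threshold_km)
  observations
}
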