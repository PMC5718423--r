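---
title: "Methods: matchup validation of citizen-science Secchi depths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matchup validation of citizen-science Secchi depths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secchimatch)
```

## Scope and procedure

`secchimatch` implements the validation chain for citizen-science
Secchi-disk observations against satellite ocean-colour chlorophyll:

1. **Ingest and QC** (`read_observations`, `qc_flag_coastal`) — parse the
   observation table (depth m, position, day of year, year, id), route
   invalid rows to a rejects table with reasons, and flag records in
   optically complex water.
2. **Matchup** (`grid_index`, `composite_period_for`,
   `extract_single_pixel`, `extract_kernel`, `build_matchups`) — locate
   each observation in the equal-angle Level-3 grid and in the 1-day or
   8-day composite period containing its date, and extract chlorophyll.
3. **Conversion** (`chl_to_zsd`, `zsd_to_chl`, `calibrate_model`) — a
   log-polynomial bio-optical model mapping chlorophyll to an estimated
   Secchi depth.
4. **Context annotation** (`idw_interpolate`, `annotate_matchups`) —
   bathymetry and distance-to-coast interpolated onto each position by
   inverse-squared-distance weighting, then the coastal flag.
5. **Statistics** (`log_correlation`, `fit_regression`,
   `predict_with_ci`, `partition_residuals`, `stratify`) — the log-space
   correlation, the OLS validation regression with t-based intervals,
   and the residual sign partition by coastal context.

`run_pipeline` executes 1–5 under one declarative `run_config`, writing
stage-level record counts, intermediate tables and a JSON manifest;
`run_scenario` wraps it around a synthetic world. Chlorophyll retrieval
itself (the OCI algorithm) is out of scope: chlorophyll is consumed as a
gridded input, never derived from radiances.

## The bio-optical model

The conversion is `log10(Zsd) = sum_k c_k X^k` with `X = log10(chl)`,
degree 3 by default. The published conversions of this type are fitted
closed forms whose adjusted coefficient values are not printed in the
validation literature we target, so the package **ships a synthetic
default** (`default_bio_optical_model()`: 10 m at 1 mg m^-3, ~26 m at
0.1 mg m^-3, ~3 m at 10 mg m^-3) whose provenance string says exactly
that; real analyses should supply coefficients or recalibrate. An
admissible model must be finite, positive and strictly decreasing in
chlorophyll over its valid range `[0.01, 30]` mg m^-3 (open-ocean,
phytoplankton-dominated water) — checked on a 10^4-point scan at
construction. Conversions outside the valid range return a value plus an
`extrapolated` flag rather than an error, because real matchups include
coastal chlorophyll.

Inversion brackets the root in `X` with `uniroot` at tolerance 1e-12;
the round-trip `chl -> Zsd -> chl` is verified below 1e-6 relative
error. Calibration minimises squared error in log10 space, either as a
full refit (`mode = "refit"`, via the normal equations with coefficient
standard errors) or an intercept-only scaling (`mode = "scale"`, a
single multiplicative adjustment of Zsd). Two guards apply: a
rank-deficiency check on the design, and a refusal — with a diagnostic
naming the data's chlorophyll range — of any fit that is not strictly
decreasing there. A calibrated model's valid range is clipped to where
the data constrained it, since a polynomial refit carries no warranty
outside its support. Whether a real adjustment was a refit or an output
scaling is typically unstated; both modes are provided, refit being the
default.

## Grid conventions and matchup rules

The Level-3 layout is cell-edge registered: row 0's northern edge is at
+90°, column 0's western edge at −180°, square cells in degrees
(default 4320 x 8640, the ~4 km grid). `grid_index` is
`floor((lat_max − lat)/cell)`; a point exactly on a cell's northern edge
belongs to that cell, the south pole clamps into the last row, and
longitudes are wrapped into [−180, 180). 8-day periods start on days 1,
9, 17, …, giving 46 periods per year with a short last period; there is
no nearest-in-time fallback — an observation whose period has no
composite is reported unmatched, never silently dropped.

Kernel extraction (3 x 3 by default) truncates at the poles, wraps
across the antimeridian, and returns the arithmetic mean of valid
pixels (the field's sources do not state the statistic; a median option
exists) together with the valid count, subject to `min_valid` (default
1). `half_width = 0` reduces exactly to single-pixel extraction.

## Inverse-distance interpolation

Context grids are cell-centre registered. The interpolator uses weights
`1/d^power` (power 2) over the `k = 4` nearest non-missing nodes — the
weighting is standard; the neighbourhood size is not, so both are
configuration. Distances are great-circle (haversine) meters, because
degree offsets distort zonally with latitude; for the same reason the
candidate-node search widens its column window by `1/cos(lat)`. A query
within 1 m of a node returns the node value exactly (removing the 1/d^2
singularity); a query with no valid node within `max_half_width = 3`
cells is treated as outside coverage and returns NA rather than an
interpolation across a large gap — records so affected get an unknown
coastal flag, counted in the QC report. The result is a convex
combination of node values, exact at nodes and continuous across cell
boundaries.

## Statistics

* **Correlation**: Pearson r between log10(depth) and log10(chl) (a
  linear-chl option exists), two-sided p from the t transform, with
  dropped incomplete pairs counted. Fewer than 3 pairs or zero variance
  is an error, not an NA.
* **Regression**: OLS with intercept on linear meters by default (a
  log10-log10 option exists). The response is configurable; the
  pipeline's default is **seafarer depth on satellite-estimated depth**,
  so that residuals live on the observed in-situ axis: coastal optical
  contamination darkens the *water the observer sees* without touching
  the chlorophyll-based estimate, and therefore shows as negative
  residuals in that orientation. The reversed orientation (the
  "satellite over seafarer" slope reading) is one switch away. An
  extrapolated polynomial can produce non-positive estimated depths;
  `drop_nonpositive` removes pairs with a non-positive value on either
  axis before fitting, with counts logged — the drop rule is explicit
  because which quantity went negative in the original analyses is not
  stated.
* **Prediction intervals**: the 95% interval reported for a predicted
  depth is the confidence interval of the *mean response* (the quoted
  bands in this literature are described as confidence intervals); the
  wider single-observation prediction interval is available via
  `interval = "prediction"`.
* **Residuals**: every fitted pair becomes a record carrying position,
  bathymetry, coast distance and sign (zero at |r| <= 1e-12), exported
  as CSV and GeoJSON for mapping; `stratify` bins by right-open
  intervals with per-bin n, median and IQR, reporting missing-variable
  records separately. p-values are reported as computed, unadjusted:
  the validation makes three headline tests, not a family needing
  correction.

## The synthetic world

The generator's defaults are the study conditions of the package's
tests: n = 500 observations, observer noise sigma_log10 = 0.1
(multiplicative log-normal, ~±26%), coastal contamination multiplier
alpha = 0.6 applied where coast distance < 20 km, drawn over a
North-Atlantic-like box (30–60°N, 45–5°W) against a meridional coastline
at 10°W.

* **Chlorophyll** is 10^(Gaussian field): white noise smoothed with a
  Gaussian kernel (correlation length 3 cells on a 1° grid, circular in
  longitude, reflected in latitude), standardised empirically to
  log10-mean −0.7 and sd 0.35 — a typical open-ocean level (~0.2
  mg m^-3) with realistic patchiness. sd = 0 degenerates to a constant
  field. A fixture helper perturbs the base field into 8 daily fields
  with per-pixel cloud dropouts (probability 0.3) whose valid-union mean
  reconstitutes the 8-day composite, for the 1-day vs 8-day comparison.
* **Coastline and context**: the straight (optionally sinusoidal)
  coastline admits a closed-form cross-track distance
  `R asin(cos(lat) sin(dlon))` (R = 6371.0088 km), against which the
  generator and an independent polyline oracle are tested; bathymetry is
  the monotone shelf profile `abyssal (1 − exp(−d/30 km))` saturating at
  4000 m; the land side is masked missing. Bathymetry is 0.5° and coast
  distance 0.25° by default — coarser than real products, chosen so a
  full world builds in about a second; a consequence is that
  inverse-distance interpolation cannot resolve the 1 km coastal-flag
  rule on synthetic grids (the flag mechanics are tested directly, and
  the pipeline exposes the thresholds for coarse-grid work).
* **Observations** lie along straight vessel routes; a fixed share
  (40% of 10 routes) runs in a 0.5° band hugging the coast, because
  coastal shipping is what places records inside the contamination
  reach. Truth tables (true chlorophyll, true depth, contamination flag)
  are emitted alongside for recovery tests. The truth uses the *pixel*
  chlorophyll, so with zero noise and no contamination the full
  pipeline closes exactly: slope 1, intercept 0, r = 1 to numerical
  precision.

What the generator does **not** emulate: retrieval error structure
(sensor noise, atmospheric correction), cloud patterns correlated with
weather, temporal mismatch within a composite window, non-straight
shipping behaviour, or a real coastline's geometry. Green tests
demonstrate the pipeline's correctness and statistical calibration
under a faithful rendition of its assumptions — not the field accuracy
of any satellite product.

## Numerical choices and problem sizes

Thresholds (25 m, 1 km) are strict inequalities: values exactly at
threshold are open ocean. QC flags mark records rather than deleting
them (the influence of coastal context is itself an analysis target);
exclusion is a config switch. Leap years follow the proleptic Gregorian
rule; date violations go to rejects. Pixel indexing is verified against
an exact-rational boundary search on dyadic-lattice points, where
integer arithmetic below 2^53 makes the oracle exact. Test and
acceptance problem sizes — 500-observation worlds, 1000-point oracle
sweeps, 100-replicate Monte-Carlo coverage studies at n = 300–500 —
were chosen to make coverage rates and medians stable at the asserted
bounds while a full suite run stays under a minute.

## Known limitations

* The default bio-optical coefficients are a documented synthetic
  stand-in, not published values; conclusions about real water require
  supplying or calibrating coefficients.
* Composite sources must present fields on the declared grid; Level-2
  swaths and on-the-fly compositing (beyond the test helper) are out of
  scope, as are base-map cartography and spatial autocorrelation
  modelling of residuals.
* The synthetic coast-distance resolution limits coastal-flag realism,
  as discussed above.
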