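# secchimatch

Matchup validation of citizen-science Secchi depths against satellite
ocean-colour chlorophyll.

## The problem

The Secchi disk — a 30 cm white disk lowered until it vanishes from
sight — gives the oldest and simplest measure of ocean transparency, and
in open ("Case 1") water transparency is controlled by phytoplankton
chlorophyll. Seafarers running a citizen-science programme can therefore
be checked against, and used to check, satellite ocean-colour products:
each in-situ Secchi depth is paired with the chlorophyll-a value of the
Level-3 composite pixel containing it, the chlorophyll is converted to a
satellite-estimated Secchi depth through a bio-optical model, and the
two depth estimates are compared by correlation, regression and residual
analysis. Near coasts the comparison degrades for non-biological
reasons — resuspended sediment and river-borne dissolved organic matter
darken the water without raising chlorophyll — so each record also
carries bathymetry and distance-to-coast, interpolated onto the
observation position, and a coastal QC flag (bathymetry < 25 m or coast
distance < 1 km).

`secchimatch` implements that whole chain as a tested R pipeline, plus a
seeded synthetic-world generator (spatially autocorrelated log-normal
chlorophyll fields, a coastline with shelf bathymetry and coast-distance
grids, vessel-track observations with observer noise and coastal
contamination) so that every stage — and the pipeline end to end — can be
validated without multi-gigabyte satellite downloads.

## The model

The bio-optical conversion is a Morel-type log-polynomial

    log10(Zsd) = c0 + c1 X + c2 X^2 + c3 X^3,   X = log10(chl)

with Zsd the Secchi depth (m) and chl the chlorophyll-a concentration
(mg m^-3), admissible only when strictly decreasing over its valid
chlorophyll range. It can be inverted (`zsd_to_chl`) and recalibrated
against matchup pairs (`calibrate_model`), either as a full refit or a
scale-only intercept adjustment. Context grids are interpolated by
inverse-squared-distance weighting over the four nearest nodes; the
validation statistics are the Pearson correlation of log10(depth) vs
log10(chl), an ordinary least-squares regression of seafarer on
satellite-estimated depth with a t-based 95% slope CI, mean-response
confidence intervals for predictions, and a residual sign partition
stratified by bathymetry and coast distance.

## Worked example

The numbered scripts under `analysis/` run the default synthetic study
(seed 2026, 500 observations, observer noise sigma_log10 = 0.1,
transparency multiplier 0.6 within 20 km of the coast):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_matchup.R
Rscript analysis/03_validate.R
Rscript analysis/04_calibrate.R
```

Stage 3 prints:

```
<run_result>
  matchup coverage: 500 / 500
  log-space correlation: r = -0.756 (n = 500)
  regression [linear]: b = 0.961 (95% CI 0.878-1.043), intercept = -0.131, n = 500
  prediction at x = 10: 9.47 m (8.06-10.89, 95% CI)
  residuals: 231 positive, 269 negative, 0 zero

residual medians: coastal -6.89 m (n=88) vs open ocean 0.66 m (n=412)
```

Reading: depth and chlorophyll anticorrelate in log space (r = -0.76);
the seafarer-vs-satellite regression is statistically consistent with
the identity line because the synthetic satellite uses the true
bio-optical model (slope CI covers 1); and the coastal stratum sits
almost 7 m below the regression line while the open ocean sits on it —
the geographic residual signature of coastal optical contamination.
Tables, a GeoJSON residual export for mapping and a JSON run manifest
land under `results/run_default/`.

Equivalent one-liner in R:

```r
library(secchimatch)
rs <- run_scenario(scenario_config(seed = 2026))
print(rs$result)
```

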