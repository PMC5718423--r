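#!/usr/bin/env Rscript
# Stage 3 — the validation statistics.
#
# Full pipeline over the stage-1 world: convert matched chlorophyll to
# satellite-estimated Secchi depth, annotate with bathymetry and coast
# distance by inverse-squared-distance interpolation, then compute the
# log-space correlation, the seafarer-vs-satellite regression with its
# 95% slope CI, predictions with confidence intervals, and the residual
# sign partition stratified by coastal context. Intermediate tables and
# the manifest land under results/run_default/.

suppressPackageStartupMessages(library(secchimatch))

seed <- 2026L
sc <- scenario_config(seed = seed)
rs <- run_scenario(sc, out_dir = "results/run_default")
res <- rs$result

print(res)

rec <- res$residuals$records
coastal <- !is.na(rec$coast_distance_km) & rec$coast_distance_km < sc$coastal_km
cat(sprintf("\nresidual medians: coastal %.2f m (n=%d) vs open ocean %.2f m (n=%d)\n",
            median(rec$residual[coastal]), sum(coastal),
            median(rec$residual[!coastal]), sum(!coastal)))
cat("coast-distance strata:\n")
print(res$strata$coast_distance)
cat("\nwrote results/run_default/\n")
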