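#!/usr/bin/env Rscript
# Stage 1 — build the default synthetic world.
#
# One seeded scenario stands in for the study's sampling of the oceans:
# a spatially autocorrelated log-normal chlorophyll field, a meridional
# coastline with shelf bathymetry and coast-distance grids, and 500
# vessel-track Secchi observations with log-normal observer noise
# (sigma_log10 = 0.1) and a 0.6 transparency multiplier within 20 km of
# the coast. Outputs: the observation table (S1-style CSV), the ground
# truth, and the true bio-optical model file.

suppressPackageStartupMessages(library(secchimatch))

seed <- 2026L
out <- "results/world"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sc <- scenario_config(seed = seed)
world <- simulate_world(sc)

write_observations(world$observations, file.path(out, "observations.csv"))
utils::write.csv(world$truth, file.path(out, "truth.csv"), row.names = FALSE)
write_bio_optical_model(sc$true_model, file.path(out, "true_model.txt"))

cat(sprintf("scenario seed %d: %d observations (%d skipped on land)\n",
            seed, nrow(world$observations), world$n_skipped))
cat(sprintf("contaminated (coast < %g km): %d\n",
            sc$coastal_km, sum(world$truth$contaminated)))
cat(sprintf("chlorophyll field: %d x %d pixels, log10 mean %.2f sd %.2f\n",
            world$chl_field$grid$n_rows, world$chl_field$grid$n_cols,
            mean(log10(world$chl_field$values)),
            sd(log10(world$chl_field$values))))
cat("wrote", out, "\n")
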