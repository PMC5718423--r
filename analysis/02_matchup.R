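#!/usr/bin/env Rscript
# Stage 2 — match the seafarer observations to composite chlorophyll.
#
# Reads the stage-1 observation table back from disk (exercising the
# ingest/QC path), regenerates the same seeded world for its gridded
# fields, and extracts single-pixel chlorophyll for every observation.
# Writes the matchup table and the coverage report.

suppressPackageStartupMessages(library(secchimatch))

seed <- 2026L
out <- "results"
sc <- scenario_config(seed = seed)
world <- simulate_world(sc)   # deterministic: same fields as stage 1

rd <- read_observations("results/world/observations.csv")
cat(sprintf("read %d observations, %d rejects\n",
            nrow(rd$observations), nrow(rd$rejects)))

bm <- build_matchups(rd$observations,
                     composite_source_constant(world$chl_field),
                     world$chl_field$grid, mode = "single",
                     length_days = 8L)
utils::write.csv(bm$matchups, file.path(out, "matchups_raw.csv"),
                 row.names = FALSE)
cat(sprintf("matchup coverage: %d / %d (%d missing pixel, %d no composite)\n",
            bm$coverage$n_matched, bm$coverage$n,
            bm$coverage$n_missing_pixel, bm$coverage$n_no_composite))
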