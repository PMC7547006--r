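#!/usr/bin/env Rscript

# Step 1: generate the synthetic study inputs.
#
# Emulates the survey programme's data situation: a 0.05-degree grid of
# daily weather (AR(1) anomalies around an austral seasonal cycle,
# zero-inflated rain), monthly NDVI, static soils, and 5,000 roadside
# survey records over one July-June year, dated September-May, with
# ordinal density classes realized from a latent square-root-scale
# abundance model.

library(locustgam)

dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(seed = 1, n_surveys = 5000)
env <- generate_env_grid(cfg)
surveys <- generate_surveys(cfg, env)

write_surveys(surveys, "results/surveys.csv")
saveRDS(env, "scratch/env_grid.rds")   # large; regenerate with seed 1 if absent
saveRDS(cfg, "scratch/sim_config.rds")

cat("grid:", length(env$lons), "x", length(env$lats), "cells,",
    length(env$dates), "days\n")
cat("surveys:", nrow(surveys), "| positive:",
    round(100 * mean(surveys$density_class > 0), 1), "%\n")
cat("dry days:", round(100 * mean(env$rain == 0), 1), "% of cell-days\n")
print(table(class = surveys$density_class))
print(table(stage = surveys$stage))
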