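#!/usr/bin/env Rscript

# Step 6: gridded abundance maps with combined uncertainty.
#
# Predicts density on the 0.05-degree grid for two mid-season dates,
# combines model standard error (delta method through the square-root
# link and back-transform) with the class-sampling variance, masks cells
# beyond 50 km of any surveyed site, and assigns bivariate
# density/uncertainty tercile classes. Also exports the gridded RMSE of
# holdout predictions.

library(locustgam)

env <- readRDS("scratch/env_grid.rds")
cfg <- readRDS("scratch/sim_config.rds")
surveys <- read_surveys("results/surveys.csv")
model <- readRDS("scratch/gam_full.rds")
features <- read_feature_table("results/features.csv")
features <- make_split(features, split_plan(seed = 3))

for (date in c("2010-01-15", "2010-03-15")) {
  grid <- predict_grid(model, env, as.Date(date),
                       scheme = cfg$class_scheme,
                       n_uncertainty_draws = 200,
                       surveyed_sites = surveys, seed = 6)
  grid <- bivariate_classify(grid)
  out <- sprintf("results/map_%s.csv", date)
  write.csv(as.data.frame(grid), out, row.names = FALSE)
  un <- !grid$masked
  cat(date, "| unmasked cells:", sum(un), "of", nrow(grid),
      "| median density:", signif(median(grid$estimate[un]), 3),
      "| median uncertainty fraction:",
      signif(median(grid$uncertainty_fraction[un]), 3), "\n")
  cat("  bivariate class counts (1..9):\n  ")
  print(table(factor(grid$class_index[un], levels = 1:9)))
}
edges <- data.frame(axis = c("density", "uncertainty"),
                    t(rbind(attr(grid, "density_edges"),
                            attr(grid, "uncertainty_edges"))))
write.csv(edges, "results/bivariate_edges.csv", row.names = FALSE)

ho <- features[features$split_label == "holdout", ]
pr <- predict_abundance(model, ho)
rmse_grid <- rmse_map(data.frame(lon = ho$lon, lat = ho$lat,
                                 observed = ho$response,
                                 predicted = pr$mu),
                      cell_size_deg = 0.25)
write.csv(rmse_grid, "results/rmse_map.csv", row.names = FALSE)
cat("RMSE map:", nrow(rmse_grid), "cells | range",
    paste(signif(range(rmse_grid$rmse), 3), collapse = " - "), "\n")
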