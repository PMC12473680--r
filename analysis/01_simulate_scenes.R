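#!/usr/bin/env Rscript

# Step 1 — simulate the synthetic study area.
#
# Builds the default landscape (200 fields on a 100 x 100 cell 60 m grid,
# 2022 class-area shares) and one season of scenes for each sensor:
# Sentinel-style 20 m reflectance pairs with SCL quality grids, Landsat-
# style 30 m pairs with QA_PIXEL grids, and Meteor-style 60 m daily NDVI
# composites. Writes the field polygons, the ground-truth label grid, a
# sample scene + mask, and the per-sensor cloud-fraction tally
# (the imagery-quality bookkeeping table) under results/.

suppressPackageStartupMessages(library(phenofuse))

seed <- 42
dir.create("results", showWarnings = FALSE)
dir.create("scratch/cache", showWarnings = FALSE, recursive = TRUE)

landscape <- simulate_landscape(rng_seed = seed)
print(landscape)
write_fields(landscape$fields, "results/fields.geojson")

label_num <- matrix(match(landscape$label, c("soybean", "grain_crops",
                                             "buckwheat",
                                             "perennial_grasses", "fallow")),
                    nrow(landscape$label), ncol(landscape$label))
write_ascii_grid(label_num, landscape$grid, "results/label_grid.asc",
                 digits = 1)

sensors <- default_sensor_models()
tally <- list()
for (nm in names(sensors)) {
  stack <- generate_scene_stack(landscape, sensors[[nm]],
                                rng_seed = seed + match(nm, names(sensors)))
  fr <- vapply(stack$scenes, function(s) s$cloud_fraction, numeric(1))
  tally[[nm]] <- as.integer(cloud_bin_tally(fr))
  cat(sprintf("%-9s %3d scenes | masked-pixel bins <5/5-20/20-50/>50: %s\n",
              nm, length(stack$scenes),
              paste(tally[[nm]], collapse = "/")))
  # one mid-season sample scene per sensor for inspection (a 60 x 60 cell
  # north-west window keeps the files small)
  mid <- stack$scenes[[ceiling(length(stack$scenes) / 2)]]
  win <- function(m) m[seq_len(min(60, nrow(m))), seq_len(min(60, ncol(m)))]
  wg <- grid_spec(stack$grid$xmin, stack$grid$ymax, stack$grid$px,
                  min(60, stack$grid$nrow), min(60, stack$grid$ncol))
  if (!is.null(mid$ndvi)) {
    write_ascii_grid(win(mid$ndvi), wg,
                     sprintf("results/%s_2022%03d.asc", nm, mid$doy),
                     digits = 4)
  } else {
    write_ascii_grid(win(compute_ndvi(mid$nir, mid$red)), wg,
                     sprintf("results/%s_2022%03d.asc", nm, mid$doy),
                     digits = 4)
    mask <- if (nm == "sentinel") sentinel_validity(mid$scl)
    else landsat_validity(mid$qa)
    write_ascii_grid(win(mask$valid + 0), wg,
                     sprintf("results/%s_2022%03d_mask.asc", nm, mid$doy),
                     digits = 1)
  }
}

tab <- data.frame(masked_pct = c("<5", "5-20", "20-50", ">50"),
                  sentinel = tally$sentinel, landsat = tally$landsat)
write.csv(tab, "results/cloud_tally.csv", row.names = FALSE)
cat("Cloud tally (cf. the published per-year imagery-quality table):\n")
print(tab)
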