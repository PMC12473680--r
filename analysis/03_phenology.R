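#!/usr/bin/env Rscript

# Step 3 — reference phenology.
#
# Summarizes per-field seasonal maxima (NDVImax, DOYmax) per class and
# sensor from the harmonized cube, splits the perennial-grass season into
# early/late maxima, and compares three simulated seasons with one-way
# ANOVA + Tukey HSD (the year-to-year comparison of the per-class
# indicator tables, here across seasons simulated with different seeds).

suppressPackageStartupMessages(library(phenofuse))

seed <- 42
dir.create("results", showWarnings = FALSE)
run <- run_pipeline(seed = seed, run_cv = FALSE,
                    cache_dir = "scratch/cache")

rows <- list()
for (sensor in names(run$phenology)) {
  ph <- run$phenology[[sensor]]
  for (cl in unique(ph$class)) {
    sub <- ph[ph$class == cl, ]
    if (nrow(sub) < 2) next
    rows[[length(rows) + 1]] <-
      class_summary(sub$ndvi_max, sub$doy_max, class = cl, sensor = sensor)
  }
}
summ <- do.call(rbind, rows)
summ[, 5:10] <- round(summ[, 5:10], 3)
write.csv(summ, "results/class_phenology_summary.csv", row.names = FALSE)
cat("Per-class seasonal maxima (mean +/- 95% half-width, CV%):\n")
print(summ[summ$sensor == "sentinel", ], row.names = FALSE)

# early/late maxima for the bimodal perennial grasses (split DOY 210)
ph <- run$phenology$sentinel
pg <- ph[ph$class == "perennial_grasses", ]
cat(sprintf("\nPerennial grasses (n=%d): first max %.2f at DOY %.0f, second max %.2f at DOY %.0f\n",
            nrow(pg), mean(pg$ndvi_max1, na.rm = TRUE),
            mean(pg$doy_max1, na.rm = TRUE),
            mean(pg$ndvi_max2, na.rm = TRUE),
            mean(pg$doy_max2, na.rm = TRUE)))

# season-to-season comparison: three simulated seasons, soybean NDVImax
seasons <- lapply(c(seed, seed + 1000, seed + 2000), function(s) {
  set.seed(s)
  m <- default_class_models()$soybean
  vapply(1:40, function(i) max(sample_phenology_curve(m)$fn(121:296)),
         numeric(1))
})
gc <- anova_tukey(unlist(seasons),
                  rep(c("season1", "season2", "season3"), each = 40))
cat("\nSoybean NDVImax across three simulated seasons "
    , "(same generating model, expect no effect):\n", sep = "")
print(gc)
comp <- data.frame(F = gc$F, p_anova = gc$p_anova)
write.csv(cbind(comp, gc$pairwise), "results/season_anova_soybean.csv",
          row.names = FALSE)
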