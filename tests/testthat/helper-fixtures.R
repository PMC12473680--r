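# Shared fixtures: small landscapes and sample tables built in code.

tiny_landscape <- function(n_fields = 25, grid_cells = 40, seed = 1, ...) {
  simulate_landscape(
    default_landscape_config(n_fields = n_fields, grid_cells = grid_cells,
                             ...),
    rng_seed = seed)
}

# A deterministic sample table with explicit field sizes, for split/CV
# tests that do not need the raster pipeline.
toy_sample_table <- function(n_fields_per_class = 8, cells_per_field = 4,
                             classes = c("soybean", "grain_crops",
                                         "buckwheat"),
                             seed = 1) {
  set.seed(seed)
  rows <- list()
  fid <- 0
  for (cl in classes) {
    for (k in seq_len(n_fields_per_class)) {
      fid <- fid + 1
      n <- if (length(cells_per_field) > 1)
        sample(cells_per_field, 1) else cells_per_field
      mu <- match(cl, classes)
      rows[[length(rows) + 1]] <- data.frame(
        f1 = rnorm(n, mu), f2 = rnorm(n, -mu),
        class = cl, field_id = fid, cell = seq_len(n))
    }
  }
  out <- do.call(rbind, rows)
  out$class <- factor(out$class, levels = phenofuse:::CLASS_LEVELS)
  out
}

fixture_confusion <- function(name) {
  read_confusion_csv(system.file("extdata", "confusion",
                                 paste0(name, "_2022_2024.csv"),
                                 package = "phenofuse"))
}
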