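test_that("degenerate (sd 0) soybean model peaks exactly as configured", {
  m <- class_phenology_model("soybean", 0.88, 0, 221, 0)
  curve <- sample_phenology_curve(m, rng_seed = 1)
  v <- curve$fn(121:296)
  expect_equal(max(v), 0.88)
  expect_equal((121:296)[which.max(v)], 221)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("models with a secondary peak yield two local maxima", {
  m <- class_phenology_model(
    "buckwheat", 0.8, 0, 170, 0,
    secondary_peak = list(value_mean = 0.75, value_sd = 0,
                          doy_mean = 250, doy_sd = 0))
  curve <- sample_phenology_curve(m, rng_seed = 2)
  v <- curve$fn(121:296)
  interior <- 2:175
  n_local_max <- sum(v[interior] > v[interior - 1] &
                       v[interior] > v[interior + 1])
  expect_equal(n_local_max, 2)
})

test_that("invalid class labels are a configuration error", {
  expect_error(class_phenology_model("corn", 0.8, 0.02, 200, 5),
               "invalid class label")
})

test_that("sampled curve maxima recover the configured mean", {
  m <- default_class_models()$soybean
  set.seed(1)
  maxima <- replicate(1000, {
    max(sample_phenology_curve(m)$fn(121:296))
  })
  expect_lt(abs(mean(maxima) - 0.88), 0.01)
  # every sampled peak within mean +/- 4 sd and the NDVI domain
  expect_true(all(maxima <= 1 & maxima >= 0))
  expect_true(all(abs(maxima - 0.88) <= 4 * m$peak_value_sd + 1e-6))
})

test_that("Meteor stacks deliver one daily 60 m scene per scheduled day", {
  L <- tiny_landscape(n_fields = 10, grid_cells = 30)
  st <- generate_scene_stack(L, default_sensor_models()$meteor, rng_seed = 3)
  expect_equal(length(st$scenes), 148)
  expect_equal(st$dates, 122:269)
  expect_equal(dim(st$scenes[[1]]$ndvi), c(30, 30))
  expect_error(generate_scene_stack(L, default_sensor_models()$meteor,
                                    schedule = integer(0)),
               "empty acquisition schedule")
})

test_that("noiseless cloud-free pixels reproduce their class curve exactly", {
  cfg <- default_landscape_config(n_fields = 10, grid_cells = 30,
                                  spatial_sd = 0)
  L <- simulate_landscape(cfg, rng_seed = 4)
  sensor <- sensor_model("sentinel", 20, 10, additive_bias = 0,
                         peak_shift = 0, noise_sd = 0)
  st <- generate_scene_stack(L, sensor, rng_seed = 5)
  obs <- stack_observations(st)
  fid <- phenofuse:::expand_to_native(L$field_id, st$factor)
  px <- which(!is.na(as.vector(fid)))[1]
  k <- as.vector(fid)[px]
  expect_equal(obs$ndvi[, px], L$curves[[k]]$fn(st$dates),
               tolerance = 1e-12)
})

test_that("drawn cloud-fraction bins follow the configured distribution", {
  probs <- c(8, 5, 11, 37) / 61
  set.seed(123)
  counts <- replicate(200, {
    draws <- replicate(61, phenofuse:::draw_mask_fraction(probs)$bin)
    sum(draws == "<5")
  })
  # binomial: mean 8, se of the mean over 200 seasons ~ 0.18
  expect_lt(abs(mean(counts) - 8), 0.8)
})

test_that("scene generation is bit-identical under a fixed seed", {
  L <- tiny_landscape(n_fields = 10, grid_cells = 30)
  s1 <- generate_scene_stack(L, default_sensor_models()$sentinel, 7)
  s2 <- generate_scene_stack(L, default_sensor_models()$sentinel, 7)
  expect_identical(s1, s2)
  L2 <- tiny_landscape(n_fields = 10, grid_cells = 30)
  expect_identical(L, L2)
})

test_that("all generated NDVI stays inside [-1, 1]", {
  L <- tiny_landscape(n_fields = 10, grid_cells = 30)
  for (sensor in default_sensor_models()) {
    st <- generate_scene_stack(L, sensor, 11,
                               schedule = if (sensor$sensor_id == "meteor")
                                 NULL else c(150L, 200L, 250L))
    obs <- stack_observations(st)
    expect_true(all(obs$ndvi >= -1 & obs$ndvi <= 1, na.rm = TRUE))
  }
})

test_that("rasterization matches a per-cell containment oracle", {
  g <- grid_spec(0, 1, 0.1, 10, 10)
  # one square field covering exactly 4 cells
  sq <- cbind(c(0.2, 0.4, 0.4, 0.2, 0.2), c(0.8, 0.8, 0.6, 0.6, 0.8))
  ras <- rasterize_fields(field_set(1L, "soybean", list(sq)), g)
  expect_equal(sum(!is.na(ras$label)), 4)

  empty <- rasterize_fields(field_set(integer(0), character(0), list()), g)
  expect_true(all(is.na(empty$label)))

  # random non-overlapping rectangles vs a bounds-check oracle
  set.seed(31)
  # edges offset from the cell-center lattice so the containment rule is
  # unambiguous for both routes
  rects <- list(c(0.04, 0.26, 0.54, 0.96), c(0.44, 0.86, 0.14, 0.46),
                c(0.56, 0.74, 0.64, 0.84))
  rings <- lapply(rects, function(r)
    cbind(c(r[1], r[2], r[2], r[1], r[1]), c(r[4], r[4], r[3], r[3], r[4])))
  fs <- field_set(1:3, c("soybean", "fallow", "buckwheat"), rings)
  ras2 <- rasterize_fields(fs, g)
  oracle <- matrix(NA_integer_, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    ctr <- cell_center(g, i, j)
    for (k in 1:3) {
      r <- rects[[k]]
      if (ctr$lon > r[1] && ctr$lon < r[2] && ctr$lat > r[3] &&
          ctr$lat < r[4]) oracle[i, j] <- k
    }
  }
  expect_identical(ras2$field_id, oracle)

  # overlap is an error naming the offenders
  overlap <- field_set(1:2, c("soybean", "fallow"),
                       list(rings[[1]], rings[[1]]))
  expect_error(rasterize_fields(overlap, g), "overlapping fields")
})

test_that("landscape class proportions track the configured shares", {
  L <- tiny_landscape(n_fields = 100, grid_cells = 70, seed = 6)
  counts <- table(L$field_table$class)
  props <- L$config$class_proportions
  for (cl in names(props))
    expect_lt(abs(counts[[cl]] / 100 - props[[cl]]), 0.03)
  # every field maps to at least one cell of the target grid
  expect_true(all(L$fields$id %in% unique(as.vector(L$field_id))))
})
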