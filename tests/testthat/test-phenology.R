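make_cube <- function(values_by_cell, label, fid) {
  n <- length(values_by_cell)
  g <- grid_spec(0, 1, 0.1, 1, n)
  layer <- do.call(rbind, values_by_cell)
  assemble_cube(list(sentinel = layer), g, label, fid)
}

test_that("field-mean series averages cells and matches an explicit oracle", {
  s1 <- rep(0.4, 26); s2 <- rep(0.6, 26)
  cube <- make_cube(list(s1, s2), c("soybean", "soybean"), c(1L, 1L))
  expect_equal(field_mean_series(cube, 1, "sentinel"), rep(0.5, 26))

  cube1 <- make_cube(list(s1), "soybean", 1L)
  expect_equal(field_mean_series(cube1, 1, "sentinel"), s1)

  set.seed(19)
  cells <- lapply(1:5, function(i) runif(26))
  cube5 <- make_cube(cells, rep("fallow", 5), rep(2L, 5))
  oracle <- sapply(1:26, function(w) mean(sapply(cells, `[`, w)))
  expect_equal(field_mean_series(cube5, 2, "sentinel"), oracle)

  # permutation invariance
  perm <- sample(5)
  cube5p <- make_cube(cells[perm], rep("fallow", 5), rep(2L, 5))
  expect_equal(field_mean_series(cube5p, 2, "sentinel"), oracle)

  expect_error(field_mean_series(cube5, 99, "sentinel"),
               "insufficient data")
})

test_that("seasonal maximum extraction honors the earliest-tie rule", {
  inc <- seq(0.1, 0.9, length.out = 26)
  expect_equal(unname(extract_max(inc)[2]), 296)

  v <- rep(0.2, 26); v[15] <- 0.88
  m <- extract_max(v)
  expect_equal(unname(m[1]), 0.88)
  expect_equal(unname(m[2]), weekly_anchors()[15])

  v2 <- rep(0.2, 26); v2[c(10, 20)] <- 0.7
  expect_equal(unname(extract_max(v2)[2]), weekly_anchors()[10])
  expect_error(extract_max(rep(NA_real_, 26)), "insufficient data")
})

test_that("dual-maximum extraction splits the season as configured", {
  m <- class_phenology_model(
    "perennial_grasses", 0.8, 0, 175, 0,
    secondary_peak = list(value_mean = 0.75, value_sd = 0,
                          doy_mean = 260, doy_sd = 0))
  curve <- sample_phenology_curve(m, rng_seed = 3)
  wk <- weekly_composites(pmin(pmax(curve$fn(121:296), -1), 1))
  two <- extract_two_maxima(wk)
  expect_lte(abs(two[["doy_max1"]] - 175), 7)
  expect_lte(abs(two[["doy_max2"]] - 260), 7)
  expect_lt(abs(two[["ndvi_max1"]] - 0.8), 0.05)

  # series observed only before the split: second maximum absent
  early <- rep(NA_real_, 26)
  early[1:10] <- seq(0.3, 0.8, length.out = 10)
  two_e <- extract_two_maxima(early)
  expect_true(is.na(two_e[["ndvi_max2"]]))
  expect_false(is.na(two_e[["ndvi_max1"]]))

  # split at season start degenerates to the plain maximum
  v <- runif(26)
  two_s <- extract_two_maxima(v, split_doy = 121)
  expect_equal(two_s[["ndvi_max2"]], unname(extract_max(v)[1]))
  expect_true(is.na(two_s[["ndvi_max1"]]))
})

test_that("class summaries match textbook formulas", {
  s <- class_summary(rep(0.8, 5), rep(200, 5))
  expect_equal(s$ndvi_max_hw, 0)
  expect_equal(s$var_ndvi, 0)

  x <- c(0.8, 0.85, 0.9); d <- c(190, 200, 210)
  s3 <- class_summary(x, d)
  expect_equal(s3$ndvi_max_mean, 0.85)
  expect_equal(s3$ndvi_max_hw, qt(0.975, 2) * sd(x) / sqrt(3))
  expect_equal(s3$var_ndvi, 100 * sd(x) / mean(x))
  expect_equal(s3$doy_max_mean, 200)
  expect_equal(s3$var_doy, 100 * sd(d) / 200)
  expect_error(class_summary(0.8, 200), "insufficient data")
})

test_that("a simulated cohort recovers its configured statistics", {
  m <- class_phenology_model("soybean", 0.88, 0.04, 221, 6)
  set.seed(42)
  stats <- t(replicate(200, {
    v <- sample_phenology_curve(m)$fn(121:296)
    c(max(v), (121:296)[which.max(v)])
  }))
  s <- class_summary(stats[, 1], stats[, 2])
  expect_lt(abs(s$ndvi_max_mean - 0.88), 0.01)
  expect_lt(abs(s$var_ndvi - 100 * 0.04 / 0.88), 1)
})

test_that("one-way ANOVA and Tukey HSD match closed-form identities", {
  set.seed(23)
  # null case: equal means
  null <- anova_tukey(rnorm(30, 0.8, 0.05), rep(1:3, each = 10))
  expect_gt(null$p_anova, 0.01)

  # extreme separation
  sep <- anova_tukey(c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 2)) * 1 +
                       rnorm(30, 0, 0.01) * 0,
                     rep(1:3, each = 10))
  sep <- anova_tukey(rnorm(30, rep(c(0, 1, 2), each = 10), 0.01),
                     rep(1:3, each = 10))
  expect_lt(sep$p_anova, 1e-10)
  expect_true(all(sep$pairwise$p < 0.001))

  # two-group F equals the square of the pooled t statistic
  x <- rnorm(12, 0.5, 0.1); y <- rnorm(15, 0.6, 0.1)
  gc <- anova_tukey(c(x, y), rep(c("a", "b"), c(12, 15)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(gc$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(gc$p_anova, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA and Tukey agree with stats::aov / stats::TukeyHSD", {
  set.seed(29)
  vals <- rnorm(40, rep(c(0.7, 0.75, 0.8, 0.72), each = 10), 0.05)
  grp <- factor(rep(c("y22", "y23", "y24", "y25"), each = 10))
  gc <- anova_tukey(vals, grp)
  fit <- aov(vals ~ grp)
  ref <- summary(fit)[[1]]
  expect_equal(gc$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(gc$p_anova, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  tk <- TukeyHSD(fit)$grp
  key <- paste(gc$pairwise$group2, gc$pairwise$group1, sep = "-")
  expect_equal(gc$pairwise$p, unname(tk[key, "p adj"]), tolerance = 1e-8)
})

test_that("degenerate zero-variance groups follow the documented convention", {
  eq <- anova_tukey(rep(0.5, 8), rep(1:2, each = 4))
  expect_equal(eq$p_anova, 1)
  diffm <- anova_tukey(rep(c(0.4, 0.6), each = 4), rep(1:2, each = 4))
  expect_true(is.infinite(diffm$F))
  expect_equal(diffm$p_anova, 0)
})
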