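test_that("IQR bounds follow the type-7 quartile convention", {
  tab <- data.frame(f1 = c(1, 2, 3, 4),
                    class = factor(rep("soybean", 4),
                                   levels = phenofuse:::CLASS_LEVELS),
                    field_id = 1:4, cell = 1:4)
  out <- iqr_filter(tab)
  expect_equal(unname(out$bounds$soybean[, "lower"]), -0.5)
  expect_equal(unname(out$bounds$soybean[, "upper"]), 5.5)
  expect_equal(nrow(out$table), 4)
  expect_equal(unname(out$removed["soybean"]), 0L)

  tab5 <- rbind(tab, data.frame(f1 = 100, class = "soybean",
                                field_id = 5, cell = 5))
  out5 <- iqr_filter(tab5)
  expect_equal(nrow(out5$table), 4)
  expect_false(100 %in% out5$table$f1)

  # degenerate: identical values collapse the bounds to the value
  tabd <- data.frame(f1 = c(5, 5, 5, 5, 7),
                     class = factor(rep("fallow", 5),
                                    levels = phenofuse:::CLASS_LEVELS),
                     field_id = 1:5, cell = 1:5)
  outd <- iqr_filter(tabd)
  expect_equal(outd$table$f1, rep(5, 4))

  # small classes are skipped with a warning
  tiny <- tab[1:3, ]
  expect_warning(iqr_filter(tiny), "IQR filter skipped")
})

test_that("grouped splits keep whole fields on one side", {
  tab <- toy_sample_table(n_fields_per_class = 10, cells_per_field = 4,
                          classes = "soybean")
  sp <- group_split(tab, 0.5, rng_seed = 1)
  expect_equal(length(unique(sp$test$field_id)), 5)
  expect_equal(length(unique(sp$train$field_id)), 5)

  for (seed in 1:10) {
    tab2 <- toy_sample_table(n_fields_per_class = 6,
                             cells_per_field = 3:9, seed = seed)
    sp2 <- group_split(tab2, 0.5, rng_seed = seed)
    expect_length(intersect(unique(sp2$train$field_id),
                            unique(sp2$test$field_id)), 0)
    expect_equal(sort(unique(c(sp2$train$field_id, sp2$test$field_id))),
                 sort(unique(tab2$field_id)))
  }

  single <- toy_sample_table(n_fields_per_class = 1)
  expect_error(group_split(single), "single field")
})

test_that("realized test shares stay near the target across seeds", {
  shares <- sapply(1:50, function(seed) {
    tab <- toy_sample_table(n_fields_per_class = 12, cells_per_field = 3:9,
                            seed = seed)
    sp <- group_split(tab, 0.5, rng_seed = 1000 + seed)
    sapply(levels(droplevels(tab$class)), function(cl)
      nrow(sp$test[sp$test$class == cl, ]) / nrow(tab[tab$class == cl, ]))
  })
  expect_true(all(abs(rowMeans(shares) - 0.5) < 0.02))
  expect_true(all(abs(shares - 0.5) < 0.15))
})

test_that("the forest separates separable classes and is deterministic", {
  tab <- toy_sample_table(n_fields_per_class = 6, cells_per_field = 5)
  tab$f1 <- as.numeric(tab$class %in% "soybean") * 10 + tab$f1 * 0.01
  tab$f2 <- as.numeric(tab$class %in% "buckwheat") * 10 + tab$f2 * 0.01
  model <- train_classifier(tab, rng_seed = 5)
  pred <- predict(model, tab)
  expect_equal(mean(pred$class == tab$class), 1)

  model2 <- train_classifier(tab, rng_seed = 5)
  expect_identical(predict(model2, tab)$class, pred$class)

  one <- tab[tab$class == "soybean", ]
  expect_error(train_classifier(one), "single class")
})

test_that("label-permuted data classify at chance level", {
  set.seed(77)
  n <- 600
  tab <- data.frame(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n),
                    class = factor(sample(phenofuse:::CLASS_LEVELS, n,
                                          replace = TRUE),
                                   levels = phenofuse:::CLASS_LEVELS),
                    field_id = rep(1:100, each = 6), cell = 1:n)
  sp <- group_split(tab, 0.5, rng_seed = 2)
  model <- train_classifier(sp$train, rng_seed = 3)
  rep <- evaluate(model, sp$test)
  expect_gt(rep$oa, 12)
  expect_lt(rep$oa, 28)
})

test_that("metrics from any matrix agree with brute-force counting", {
  set.seed(41)
  actual <- sample(phenofuse:::CLASS_LEVELS, 300, replace = TRUE)
  predicted <- ifelse(runif(300) < 0.7, actual,
                      sample(phenofuse:::CLASS_LEVELS, 300, replace = TRUE))
  m <- confusion_matrix(actual, predicted)
  rep <- evaluate_matrix(m)

  expect_equal(rep$oa, 100 * mean(actual == predicted))
  for (cl in phenofuse:::CLASS_LEVELS) {
    tp <- sum(actual == cl & predicted == cl)
    fp <- sum(actual != cl & predicted == cl)
    fn <- sum(actual == cl & predicted != cl)
    expect_equal(unname(rep$f1[cl]), tp / (tp + (fp + fn) / 2))
    expect_equal(sum(m[cl, ]), sum(actual == cl))
    expect_equal(sum(m[, cl]), sum(predicted == cl))
  }
  expect_equal(rep$f1_mean, mean(rep$f1))

  ident <- diag(5) * 10
  rownames(ident) <- colnames(ident) <- phenofuse:::CLASS_LEVELS
  ri <- evaluate_matrix(ident)
  expect_equal(ri$oa, 100)
  expect_equal(unname(ri$f1), rep(1, 5))
})

test_that("stratified group CV partitions fields exactly once", {
  tab <- toy_sample_table(n_fields_per_class = 3, cells_per_field = 4)
  cv <- suppressWarnings(
    stratified_group_cv(tab, k = 3, rng_seed = 9, n_trees = 10))
  expect_equal(sort(cv$assignment$field_id), sort(unique(tab$field_id)))
  expect_equal(as.integer(table(cv$assignment$fold)), rep(3L, 3))
  per_class_fold <- table(
    tab$class[match(cv$assignment$field_id, tab$field_id)],
    cv$assignment$fold)
  expect_true(all(per_class_fold[rowSums(per_class_fold) > 0, ] == 1))

  tab2 <- toy_sample_table(n_fields_per_class = 7, cells_per_field = 3:6)
  cv2 <- suppressWarnings(
    stratified_group_cv(tab2, k = 3, rng_seed = 10, n_trees = 10))
  covered <- unlist(lapply(cv2$folds, function(f)
    unique(f$predictions$field_id)))
  expect_equal(sort(covered), sort(unique(tab2$field_id)))
  expect_equal(anyDuplicated(covered), 0)
  expect_equal(sum(cv2$pooled$confusion), nrow(tab2))

  expect_error(stratified_group_cv(toy_sample_table(2), k = 3),
               "< k = 3")
})

test_that("dominant-class maps use majority, probability mass, then order", {
  pred <- data.frame(field_id = c(1, 1, 1), predicted = c("soybean",
                                                          "soybean",
                                                          "fallow"))
  expect_equal(dominant_class_map(pred)$dominant_class, "soybean")

  tie <- data.frame(field_id = c(2, 2), predicted = c("fallow", "soybean"))
  prob <- rbind(c(soybean = 0.1, fallow = 0.9),
                c(soybean = 0.6, fallow = 0.4))
  prob <- cbind(prob, grain_crops = 0, buckwheat = 0,
                perennial_grasses = 0)
  expect_equal(dominant_class_map(tie, prob)$dominant_class, "fallow")

  # no probabilities: canonical order decides
  expect_equal(dominant_class_map(tie)$dominant_class, "soybean")

  out <- dominant_class_map(pred, fields = c(1, 5))
  expect_true(is.na(out$dominant_class[out$field_id == 5]))
})
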