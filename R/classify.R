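# Classification and evaluation: sample-table construction from the
# weekly cube, per-class IQR outlier filtering, grouped train/test
# splitting, a 50-tree random forest, confusion-matrix metrics (overall
# accuracy and per-class F1), stratified group cross-validation and
# field-level dominant-class maps.

#' Build the classification sample table
#'
#' One row per labeled target cell with complete features: the
#' concatenated 26-week NDVI series of every requested sensor (26 features
#' per sensor), the class label and the field id (the leakage group).
#'
#' @param cube A `weekly_cube`.
#' @param sensors Sensors to concatenate (default all in the cube).
#' @return A `data.frame` with feature columns `<sensor>_w01..w26`,
#'   `class` (factor in canonical order), `field_id`, `cell`.
#' @export
build_sample_table <- function(cube, sensors = names(cube$sensors)) {
  stopifnot(inherits(cube, "weekly_cube"), length(sensors) >= 1)
  keep <- !is.na(cube$label)
  for (s in sensors) keep <- keep & cube$complete[, s]
  idx <- which(keep)
  feats <- do.call(cbind, lapply(sensors, function(s) {
    m <- cube$sensors[[s]][idx, , drop = FALSE]
    colnames(m) <- sprintf("%s_w%02d", s, seq_len(ncol(m)))
    m
  }))
  out <- data.frame(feats, check.names = FALSE)
  out$class <- factor(cube$label[idx], levels = CLASS_LEVELS)
  out$field_id <- cube$field_id[idx]
  out$cell <- idx
  out
}

feature_cols <- function(table) {
  setdiff(names(table), c("class", "field_id", "cell"))
}

#' Per-class IQR outlier filtering
#'
#' For each class and each feature, computes Q1, Q3 (type-7 linear
#' interpolation quantiles) and removes any row with a feature outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` for its class. Intended for the training
#' partition only. Classes with fewer than 4 rows are passed through
#' unfiltered with a warning.
#'
#' @param table A sample table (see [build_sample_table()]).
#' @return List with `table` (filtered), `removed` (per-class counts),
#'   `bounds` (per class: feature x c(lower, upper) matrices).
#' @export
iqr_filter <- function(table) {
  fc <- feature_cols(table)
  keep <- rep(TRUE, nrow(table))
  removed <- integer(0)
  bounds <- list()
  for (cl in levels(droplevels(table$class))) {
    rows <- which(table$class == cl)
    if (length(rows) < 4) {
      warning(sprintf("class '%s' has %d rows (< 4); IQR filter skipped",
                      cl, length(rows)), call. = FALSE)
      removed[cl] <- 0L
      next
    }
    x <- as.matrix(table[rows, fc, drop = FALSE])
    q <- apply(x, 2, stats::quantile, probs = c(0.25, 0.75), type = 7,
               names = FALSE)
    iqr <- q[2, ] - q[1, ]
    lower <- q[1, ] - 1.5 * iqr
    upper <- q[2, ] + 1.5 * iqr
    ok <- rowSums(sweep(x, 2, lower, "<") | sweep(x, 2, upper, ">")) == 0
    keep[rows[!ok]] <- FALSE
    removed[cl] <- sum(!ok)
    bounds[[cl]] <- cbind(lower = lower, upper = upper)
  }
  list(table = table[keep, , drop = FALSE], removed = removed,
       bounds = bounds)
}

#' Grouped train/test split
#'
#' Splits whole fields (groups) between train and test so that no field
#' appears on both sides and, per class, the realized test row share
#' approximates `test_fraction`: fields are visited in random order and
#' greedily assigned to whichever side is currently further below its
#' target share of the class's rows.
#'
#' @param table A sample table.
#' @param test_fraction Target test share of rows (default 0.5).
#' @param rng_seed Integer seed.
#' @return List with `train` and `test` tables.
#' @export
group_split <- function(table, test_fraction = 0.5, rng_seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  set.seed(rng_seed)
  test_fields <- integer(0)
  for (cl in levels(droplevels(table$class))) {
    rows <- table[table$class == cl, ]
    sizes <- table(rows$field_id)
    if (length(sizes) < 2)
      stop(sprintf("class '%s' has a single field; grouped split impossible",
                   cl), call. = FALSE)
    target <- test_fraction * sum(sizes)
    in_test <- 0
    for (f in sample(names(sizes))) {
      # take the field only if it moves the test share closer to target
      if (abs(in_test + sizes[[f]] - target) < abs(in_test - target)) {
        test_fields <- c(test_fields, as.integer(f))
        in_test <- in_test + sizes[[f]]
      }
    }
    if (in_test == 0) {  # degenerate repair: force one field into test
      f <- sample(names(sizes), 1)
      test_fields <- c(test_fields, as.integer(f))
      in_test <- sizes[[f]]
    }
    if (in_test == sum(sizes))  # keep at least one field in train
      test_fields <- setdiff(test_fields, as.integer(sample(names(sizes), 1)))
  }
  is_test <- table$field_id %in% test_fields
  list(train = table[!is_test, , drop = FALSE],
       test = table[is_test, , drop = FALSE])
}

#' Train the random-forest classifier
#'
#' A 50-tree random forest (bootstrap-aggregated axis-aligned decision
#' trees with majority vote), deterministic given the seed.
#'
#' @param train Sample table (ideally IQR-filtered).
#' @param n_trees Number of trees (default 50).
#' @param rng_seed Integer seed.
#' @return A `crop_classifier` wrapping the fitted forest.
#' @export
train_classifier <- function(train, n_trees = 50, rng_seed = 1) {
  cls <- droplevels(train$class)
  if (nlevels(cls) < 2)
    stop("training data contain a single class", call. = FALSE)
  fc <- feature_cols(train)
  fit <- ranger::ranger(
    x = train[, fc, drop = FALSE], y = cls,
    num.trees = n_trees, probability = TRUE, seed = rng_seed,
    num.threads = 1)
  structure(list(forest = fit, features = fc, levels = levels(cls),
                 n_trees = n_trees, rng_seed = rng_seed),
            class = "crop_classifier")
}

#' Predict classes (and probabilities) for a sample table
#'
#' @param object A `crop_classifier`.
#' @param newdata Sample table with the training feature columns.
#' @param ... Unused.
#' @return List with `class` (factor) and `prob` (matrix).
#' @export
predict.crop_classifier <- function(object, newdata, ...) {
  p <- stats::predict(object$forest,
                      data = newdata[, object$features, drop = FALSE],
                      num.threads = 1)$predictions
  lab <- factor(object$levels[max.col(p, ties.method = "first")],
                levels = CLASS_LEVELS)
  colnames(p) <- object$levels
  list(class = lab, prob = p)
}

#' Confusion matrix from actual/predicted labels
#'
#' Rows are actual classes, columns predicted, in the canonical class
#' order.
#'
#' @param actual,predicted Label vectors.
#' @param levels Class order (default canonical).
#' @return Integer matrix.
#' @export
confusion_matrix <- function(actual, predicted, levels = CLASS_LEVELS) {
  table(actual = factor(actual, levels = levels),
        predicted = factor(predicted, levels = levels))
}

#' Evaluation metrics from a confusion matrix
#'
#' Overall accuracy = trace/total, in percent. Per-class
#' F1 = TP / (TP + (FP + FN)/2); F1mean is the unweighted mean over
#' classes present in the matrix (classes absent from both rows and
#' columns are excluded with a warning).
#'
#' @param m Square count matrix (rows actual, columns predicted).
#' @return An `evaluation_report`: `confusion`, `oa` (percent), `f1`
#'   (per class), `f1_mean`.
#' @export
evaluate_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  f1 <- tp / (tp + (fp + fn) / 2)
  names(f1) <- rownames(m)
  present <- (rowSums(m) + colSums(m)) > 0
  if (any(!present)) {
    warning(sprintf("class(es) absent from the matrix: %s",
                    paste(rownames(m)[!present], collapse = ", ")),
            call. = FALSE)
    f1[!present] <- NA_real_
  }
  structure(list(confusion = m, oa = 100 * sum(tp) / total, f1 = f1,
                 f1_mean = mean(f1, na.rm = TRUE)),
            class = "evaluation_report")
}

#' Evaluate a classifier on a test table
#'
#' @param model A `crop_classifier`.
#' @param test Non-empty sample table.
#' @return An `evaluation_report` (with the predictions attached as
#'   `predictions`).
#' @export
evaluate <- function(model, test) {
  if (nrow(test) == 0) stop("empty test set", call. = FALSE)
  pred <- predict(model, test)
  rep <- evaluate_matrix(confusion_matrix(test$class, pred$class))
  rep$predictions <- data.frame(cell = test$cell, field_id = test$field_id,
                                actual = test$class, predicted = pred$class)
  rep$prob <- pred$prob
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  print(x$confusion)
  cat(sprintf("OA: %d%%   F1: %s   F1mean: %.2f\n", round(x$oa),
              paste(sprintf("%s %.2f", names(x$f1), x$f1), collapse = ", "),
              x$f1_mean))
  invisible(x)
}

#' Stratified group k-fold cross-validation
#'
#' Partitions fields into `k` folds so that every field lands in exactly
#' one test fold and each fold's per-class field composition approximately
#' preserves the class distribution (fields are dealt, in random order, to
#' the fold currently lightest in that class). Each fold is evaluated with
#' a forest trained on the remaining folds (IQR-filtered).
#'
#' @param table A sample table.
#' @param k Number of folds (default 3).
#' @param rng_seed Integer seed.
#' @param n_trees Trees per forest.
#' @return List with `folds` (per-fold `evaluation_report`s),
#'   `assignment` (field -> fold), `pooled` (report over the pooled
#'   confusion matrix).
#' @export
stratified_group_cv <- function(table, k = 3, rng_seed = 1, n_trees = 50) {
  set.seed(rng_seed)
  assignment <- integer(0)
  for (cl in levels(droplevels(table$class))) {
    rows <- table[table$class == cl, ]
    sizes <- table(rows$field_id)
    if (length(sizes) < k)
      stop(sprintf("class '%s' has %d fields < k = %d folds",
                   cl, length(sizes), k), call. = FALSE)
    load <- numeric(k)
    for (f in sample(names(sizes), length(sizes))) {
      fold <- which.min(load)
      load[fold] <- load[fold] + sizes[[f]]
      assignment[f] <- fold
    }
  }
  folds <- vector("list", k)
  pooled <- NULL
  for (fold in seq_len(k)) {
    test_ids <- as.integer(names(assignment)[assignment == fold])
    is_test <- table$field_id %in% test_ids
    train <- iqr_filter(table[!is_test, , drop = FALSE])$table
    model <- train_classifier(train, n_trees = n_trees,
                              rng_seed = rng_seed + fold)
    folds[[fold]] <- evaluate(model, table[is_test, , drop = FALSE])
    pooled <- if (is.null(pooled)) folds[[fold]]$confusion
    else pooled + folds[[fold]]$confusion
  }
  list(folds = folds,
       assignment = data.frame(field_id = as.integer(names(assignment)),
                               fold = unname(assignment)),
       pooled = evaluate_matrix(pooled))
}

#' Field-level dominant-class map
#'
#' Assigns each field the modal predicted class of its cells; ties are
#' broken by total predicted-probability mass, then by canonical class
#' order. Fields with no covered cells are flagged unclassified (`NA`).
#'
#' @param predictions `data.frame` with `field_id` and `predicted`
#'   (e.g. an `evaluation_report$predictions`).
#' @param prob Optional probability matrix aligned with `predictions`.
#' @param fields Optional vector of all field ids (uncovered ones are
#'   reported `NA`).
#' @return `data.frame` with `field_id` and `dominant_class`.
#' @export
dominant_class_map <- function(predictions, prob = NULL, fields = NULL) {
  ids <- unique(predictions$field_id)
  pick <- vapply(ids, function(f) {
    sel <- predictions$field_id == f
    counts <- table(factor(predictions$predicted[sel],
                           levels = CLASS_LEVELS))
    top <- which(counts == max(counts))
    if (length(top) > 1 && !is.null(prob)) {
      mass <- colSums(prob[sel, , drop = FALSE])
      mass <- mass[match(CLASS_LEVELS[top], names(mass))]
      mass[is.na(mass)] <- 0
      top <- top[order(-mass)]
    }
    CLASS_LEVELS[top[1]]
  }, character(1))
  out <- data.frame(field_id = ids, dominant_class = pick)
  if (!is.null(fields)) {
    missing <- setdiff(fields, ids)
    if (length(missing))
      out <- rbind(out, data.frame(field_id = missing,
                                   dominant_class = NA_character_))
    out <- out[order(out$field_id), ]
  }
  out
}
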