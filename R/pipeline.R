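# End-to-end driver: simulate -> mask -> fit -> harmonize -> features ->
# classify -> evaluate -> map, reproducible from (config, seed) alone.

#' Default pipeline configuration
#'
#' Bundles the landscape, sensor models and analysis settings of the
#' default synthetic study.
#'
#' @param landscape See [default_landscape_config()].
#' @param sensors See [default_sensor_models()].
#' @param min_obs Minimum valid observations per fitted pixel (default 6,
#'   the identifiability floor of the six-parameter series; pixels below
#'   it are excluded and counted). Sparse-revisit sensors in cloudy
#'   seasons sit near this limit, so a stricter floor silently removes
#'   most of their grid.
#' @param test_fraction Grouped-split test share.
#' @param cv_folds Stratified group CV folds.
#' @param n_trees Random-forest size.
#' @return Configuration list for [run_pipeline()].
#' @export
default_pipeline_config <- function(landscape = default_landscape_config(),
                                    sensors = default_sensor_models(),
                                    min_obs = 6, test_fraction = 0.5,
                                    cv_folds = 3, n_trees = 50) {
  list(landscape = landscape, sensors = sensors, min_obs = min_obs,
       test_fraction = test_fraction, cv_folds = cv_folds,
       n_trees = n_trees)
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 101 + k * 9973) %% 2147483647)
}

#' Run the multi-sensor classification pipeline
#'
#' Executes the full chain on a synthetic landscape: scene simulation per
#' sensor, quality masking, per-pixel Fourier fitting (Meteor: windowed
#' daily composites), weekly compositing, bilinear harmonization onto the
#' common 60 m grid, cube assembly, grouped 50/50 train/test evaluation
#' and stratified group cross-validation for each single-sensor feature
#' set and the combined multi-sensor set, and the field-level
#' dominant-class map from the multi-sensor predictions. When `cache_dir`
#' is given, completed stages are reloaded from cache on rerun (keyed by
#' seed), skipping recomputation.
#'
#' @param config See [default_pipeline_config()].
#' @param seed Integer seed; all randomized stages derive their seeds
#'   from it.
#' @param feature_sets Named list of sensor combinations to classify
#'   (default: each sensor alone plus all combined).
#' @param run_cv Whether to run cross-validation (default TRUE).
#' @param cache_dir Optional directory for stage caching.
#' @param verbose Print one progress line per stage.
#' @return A list: `landscape`, `cube`, `cloud_tally`, `phenology`,
#'   `split_reports`, `cv_reports`, `crop_map`, `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = 1,
                         feature_sets = NULL, run_cv = TRUE,
                         cache_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  cached <- function(name, expr) {
    if (is.null(cache_dir)) return(expr)
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(cache_dir, sprintf("%s_seed%d.rds", name, seed))
    if (file.exists(f)) { say("stage %s: cached", name); return(readRDS(f)) }
    out <- expr
    saveRDS(out, f)
    out
  }
  sensors <- config$sensors
  if (is.null(feature_sets)) {
    feature_sets <- c(as.list(stats::setNames(names(sensors), names(sensors))),
                      list(multi = names(sensors)))
  }

  say("stage simulate: landscape")
  landscape <- cached("landscape",
                      simulate_landscape(config$landscape,
                                         derive_seed(seed, 0)))
  counts <- list(fields = length(landscape$fields$id),
                 labeled_cells = sum(!is.na(landscape$label)))

  layers <- list(); tally <- list(); excluded <- list()
  for (i in seq_along(sensors)) {
    nm <- names(sensors)[i]
    layers[[nm]] <- cached(paste0("weekly_", nm), {
      say("stage simulate/mask/fit: %s", nm)
      stack <- generate_scene_stack(landscape, sensors[[nm]],
                                    derive_seed(seed, i))
      obs <- stack_observations(stack)
      tally_i <- cloud_bin_tally(vapply(stack$scenes,
                                        function(s) s$cloud_fraction,
                                        numeric(1)))
      fid <- expand_to_native(landscape$field_id, stack$factor)
      px <- which(!is.na(as.vector(fid)))
      fitted <- if (nm == "meteor") meteor_stack_weekly(obs, px)
      else fit_stack_weekly(obs, px, min_obs = config$min_obs)
      list(weekly = resample_weekly(fitted$weekly, stack$grid,
                                    landscape$grid),
           tally = tally_i, n_fitted = fitted$n_fitted,
           n_excluded = fitted$n_excluded)
    })
    tally[[nm]] <- layers[[nm]]$tally
    excluded[[nm]] <- layers[[nm]]$n_excluded
    layers[[nm]] <- layers[[nm]]$weekly
  }

  say("stage harmonize: cube")
  cube <- assemble_cube(layers, landscape$grid, landscape$label,
                        landscape$field_id)

  say("stage features: phenology")
  phen <- lapply(names(sensors), function(nm)
    field_phenology(cube, nm, landscape$field_table,
                    resolution = if (nm == "meteor") "weekly" else "daily"))
  names(phen) <- names(sensors)

  split_reports <- list(); cv_reports <- list(); crop_map <- NULL
  for (fs in names(feature_sets)) {
    say("stage classify: %s", fs)
    tab <- build_sample_table(cube, feature_sets[[fs]])
    if (nrow(tab) == 0) {
      warning(sprintf("feature set '%s': no complete cells", fs),
              call. = FALSE)
      next
    }
    res <- tryCatch({
      sp <- group_split(tab, config$test_fraction, derive_seed(seed, 100))
      train <- iqr_filter(sp$train)$table
      model <- train_classifier(train, config$n_trees,
                                derive_seed(seed, 101))
      evaluate(model, sp$test)
    }, error = function(e) {
      warning(sprintf("feature set '%s': split evaluation skipped (%s)",
                      fs, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(res)) next
    split_reports[[fs]] <- res
    if (run_cv)
      cv_reports[[fs]] <- tryCatch(
        stratified_group_cv(tab, config$cv_folds, derive_seed(seed, 102),
                            config$n_trees),
        error = function(e) {
          warning(sprintf("feature set '%s': CV skipped (%s)", fs,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
    if (fs == "multi")
      crop_map <- dominant_class_map(split_reports[[fs]]$predictions,
                                     split_reports[[fs]]$prob,
                                     landscape$fields$id)
  }

  manifest <- list(
    seed = seed,
    config_digest = config_digest(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    n_fields = counts$fields,
    n_labeled_cells = counts$labeled_cells,
    scenes = lapply(tally, as.list),
    pixels_excluded = excluded,
    feature_sets = lapply(feature_sets, paste, collapse = "+"))

  list(landscape = landscape, cube = cube, cloud_tally = tally,
       phenology = phen, split_reports = split_reports,
       cv_reports = cv_reports, crop_map = crop_map, manifest = manifest)
}

# Order-independent digest of the config (no external digest package:
# sum of character codes of the deparsed object).
config_digest <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "sensors")]),
               collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %%
            .Machine$integer.max)
}
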