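# Stack-level processing: masked NDVI assembly per scene, per-pixel
# Fourier fitting to weekly layers, bilinear harmonization of all sensors
# onto the common target grid, and weekly-cube assembly.

#' Masked NDVI observations of a scene stack
#'
#' Runs the masking module over every scene (SCL rules for Sentinel,
#' QA_PIXEL equality for Landsat, no-data only for Meteor), computes NDVI
#' from the reflectance pair where needed, and propagates masked pixels as
#' missing values.
#'
#' @param stack A `scene_stack`.
#' @return List with `ndvi` (matrix: scenes x pixels, `NA` = masked),
#'   `dates`, `masks` (per-scene `validity_mask`), `grid`.
#' @export
stack_observations <- function(stack) {
  npx <- stack$grid$nrow * stack$grid$ncol
  obs <- matrix(NA_real_, length(stack$scenes), npx)
  masks <- vector("list", length(stack$scenes))
  for (s in seq_along(stack$scenes)) {
    sc <- stack$scenes[[s]]
    if (!is.null(sc$ndvi)) {
      m <- meteor_validity(sc$ndvi, doy = sc$doy)
      v <- sc$ndvi
    } else {
      v <- compute_ndvi(sc$nir, sc$red)
      m <- if (!is.null(sc$scl)) sentinel_validity(sc$scl, doy = sc$doy)
      else landsat_validity(sc$qa, doy = sc$doy)
    }
    obs[s, ] <- as.vector(apply_mask(v, m))
    masks[[s]] <- m
  }
  list(ndvi = obs, dates = stack$dates, masks = masks, grid = stack$grid)
}

#' Per-pixel Fourier fitting of a stack to weekly layers
#'
#' Fits the truncated Fourier series independently to every requested
#' pixel's gapped NDVI series and reduces the daily reconstruction to the
#' 26-anchor weekly grid. Pixels with fewer than `min_obs` valid
#' observations (or non-converged fits) are excluded and counted.
#'
#' @param obs Result of [stack_observations()].
#' @param pixels Integer vector of pixel indices (column-major) to fit;
#'   default all.
#' @param min_obs Minimum valid observations per pixel (default 8).
#' @return List with `weekly` (pixels-kept x 26 matrix, `NA` rows for
#'   excluded pixels), `n_fitted`, `n_excluded`, `excluded` (indices).
#' @export
fit_stack_weekly <- function(obs, pixels = NULL, min_obs = 8) {
  npx <- ncol(obs$ndvi)
  if (is.null(pixels)) pixels <- seq_len(npx)
  weekly <- matrix(NA_real_, npx, length(weekly_anchors()))
  t_all <- as.numeric(obs$dates)
  excluded <- integer(0)
  win <- weekly_window_index()
  for (p in pixels) {
    y <- obs$ndvi[, p]
    ok <- is.finite(y)
    if (sum(ok) < min_obs) { excluded <- c(excluded, p); next }
    fit <- fit_fourier(t_all[ok], y[ok], min_obs = min_obs)
    if (!fit$converged) { excluded <- c(excluded, p); next }
    daily <- reconstruct_daily(fit)
    weekly[p, ] <- vapply(win, function(ix) mean(daily[ix]), numeric(1))
  }
  list(weekly = weekly, n_fitted = length(pixels) - length(excluded),
       n_excluded = length(excluded), excluded = excluded)
}

weekly_window_index <- function() {
  lapply(weekly_anchors(), function(a)
    which(SEASON_DOY >= a & SEASON_DOY <= min(a + 6, 296)))
}

#' Weekly layers from Meteor daily composites
#'
#' Applies [meteor_weekly()] per pixel over the stack's daily NDVI
#' observations.
#'
#' @inheritParams fit_stack_weekly
#' @return Same shape as [fit_stack_weekly()].
#' @export
meteor_stack_weekly <- function(obs, pixels = NULL) {
  npx <- ncol(obs$ndvi)
  if (is.null(pixels)) pixels <- seq_len(npx)
  weekly <- matrix(NA_real_, npx, length(weekly_anchors()))
  excluded <- integer(0)
  for (p in pixels) {
    y <- obs$ndvi[, p]
    if (!any(is.finite(y))) { excluded <- c(excluded, p); next }
    weekly[p, ] <- meteor_weekly(obs$dates, y)
  }
  list(weekly = weekly, n_fitted = length(pixels) - length(excluded),
       n_excluded = length(excluded), excluded = excluded)
}

#' Resample weekly layers onto the target grid
#'
#' Bilinearly resamples each of the 26 weekly layers from the sensor's
#' native grid to the common target grid.
#'
#' @param weekly Pixels x 26 matrix on the native grid (column-major).
#' @param src,target `grid_spec`s.
#' @return Cells x 26 matrix on the target grid.
#' @export
resample_weekly <- function(weekly, src, target) {
  out <- matrix(NA_real_, target$nrow * target$ncol, ncol(weekly))
  for (k in seq_len(ncol(weekly))) {
    m <- matrix(weekly[, k], src$nrow, src$ncol)
    out[, k] <- as.vector(resample_bilinear(m, src, target))
  }
  out
}

#' Assemble the harmonized weekly cube
#'
#' Combines per-sensor weekly layers (already on the target grid) with the
#' ground-truth labels into the classifier's input: for every target cell,
#' 26 weekly NDVI values per sensor. Cells missing any sensor-week value
#' are flagged per sensor; only labeled cells are retained downstream.
#'
#' @param layers Named list (sensor -> cells x 26 matrix on the target
#'   grid).
#' @param grid Target `grid_spec`.
#' @param label Character matrix (or vector) of cell labels, `NA` =
#'   background.
#' @param field_id Integer matrix (or vector) of field ids.
#' @return A `weekly_cube`: `grid`, `anchors`, `sensors` (matrices),
#'   `complete` (cell x sensor logical), `label`, `field_id`.
#' @export
assemble_cube <- function(layers, grid, label, field_id) {
  ncell <- grid$nrow * grid$ncol
  for (nm in names(layers)) {
    if (nrow(layers[[nm]]) != ncell)
      stop(sprintf("layer '%s' does not match the target grid", nm),
           call. = FALSE)
    if (ncol(layers[[nm]]) != length(weekly_anchors()))
      stop(sprintf("layer '%s': anchor mismatch (expected %d weeks)",
                   nm, length(weekly_anchors())), call. = FALSE)
  }
  complete <- vapply(layers, function(m) rowSums(is.na(m)) == 0,
                     logical(ncell))
  structure(list(grid = grid, anchors = weekly_anchors(), sensors = layers,
                 complete = complete, label = as.vector(label),
                 field_id = as.vector(field_id)),
            class = "weekly_cube")
}

#' @export
print.weekly_cube <- function(x, ...) {
  cat(sprintf("weekly_cube: %d cells x %d weeks x %d sensors (%s)\n",
              x$grid$nrow * x$grid$ncol, length(x$anchors),
              length(x$sensors), paste(names(x$sensors), collapse = ", ")))
  cat(sprintf("  labeled cells: %d\n", sum(!is.na(x$label))))
  invisible(x)
}
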