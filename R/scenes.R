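# Synthetic multi-sensor scene generation: acquisition schedules,
# spatially coherent cloud masks, encoded quality layers, and per-scene
# reflectance/NDVI grids on each sensor's native grid.

#' Sensor model
#'
#' Acquisition and radiometric characteristics of one sensor: native
#' resolution, number of scenes per season, additive NDVI bias, seasonal
#' peak shift in days (negative = earlier), per-observation Gaussian noise
#' sd, and the categorical distribution of per-scene masked-pixel
#' fractions over the four reporting bins.
#'
#' @param sensor_id `"sentinel"`, `"landsat"` or `"meteor"`.
#' @param native_resolution Meters (20/30/60).
#' @param scenes_per_season Scene count (>= 1).
#' @param additive_bias NDVI offset added to every observation.
#' @param peak_shift Days; negative shifts the observed season earlier.
#' @param noise_sd Per-observation NDVI noise sd (>= 0).
#' @param mask_fraction_distribution Probabilities over the bins
#'   `<5, 5-20, 20-50, >50` (must sum to 1), or `NULL` for a sensor whose
#'   delivered product carries no cloud mask (Meteor).
#' @return A `sensor_model`.
#' @export
sensor_model <- function(sensor_id, native_resolution, scenes_per_season,
                         additive_bias = 0, peak_shift = 0, noise_sd = 0.02,
                         mask_fraction_distribution = NULL) {
  stopifnot(sensor_id %in% c("sentinel", "landsat", "meteor"),
            native_resolution > 0, scenes_per_season >= 1, noise_sd >= 0)
  if (!is.null(mask_fraction_distribution)) {
    stopifnot(length(mask_fraction_distribution) == 4,
              abs(sum(mask_fraction_distribution) - 1) < 1e-9)
  }
  structure(list(sensor_id = sensor_id,
                 native_resolution = native_resolution,
                 scenes_per_season = scenes_per_season,
                 additive_bias = additive_bias, peak_shift = peak_shift,
                 noise_sd = noise_sd,
                 mask_fraction_distribution = mask_fraction_distribution),
            class = "sensor_model")
}

#' Default sensor models
#'
#' Three-sensor configuration of the default synthetic scene, 2022
#' conditions: Sentinel at 20 m, 61 scenes (roughly every 3 days with
#' jitter), masked-fraction bin counts 8/5/11/37 of 61; Landsat at 30 m,
#' 15 scenes (every 11-12 days), bins 2/1/5/7 of 15; Meteor at 60 m as
#' daily NDVI composites over DOY 122-269 with no quality layer, an
#' additive bias of -0.06 NDVI and a peak shift of -15 days (the
#' provider-side smoothing lowers and advances the observed maxima).
#'
#' @return Named list of `sensor_model` objects.
#' @export
default_sensor_models <- function() {
  list(
    sentinel = sensor_model("sentinel", 20, 61,
                            mask_fraction_distribution = c(8, 5, 11, 37) / 61),
    landsat = sensor_model("landsat", 30, 15,
                           mask_fraction_distribution = c(2, 1, 5, 7) / 15),
    meteor = sensor_model("meteor", 60, 148, additive_bias = -0.06,
                          peak_shift = -15, noise_sd = 0.01)
  )
}

#' Acquisition schedule
#'
#' `n` strictly increasing integer days of year between `start` and `end`,
#' evenly spaced with Gaussian jitter.
#'
#' @param n Number of scenes.
#' @param start,end Season limits (days of year).
#' @param jitter_sd Jitter sd in days (0 = regular).
#' @return Integer vector of length `n`.
#' @export
make_schedule <- function(n, start, end, jitter_sd = 1) {
  stopifnot(n >= 1, end - start + 1 >= n)
  if (n == 1) return(as.integer(round((start + end) / 2)))
  d <- round(sort(seq(start, end, length.out = n) +
                    stats::rnorm(n, 0, jitter_sd)))
  for (i in 2:n) if (d[i] <= d[i - 1]) d[i] <- d[i - 1] + 1
  for (i in (n - 1):1) if (d[i + 1] > end - (n - 1 - i)) {
    d[i + 1] <- end - (n - 1 - i)
    if (d[i] >= d[i + 1]) d[i] <- d[i + 1] - 1
  }
  d <- pmax(d, start)
  as.integer(d)
}

# Spatially coherent cloud mask: threshold a bilinearly upsampled coarse
# Gaussian noise field at the quantile giving exactly the requested
# masked-pixel count. Returns TRUE = cloudy.
cloud_field <- function(g, fraction, block_cells = 8) {
  n <- g$nrow * g$ncol
  k <- round(fraction * n)
  if (k <= 0) return(matrix(FALSE, g$nrow, g$ncol))
  if (k >= n) return(matrix(TRUE, g$nrow, g$ncol))
  cpx <- g$px * block_cells
  cnr <- ceiling(g$nrow / block_cells) + 2
  cnc <- ceiling(g$ncol / block_cells) + 2
  cg <- grid_spec(g$xmin - cpx, g$ymax + cpx, cpx, cnr, cnc)
  coarse <- matrix(stats::rnorm(cnr * cnc), cnr, cnc)
  smooth <- resample_bilinear(coarse, cg, g)
  thr <- sort(smooth)[k]
  smooth <= thr
}

draw_mask_fraction <- function(probs) {
  bin <- sample.int(4, 1, prob = probs)
  lo <- c(0, 0.05, 0.20, 0.50)[bin]
  hi <- c(0.05, 0.20, 0.50, 0.98)[bin]
  list(bin = CLOUD_BINS[bin], fraction = stats::runif(1, lo, hi))
}

encode_scl <- function(cloudy) {
  n <- length(cloudy)
  codes <- integer(n)
  codes[!cloudy] <- sample(c(4L, 5L, 6L, 2L, 7L), sum(!cloudy),
                           replace = TRUE,
                           prob = c(0.7, 0.15, 0.05, 0.05, 0.05))
  codes[cloudy] <- sample(c(3L, 8L, 9L, 10L, 0L, 1L, 11L), sum(cloudy),
                          replace = TRUE,
                          prob = c(0.2, 0.3, 0.3, 0.1, 0.03, 0.03, 0.04))
  dim(codes) <- dim(cloudy)
  codes
}

encode_qa <- function(cloudy) {
  n <- length(cloudy)
  qa <- integer(n)
  qa[!cloudy] <- LANDSAT_CLEAR_QA
  qa[cloudy] <- sample(c(21826L, 22080L, 23888L, 21890L, 1L), sum(cloudy),
                       replace = TRUE)
  dim(qa) <- dim(cloudy)
  qa
}

# Expand a coarse (target-grid) matrix to a nested finer grid by block
# replication (each coarse cell covers factor x factor native cells).
expand_to_native <- function(m, factor) {
  if (factor == 1) return(m)
  m[rep(seq_len(nrow(m)), each = factor),
    rep(seq_len(ncol(m)), each = factor)]
}

native_grid <- function(landscape_grid, coarse_res_m, sensor_res_m) {
  factor <- coarse_res_m / sensor_res_m
  if (abs(factor - round(factor)) > 1e-9)
    stop("sensor resolution must divide the landscape resolution",
         call. = FALSE)
  factor <- as.integer(round(factor))
  list(grid = grid_spec(landscape_grid$xmin, landscape_grid$ymax,
                        landscape_grid$px / factor,
                        landscape_grid$nrow * factor,
                        landscape_grid$ncol * factor),
       factor = factor)
}

#' Generate a synthetic scene stack for one sensor
#'
#' Simulates the sensor's full season over the landscape: each scheduled
#' date yields one scene on the sensor's native grid. Pixel values are the
#' field's seasonal curve at the (peak-shifted) acquisition day, plus the
#' within-field spatial offset, the sensor's additive bias and Gaussian
#' observation noise, clipped to `[-1, 1]`. Sentinel and Landsat scenes are
#' emitted as a NIR/RED reflectance pair plus an encoded quality grid (SCL
#' codes / QA_PIXEL integers) whose cloud pattern is a spatially coherent
#' field with the per-scene masked fraction drawn from the sensor's bin
#' distribution; Meteor scenes are delivered NDVI composites with no
#' quality layer.
#'
#' @param landscape A `simulated_landscape`.
#' @param sensor A `sensor_model`.
#' @param rng_seed Integer seed.
#' @param schedule Optional explicit integer DOY schedule (default: Meteor
#'   daily DOY 122-269; otherwise jittered-regular over DOY 122-295).
#' @return A `scene_stack`: `sensor`, native `grid`, `dates`, and `scenes`
#'   (per date: `nir`/`red` + `scl`|`qa`, or `ndvi`; plus the drawn
#'   `cloud_fraction` and `cloud_bin`).
#' @export
generate_scene_stack <- function(landscape, sensor, rng_seed = 1,
                                 schedule = NULL) {
  stopifnot(inherits(landscape, "simulated_landscape"),
            inherits(sensor, "sensor_model"))
  set.seed(rng_seed)
  if (is.null(schedule)) {
    schedule <- if (sensor$sensor_id == "meteor") 122:269
    else make_schedule(sensor$scenes_per_season, 122, 295)
  }
  if (length(schedule) == 0) stop("empty acquisition schedule", call. = FALSE)

  ng <- native_grid(landscape$grid, landscape$config$resolution_m,
                    sensor$native_resolution)
  g <- ng$grid
  fid <- expand_to_native(landscape$field_id, ng$factor)
  offs <- expand_to_native(landscape$offset, ng$factor)
  field_px <- split(seq_along(fid), as.vector(fid))
  npx <- g$nrow * g$ncol
  bg <- landscape$config$background_ndvi

  scenes <- vector("list", length(schedule))
  for (s in seq_along(schedule)) {
    doy <- schedule[s]
    v <- rep(bg, npx)
    doy_eff <- doy - sensor$peak_shift
    for (nm in names(field_px)) {
      k <- as.integer(nm)
      v[field_px[[nm]]] <- landscape$curves[[k]]$fn(doy_eff)
    }
    v <- v + as.vector(offs) + sensor$additive_bias
    if (sensor$noise_sd > 0) v <- v + stats::rnorm(npx, 0, sensor$noise_sd)
    v <- pmin(pmax(v, -1), 1)
    dim(v) <- c(g$nrow, g$ncol)

    if (sensor$sensor_id == "meteor") {
      scenes[[s]] <- list(doy = doy, ndvi = v, cloud_fraction = 0,
                          cloud_bin = "<5")
    } else {
      drawn <- if (is.null(sensor$mask_fraction_distribution))
        list(bin = "<5", fraction = 0)  # cloud-free configuration
      else draw_mask_fraction(sensor$mask_fraction_distribution)
      cloudy <- cloud_field(g, drawn$fraction)
      scale <- 0.5
      scene <- list(doy = doy,
                    nir = scale * (1 + v) / 2,
                    red = scale * (1 - v) / 2,
                    cloud_fraction = sum(cloudy) / npx,
                    cloud_bin = drawn$bin)
      if (sensor$sensor_id == "sentinel") scene$scl <- encode_scl(cloudy)
      else scene$qa <- encode_qa(cloudy)
      scenes[[s]] <- scene
    }
  }
  structure(list(sensor = sensor, grid = g, factor = ng$factor,
                 dates = as.integer(schedule), scenes = scenes,
                 rng_seed = rng_seed),
            class = "scene_stack")
}

#' @export
print.scene_stack <- function(x, ...) {
  cat(sprintf("scene_stack [%s]: %d scenes, %d x %d at %g m\n",
              x$sensor$sensor_id, length(x$scenes), x$grid$nrow,
              x$grid$ncol, x$sensor$native_resolution))
  invisible(x)
}
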