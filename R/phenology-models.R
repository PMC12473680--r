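# Class-specific seasonal NDVI curve models for the synthetic landscape.
# Calibration: per-class seasonal maxima and their timing (means and
# coefficients of variation) for the 2022 season of the study region;
# perennial grasses are bimodal (early-summer mowing peak plus an
# early-autumn regrowth peak).

CLASS_LEVELS <- c("soybean", "grain_crops", "buckwheat",
                  "perennial_grasses", "fallow")

#' Class phenology model
#'
#' Describes the distribution of a crop class's seasonal NDVI curve:
#' the seasonal maximum (mean and between-field sd, NDVI units), its day
#' of year (mean and sd, days), the off-season baseline, an optional
#' secondary peak for bimodal classes, and the curve family.
#'
#' @param class_label One of soybean, grain_crops, buckwheat,
#'   perennial_grasses, fallow.
#' @param peak_value_mean,peak_value_sd Seasonal NDVI maximum, in (0, 1].
#' @param peak_doy_mean,peak_doy_sd Day of the maximum, within the season.
#' @param baseline NDVI at season start/end (default 0.2, bare/senescent).
#' @param secondary_peak Optional list
#'   `(value_mean, value_sd, doy_mean, doy_sd)`; its `doy_mean` must lie
#'   after the primary peak.
#' @param curve_family `"fourier"` (default; exactly representable by the
#'   fitting basis), `"double_logistic"`, or `"bimodal_mixture"` (implied
#'   when `secondary_peak` is given).
#' @param period_days Fundamental period of the fourier family (days);
#'   controls seasonal curve width — long periods give broad plateaus,
#'   short ones narrow peaks.
#' @param shape Second-harmonic fraction of the fourier family
#'   (`[0, 0.25)`); higher values sharpen the peak.
#' @return A `class_phenology_model`.
#' @export
class_phenology_model <- function(class_label, peak_value_mean,
                                  peak_value_sd, peak_doy_mean, peak_doy_sd,
                                  baseline = 0.2, secondary_peak = NULL,
                                  curve_family = c("fourier",
                                                   "double_logistic",
                                                   "bimodal_mixture"),
                                  period_days = 368, shape = 0.2) {
  if (!class_label %in% CLASS_LEVELS)
    stop(sprintf("invalid class label '%s' (expected one of %s)",
                 class_label, paste(CLASS_LEVELS, collapse = ", ")),
         call. = FALSE)
  curve_family <- match.arg(curve_family)
  stopifnot(peak_value_mean > 0, peak_value_mean <= 1,
            peak_doy_mean >= 121, peak_doy_mean <= 296,
            peak_value_sd >= 0, peak_doy_sd >= 0,
            baseline >= 0, baseline < peak_value_mean)
  if (!is.null(secondary_peak)) {
    stopifnot(secondary_peak$doy_mean > peak_doy_mean)
    curve_family <- "bimodal_mixture"
  }
  stopifnot(period_days >= 125, period_days <= 790, shape >= 0,
            shape < 0.25)
  structure(list(class_label = class_label,
                 peak_value_mean = peak_value_mean,
                 peak_value_sd = peak_value_sd,
                 peak_doy_mean = peak_doy_mean, peak_doy_sd = peak_doy_sd,
                 baseline = baseline, secondary_peak = secondary_peak,
                 curve_family = curve_family, period_days = period_days,
                 shape = shape),
            class = "class_phenology_model")
}

#' Default class phenology models
#'
#' The five-class calibration used by the default synthetic landscape:
#' means and between-field coefficients of variation of the seasonal NDVI
#' maximum and its timing for the 2022 season, with class-specific curve
#' widths reflecting the reference-curve shapes — soybean a narrow late
#' season (late sowing), grain crops an early peak followed by harvest
#' decline, buckwheat a sharp mid-summer peak, fallow a broad plateau.
#' Perennial grasses carry a secondary (regrowth) peak and are generated
#' as a bimodal mixture.
#'
#' @return Named list of `class_phenology_model` objects.
#' @export
default_class_models <- function() {
  cv <- function(m, pct) m * pct / 100
  list(
    soybean = class_phenology_model(
      "soybean", 0.88, cv(0.88, 4.89), 220.8, cv(220.8, 2.88),
      period_days = 330, shape = 0.20),
    grain_crops = class_phenology_model(
      "grain_crops", 0.77, cv(0.77, 5.09), 192.0, cv(192.0, 14.79),
      period_days = 300, shape = 0.15),
    buckwheat = class_phenology_model(
      "buckwheat", 0.88, cv(0.88, 3.87), 195.7, cv(195.7, 1.85),
      period_days = 240, shape = 0.22),
    perennial_grasses = class_phenology_model(
      "perennial_grasses", 0.81, cv(0.81, 7.0), 174.0, cv(174.0, 5.9),
      secondary_peak = list(value_mean = 0.78, value_sd = cv(0.78, 12.0),
                            doy_mean = 264.7, doy_sd = cv(264.7, 3.2))),
    fallow = class_phenology_model(
      "fallow", 0.84, cv(0.84, 5.78), 190.9, cv(190.9, 5.62),
      period_days = 520, shape = 0.05)
  )
}

#' Fourier parameters of a single-peak seasonal curve
#'
#' Constructs a curve in the two-term Fourier basis with its unique
#' in-season maximum `peak_value` at `peak_doy` and value `baseline` at the
#' season edge farthest from the peak. The second harmonic's relative
#' amplitude `shape` (in `[0, 0.25)`) sharpens the peak; below 0.25 the
#' derivative `-Aw sin(u) (1 + 4 shape cos(u))` has no spurious zero, so
#' the maximum at the peak day is guaranteed.
#'
#' @param peak_value,peak_doy Seasonal maximum and its day.
#' @param baseline Edge NDVI.
#' @param shape Second-harmonic fraction (default 0.2).
#' @param w Angular frequency (default one cycle per 368 days).
#' @return Named parameter vector for [fourier_eval()].
#' @export
fourier_curve_params <- function(peak_value, peak_doy, baseline = 0.2,
                                 shape = 0.2, w = W_INIT) {
  stopifnot(shape >= 0, shape < 0.25)
  edge <- if (abs(121 - peak_doy) > abs(296 - peak_doy)) 121 else 296
  d <- w * (edge - peak_doy)
  A <- (peak_value - baseline) /
    ((1 + shape) - (cos(d) + shape * cos(2 * d)))
  a0 <- peak_value - A * (1 + shape)
  # A cos(w(t - D)) + shape A cos(2w(t - D)) expanded into the basis
  c(w = w,
    a0 = a0,
    a1 = A * cos(w * peak_doy),
    b1 = A * sin(w * peak_doy),
    a2 = shape * A * cos(2 * w * peak_doy),
    b2 = shape * A * sin(2 * w * peak_doy))
}

# rnorm truncated to mean +/- 4 sd and an absolute range
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  lo <- pmax(lo, mean - 4 * sd); hi <- pmin(hi, mean + 4 * sd)
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Sample a seasonal NDVI curve from a class model
#'
#' Draws a field-level seasonal curve: the peak value and peak day are
#' sampled from truncated normals (mean +/- 4 sd, clipped to the NDVI
#' domain and the season), then a continuous DOY -> NDVI function of the
#' model's curve family is built through them. Deterministic given the
#' RNG state/seed.
#'
#' @param model A `class_phenology_model`.
#' @param rng_seed Optional integer seed; if `NULL` the current RNG state
#'   is used (for drawing many curves in sequence).
#' @return List with `fn` (vectorized DOY -> NDVI function), `family`,
#'   sampled `peak_value`, `peak_doy`, and `par` (Fourier parameters, for
#'   the fourier family only).
#' @export
sample_phenology_curve <- function(model, rng_seed = NULL) {
  stopifnot(inherits(model, "class_phenology_model"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  v <- rnorm_trunc(1, model$peak_value_mean, model$peak_value_sd,
                   lo = model$baseline + 0.02, hi = 1)
  d <- rnorm_trunc(1, model$peak_doy_mean, model$peak_doy_sd,
                   lo = 123, hi = 294)
  B <- model$baseline
  if (model$curve_family == "fourier") {
    par <- fourier_curve_params(v, d, B, shape = model$shape,
                                w = 2 * pi / model$period_days)
    return(list(fn = function(t) fourier_eval(par, t), family = "fourier",
                peak_value = v, peak_doy = d, par = par))
  }
  if (model$curve_family == "bimodal_mixture") {
    sp <- model$secondary_peak
    v2 <- rnorm_trunc(1, sp$value_mean, sp$value_sd, lo = B + 0.02, hi = 1)
    d2 <- rnorm_trunc(1, sp$doy_mean, sp$doy_sd, lo = d + 20, hi = 294)
    width <- 20
    fn <- function(t) {
      pmin(B + (v - B) * exp(-(t - d)^2 / (2 * width^2)) +
             (v2 - B) * exp(-(t - d2)^2 / (2 * width^2)), 1)
    }
    return(list(fn = fn, family = "bimodal_mixture", peak_value = v,
                peak_doy = d, peak_value2 = v2, peak_doy2 = d2))
  }
  # double logistic: green-up and senescence sigmoids around the peak
  sos <- d - 40; eos <- d + 45
  fn <- function(t) {
    B + (v - B) * (1 / (1 + exp(-(t - sos) / 7)) -
                     1 / (1 + exp(-(t - eos) / 10)))
  }
  list(fn = fn, family = "double_logistic", peak_value = v, peak_doy = d)
}
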