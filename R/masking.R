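# Cloud/quality masking for the two optical sensors that ship quality
# layers. Meteor scenes arrive as provider-side daily composites without a
# QA band; their validity mask is all-true unless a pixel carries the
# sentinel no-data value.

# Sentinel-2 L2A scene-classification codes marked unusable: no data,
# saturated/defective, cloud shadow, medium/high cloud probability, haze
# (thin cirrus), snow. Code 2 (dark-area pixels) is not in the exclusion
# list and is treated as valid.
SCL_INVALID <- c(0L, 1L, 3L, 8L, 9L, 10L, 11L)

# The single Landsat QA_PIXEL value accepted as clear land.
LANDSAT_CLEAR_QA <- 21824L

new_validity_mask <- function(valid, sensor_id, doy = NA_integer_,
                              year = NA_integer_) {
  structure(
    list(valid = valid, sensor_id = sensor_id, doy = doy, year = year,
         masked_fraction = 1 - sum(valid) / length(valid)),
    class = "validity_mask"
  )
}

#' @export
print.validity_mask <- function(x, ...) {
  cat(sprintf("validity_mask [%s]: %d x %d, %.1f%% masked\n", x$sensor_id,
              nrow(x$valid), ncol(x$valid), 100 * x$masked_fraction))
  invisible(x)
}

#' Sentinel-2 validity mask from the scene classification layer
#'
#' A pixel is unusable iff its SCL code is one of 0 (no data), 1
#' (saturated/defective), 3 (cloud shadow), 8 (cloud medium probability),
#' 9 (cloud high probability), 10 (haze/thin cirrus) or 11 (snow). All
#' other codes, including 2 (dark-area pixels), are valid.
#'
#' @param scl Integer matrix of SCL codes (0-11).
#' @param doy,year Optional scene date metadata.
#' @return A `validity_mask`: logical grid (`TRUE` = usable) plus the
#'   masked fraction.
#' @export
sentinel_validity <- function(scl, doy = NA_integer_, year = NA_integer_) {
  bad <- scl < 0 | scl > 11
  if (any(bad, na.rm = TRUE))
    stop(sprintf("SCL code outside 0-11: %s",
                 paste(unique(scl[which(bad)]), collapse = ", ")),
         call. = FALSE)
  valid <- !(scl %in% SCL_INVALID)
  dim(valid) <- dim(scl)
  new_validity_mask(valid, "sentinel", doy, year)
}

#' Landsat validity mask from the QA_PIXEL band
#'
#' Only pixels whose QA_PIXEL value equals 21824 (clear land: no haze,
#' cloud, cloud shadow, snow or water) are valid.
#'
#' @param qa Non-negative integer matrix of QA_PIXEL values.
#' @inheritParams sentinel_validity
#' @return A `validity_mask`.
#' @export
landsat_validity <- function(qa, doy = NA_integer_, year = NA_integer_) {
  if (any(qa < 0, na.rm = TRUE))
    stop("QA_PIXEL values must be non-negative", call. = FALSE)
  valid <- qa == LANDSAT_CLEAR_QA
  dim(valid) <- dim(qa)
  new_validity_mask(valid, "landsat", doy, year)
}

#' Cloud-fraction bin of a scene
#'
#' Bins the masked-pixel percentage into the four reporting classes
#' `<5` (cloud-free), `5-20` (low-cloud), `20-50` and `>50`. Bins are
#' half-open on the left (`[0,0.05)`, `[0.05,0.20)`, `[0.20,0.50)`) with
#' the last bin closed at 1, so the four bins partition `[0,1]`.
#'
#' @param mask A `validity_mask`, or a numeric masked fraction in `[0,1]`.
#' @return A factor level among `c("<5","5-20","20-50",">50")`.
#' @export
cloud_bin <- function(mask) {
  f <- if (inherits(mask, "validity_mask")) mask$masked_fraction else mask
  stopifnot(all(f >= 0 & f <= 1))
  cut(f, breaks = c(-Inf, 0.05, 0.20, 0.50, Inf), right = FALSE,
      labels = CLOUD_BINS)
}

CLOUD_BINS <- c("<5", "5-20", "20-50", ">50")

#' Tally scenes by cloud-fraction bin
#'
#' Produces the per-stack summary used for imagery bookkeeping: how many
#' scenes fall in each masked-percentage bin.
#'
#' @param fractions Numeric vector of per-scene masked fractions, or a list
#'   of `validity_mask` objects.
#' @return Named integer vector over the four bins.
#' @export
cloud_bin_tally <- function(fractions) {
  if (is.list(fractions))
    fractions <- vapply(fractions, function(m) m$masked_fraction, numeric(1))
  table(factor(cloud_bin(fractions), levels = CLOUD_BINS))
}

#' Apply a validity mask to a value grid
#'
#' Masked pixels become `NA` (missing), never zero, so downstream curve
#' fitting only ever sees valid observations. Idempotent: masking
#' already-masked data changes nothing.
#'
#' @param values Numeric matrix.
#' @param mask A `validity_mask` with matching dimensions.
#' @return The matrix with invalid pixels set to `NA`.
#' @export
apply_mask <- function(values, mask) {
  stopifnot(inherits(mask, "validity_mask"),
            all(dim(values) == dim(mask$valid)))
  values[!mask$valid] <- NA_real_
  values
}

#' Meteor validity mask
#'
#' Meteor daily composites carry no quality layer; everything is valid
#' except explicit no-data pixels.
#'
#' @param ndvi Meteor NDVI grid.
#' @param nodata Sentinel value marking no-data (default `NA`).
#' @inheritParams sentinel_validity
#' @return A `validity_mask`.
#' @export
meteor_validity <- function(ndvi, nodata = NA_real_, doy = NA_integer_,
                            year = NA_integer_) {
  valid <- if (is.na(nodata)) !is.na(ndvi) else ndvi != nodata & !is.na(ndvi)
  dim(valid) <- dim(ndvi)
  new_validity_mask(valid, "meteor", doy, year)
}
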