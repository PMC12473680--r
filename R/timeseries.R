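# Seasonal NDVI series: NDVI computation, truncated Fourier fitting of
# gapped observations, daily reconstruction over the growing season
# (DOY 121-296) and weekly sliding-window composites.

SEASON_DOY <- 121:296

#' Weekly anchor days
#'
#' The 26 anchors of the weekly grid: DOY 121, 128, ..., 296.
#' @return Integer vector of length 26.
#' @export
weekly_anchors <- function() as.integer(121 + 7 * (0:25))

#' NDVI from a reflectance pair
#'
#' `(NIR - RED) / (NIR + RED)` per pixel. Pixels where both bands are zero
#' are returned missing. Result lies in `[-1, 1]` for non-negative
#' reflectances.
#'
#' @param nir,red Non-negative reflectance matrices of identical shape.
#' @return NDVI matrix.
#' @export
compute_ndvi <- function(nir, red) {
  if (!all(dim(nir) == dim(red)))
    stop("NIR and RED grids have different shapes", call. = FALSE)
  if (any(nir < 0, na.rm = TRUE) || any(red < 0, na.rm = TRUE))
    stop("reflectances must be non-negative", call. = FALSE)
  s <- nir + red
  out <- (nir - red) / s
  out[s == 0] <- NA_real_
  out
}

#' Evaluate a truncated (two-term) Fourier series
#'
#' `a0 + a1 cos(wt) + b1 sin(wt) + a2 cos(2wt) + b2 sin(2wt)`.
#'
#' @param par Named numeric vector or list with `w, a0, a1, b1, a2, b2`.
#' @param t Days of year at which to evaluate.
#' @return Numeric vector.
#' @export
fourier_eval <- function(par, t) {
  w <- par[["w"]]
  par[["a0"]] + par[["a1"]] * cos(w * t) + par[["b1"]] * sin(w * t) +
    par[["a2"]] * cos(2 * w * t) + par[["b2"]] * sin(2 * w * t)
}

fourier_basis <- function(w, t) {
  cbind(1, cos(w * t), sin(w * t), cos(2 * w * t), sin(2 * w * t))
}

# Residual sum of squares for the linear coefficients profiled out at a
# given angular frequency.
profile_rss <- function(w, t, y) {
  fit <- .lm.fit(fourier_basis(w, t), y)
  sum(fit$residuals^2)
}

W_LOWER <- 2 * pi / 800
W_UPPER <- 2 * pi / 120
W_INIT <- 2 * pi / 368

#' Fit a truncated Fourier series to a gapped NDVI series
#'
#' Nonlinear least squares over the six parameters, solved by profiling:
#' for each candidate angular frequency `w` the remaining five
#' coefficients are the exact linear least-squares solution, and the
#' one-dimensional residual profile over `w` is minimized by golden-section
#' refinement around the best local minima of a coarse frequency grid
#' (multi-start, bounded to one cycle per 120-800 days, seasonal prior at
#' one cycle per 368 days). Deterministic given the series.
#'
#' @param doy Integer days of year of the observations.
#' @param ndvi NDVI observations; `NA` = masked/invalid.
#' @param min_obs Minimum number of valid observations (default 8:
#'   six parameters plus two).
#' @param w_init Frequency used for degenerate (constant) series.
#' @param w_bounds Frequency search interval.
#' @return A `fourier_fit`: parameters, `n_obs`, `rmse`, `converged` flag.
#' @export
fit_fourier <- function(doy, ndvi, min_obs = 8, w_init = W_INIT,
                        w_bounds = c(W_LOWER, W_UPPER), tol = 1e-9) {
  ok <- is.finite(ndvi)
  t <- as.numeric(doy[ok]); y <- as.numeric(ndvi[ok])
  if (anyDuplicated(t) || is.unsorted(t))
    stop("observation DOYs must be strictly increasing", call. = FALSE)
  if (length(y) < min_obs)
    stop(sprintf("insufficient data: %d valid observations < min_obs = %d",
                 length(y), min_obs), call. = FALSE)
  if (stats::sd(y) == 0) {
    par <- c(w = w_init, a0 = y[1], a1 = 0, b1 = 0, a2 = 0, b2 = 0)
    return(new_fourier_fit(par, length(y), 0, TRUE))
  }
  grid <- exp(seq(log(w_bounds[1]), log(w_bounds[2]), length.out = 12))
  if (!any(abs(grid / w_init - 1) < 1e-12)) grid <- sort(c(grid, w_init))
  rss <- vapply(grid, profile_rss, numeric(1), t = t, y = y)
  # refine the best local minima of the coarse profile (multi-start)
  n <- length(grid)
  locmin <- which(rss <= c(Inf, rss[-n]) & rss <= c(rss[-1], Inf))
  locmin <- locmin[order(rss[locmin])][seq_len(min(2, length(locmin)))]
  best <- list(w = grid[which.min(rss)], rss = min(rss))
  for (i in locmin) {
    lo <- grid[max(1, i - 1)]; hi <- grid[min(n, i + 1)]
    opt <- stats::optimize(profile_rss, c(lo, hi), t = t, y = y, tol = tol)
    if (opt$objective < best$rss) best <- list(w = opt$minimum,
                                               rss = opt$objective)
  }
  fit <- .lm.fit(fourier_basis(best$w, t), y)
  par <- c(w = best$w, a0 = fit$coefficients[1], a1 = fit$coefficients[2],
           b1 = fit$coefficients[3], a2 = fit$coefficients[4],
           b2 = fit$coefficients[5])
  conv <- all(is.finite(par))
  new_fourier_fit(par, length(y), sqrt(max(best$rss, 0) / length(y)), conv)
}

new_fourier_fit <- function(par, n_obs, rmse, converged) {
  structure(list(par = par, n_obs = n_obs, rmse = rmse,
                 converged = converged),
            class = "fourier_fit")
}

#' @export
print.fourier_fit <- function(x, ...) {
  cat(sprintf(
    "fourier_fit: period %.1f d, a0 %.3f, n_obs %d, rmse %.4g%s\n",
    2 * pi / x$par[["w"]], x$par[["a0"]], x$n_obs, x$rmse,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Daily NDVI reconstruction from a fitted curve
#'
#' Evaluates the fitted series at every integer day of `doy_range`
#' (default the 176-day growing season, DOY 121-296) and clamps to the
#' NDVI domain `[-1, 1]`.
#'
#' @param fit A `fourier_fit` (or a parameter vector accepted by
#'   [fourier_eval()]).
#' @param doy_range Integer days to evaluate.
#' @return Numeric vector, one value per day.
#' @export
reconstruct_daily <- function(fit, doy_range = SEASON_DOY) {
  par <- if (inherits(fit, "fourier_fit")) fit$par else fit
  pmin(pmax(fourier_eval(par, doy_range), -1), 1)
}

#' Weekly sliding-window composites of a daily series
#'
#' Averages the daily reconstruction within the 7-day window
#' `[anchor, anchor + 6]` at each of the 26 weekly anchors (DOY 121, 128,
#' ..., 296); the last window is truncated at DOY 296. `stat = "max"` takes
#' the window maximum instead of the mean.
#'
#' @param daily Numeric vector of 176 daily values on DOY 121-296.
#' @param stat Window statistic, `"mean"` (default) or `"max"`.
#' @return Numeric vector of 26 weekly values.
#' @export
weekly_composites <- function(daily, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  if (length(daily) != length(SEASON_DOY))
    stop(sprintf("expected %d daily values, got %d", length(SEASON_DOY),
                 length(daily)), call. = FALSE)
  f <- if (stat == "mean") mean else max
  vapply(weekly_anchors(), function(a) {
    idx <- which(SEASON_DOY >= a & SEASON_DOY <= min(a + 6, 296))
    f(daily[idx])
  }, numeric(1))
}

#' Weekly composites from Meteor daily scenes
#'
#' Meteor series are not curve-fitted (the daily composites are already
#' provider-smoothed and carry no quality layer to drive refitting); the
#' weekly value is the mean of the valid daily observations inside each
#' 7-day window. Interior anchors with no valid day are filled by linear
#' interpolation between neighboring anchors; leading/trailing empty
#' anchors take the nearest valid anchor value (Meteor coverage spans DOY
#' 122-269 only).
#'
#' @param doy Days of year of the daily observations.
#' @param ndvi Daily NDVI values; `NA` = missing.
#' @param stat Window statistic, `"mean"` (default) or `"max"`.
#' @return Numeric vector of 26 weekly values.
#' @export
meteor_weekly <- function(doy, ndvi, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  ok <- is.finite(ndvi)
  if (!any(ok)) stop("insufficient data: all-missing Meteor series",
                     call. = FALSE)
  t <- doy[ok]; y <- ndvi[ok]
  f <- if (stat == "mean") mean else max
  anchors <- weekly_anchors()
  raw <- vapply(anchors, function(a) {
    v <- y[t >= a & t <= min(a + 6, 296)]
    if (length(v) == 0) NA_real_ else f(v)
  }, numeric(1))
  fill_anchor_gaps(raw)
}

# Linear interpolation of interior NA anchors; nearest-value extension at
# the ends.
fill_anchor_gaps <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- seq_along(x)
  stats::approx(idx[!is.na(x)], x[!is.na(x)], xout = idx, rule = 2)$y
}
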