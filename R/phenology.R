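# Field-level phenology: mean weekly series per field, seasonal maximum
# (NDVImax) and its day (DOYmax), dual-maximum extraction for bimodal
# classes, per-class summaries and year-to-year ANOVA/Tukey comparisons.

#' Field-mean weekly series
#'
#' Unweighted per-week mean over a field's cells for one sensor. Weeks
#' missing in some cells average over the available ones; weeks missing in
#' every cell stay missing.
#'
#' @param cube A `weekly_cube`.
#' @param field Field id.
#' @param sensor Sensor name present in the cube.
#' @return Numeric vector of 26 weekly values.
#' @export
field_mean_series <- function(cube, field, sensor) {
  stopifnot(inherits(cube, "weekly_cube"))
  cells <- which(!is.na(cube$field_id) & cube$field_id == field)
  m <- cube$sensors[[sensor]][cells, , drop = FALSE]
  m <- m[rowSums(is.finite(m)) > 0, , drop = FALSE]
  if (nrow(m) == 0)
    stop(sprintf("insufficient data: field %s has no usable cells for %s",
                 field, sensor), call. = FALSE)
  out <- colMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Seasonal maximum of an NDVI series
#'
#' Maximum value and the day it occurs; ties take the earliest day.
#'
#' @param values NDVI values.
#' @param doys Days of year of the values (default the weekly anchors).
#' @return Named vector `c(ndvi_max, doy_max)`.
#' @export
extract_max <- function(values, doys = weekly_anchors()) {
  stopifnot(length(values) == length(doys))
  ok <- is.finite(values)
  if (!any(ok)) stop("insufficient data: all-missing series", call. = FALSE)
  i <- which(ok)[which.max(values[ok])]
  c(ndvi_max = values[i], doy_max = doys[i])
}

#' Early and late seasonal maxima
#'
#' Splits the season at `split_doy` and extracts the maximum on each side
#' separately (for classes whose mowing/regrowth cycle yields two peaks).
#' An empty side reports `NA`s rather than an error.
#'
#' @inheritParams extract_max
#' @param split_doy Boundary day (default 210, separating the
#'   late-June/July first maxima from the late-August/September second
#'   maxima).
#' @return Named vector `c(ndvi_max1, doy_max1, ndvi_max2, doy_max2)`.
#' @export
extract_two_maxima <- function(values, doys = weekly_anchors(),
                               split_doy = 210) {
  stopifnot(length(values) == length(doys))
  side <- function(sel) {
    if (any(sel & is.finite(values))) extract_max(values[sel], doys[sel])
    else c(ndvi_max = NA_real_, doy_max = NA_real_)
  }
  m1 <- side(doys < split_doy)
  m2 <- side(doys >= split_doy)
  c(ndvi_max1 = unname(m1[1]), doy_max1 = unname(m1[2]),
    ndvi_max2 = unname(m2[1]), doy_max2 = unname(m2[2]))
}

#' Per-class phenology summary
#'
#' Mean, 95\% t-interval half-width and coefficient of variation
#' (sd/mean x 100) of NDVImax and DOYmax over the fields of one class:
#' the row format of the per-class indicator tables.
#'
#' @param ndvi_max,doy_max Per-field values (equal length, n >= 2).
#' @param class,year,sensor Optional labels carried into the output.
#' @return One-row `data.frame` with n, means, half-widths and CVs.
#' @export
class_summary <- function(ndvi_max, doy_max, class = NA, year = NA,
                          sensor = NA) {
  stopifnot(length(ndvi_max) == length(doy_max))
  n <- length(ndvi_max)
  if (n < 2) stop("insufficient data: need >= 2 fields", call. = FALSE)
  half <- function(x) stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n)
  cv <- function(x) 100 * stats::sd(x) / mean(x)
  data.frame(class = class, year = year, sensor = sensor, n = n,
             ndvi_max_mean = mean(ndvi_max), ndvi_max_hw = half(ndvi_max),
             var_ndvi = cv(ndvi_max),
             doy_max_mean = mean(doy_max), doy_max_hw = half(doy_max),
             var_doy = cv(doy_max))
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Closed-form one-way analysis of variance over groups (years), followed
#' by Tukey honest-significant-difference pairwise p-values from the
#' studentized range distribution (Tukey-Kramer standard error for
#' unequal group sizes). If the within-group variance is zero with
#' unequal means, F is reported infinite with p = 0 by convention.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups, each n >= 2).
#' @return A `group_comparison`: `levels`, `F`, `p_anova`, `df`, and
#'   `pairwise` (data.frame of level pairs, differences and p-values).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ni <- tabulate(groups)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(ni < 2)) stop("every group needs n >= 2", call. = FALSE)
  n <- length(values)
  mi <- tapply(values, groups, mean)
  gm <- mean(values)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((values - mi[groups])^2)
  df1 <- k - 1; df2 <- n - k
  if (ssw == 0) {
    if (ssb == 0) { F <- 0; p <- 1 } else { F <- Inf; p <- 0 }
    s2 <- 0
  } else {
    s2 <- ssw / df2
    F <- (ssb / df1) / s2
    p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  }
  pairs <- utils::combn(levels(groups), 2)
  pw <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    diff = mi[pairs[2, ]] - mi[pairs[1, ]], row.names = NULL)
  se <- sqrt(s2 / 2 * (1 / ni[match(pw$group1, levels(groups))] +
                         1 / ni[match(pw$group2, levels(groups))]))
  q <- abs(pw$diff) / se
  pw$p <- ifelse(is.nan(q), 1,
                 ifelse(is.infinite(q), 0,
                        stats::ptukey(q, k, df2, lower.tail = FALSE)))
  structure(list(levels = levels(groups), F = F, p_anova = p,
                 df = c(df1, df2), pairwise = pw),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p_anova))
  print(x$pairwise, digits = 3)
  invisible(x)
}

#' Per-field phenology over a cube
#'
#' Extracts NDVImax/DOYmax (and the early/late pair) from the field-mean
#' weekly series of every field, for one sensor.
#'
#' @param cube A `weekly_cube`.
#' @param sensor Sensor name.
#' @param classes Named field -> class lookup (`data.frame` with `id`,
#'   `class`), e.g. a landscape's `field_table`.
#' @param split_doy Passed to [extract_two_maxima()].
#' @param resolution `"daily"` re-fits the seasonal curve through the
#'   field's 26 weekly anchors and extracts maxima from the 176-day
#'   reconstruction (day precision, appropriate for sensors whose weekly
#'   layers come from fitted curves); `"weekly"` extracts on the anchor
#'   grid directly (7-day precision, appropriate for windowed Meteor
#'   composites).
#' @return `data.frame`: field id, class, ndvi_max, doy_max and the two
#'   split maxima.
#' @export
field_phenology <- function(cube, sensor, classes, split_doy = 210,
                            resolution = c("daily", "weekly")) {
  resolution <- match.arg(resolution)
  ids <- sort(unique(cube$field_id[!is.na(cube$field_id)]))
  rows <- lapply(ids, function(f) {
    s <- tryCatch(field_mean_series(cube, f, sensor),
                  error = function(e) NULL)
    if (is.null(s) || !any(is.finite(s))) return(NULL)
    if (resolution == "daily" && !anyNA(s)) {
      fit <- fit_fourier(weekly_anchors(), s, min_obs = 6)
      vals <- reconstruct_daily(fit)
      doys <- SEASON_DOY
    } else {
      vals <- s
      doys <- weekly_anchors()
    }
    m <- extract_max(vals, doys)
    m2 <- extract_two_maxima(vals, doys, split_doy = split_doy)
    data.frame(id = f, class = classes$class[match(f, classes$id)],
               ndvi_max = m[["ndvi_max"]], doy_max = m[["doy_max"]],
               t(m2))
  })
  do.call(rbind, rows)
}
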