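#' Geographic grid specification
#'
#' A north-up, row-major regular grid in geographic (longitude/latitude)
#' coordinates with square pixels. Rows run north to south, columns west to
#' east; cell (1,1) is the north-west corner. Cell centers sit half a pixel
#' inside the bounds, and pixel extents are half-open.
#'
#' @param xmin,ymax Coordinates of the grid origin (west edge, north edge),
#'   in degrees.
#' @param px Pixel size in degrees (same in both axes).
#' @param nrow,ncol Grid dimensions in cells.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(xmin, ymax, px, nrow, ncol) {
  stopifnot(px > 0, nrow >= 1, ncol >= 1)
  structure(
    list(xmin = xmin, ymax = ymax, px = px, nrow = as.integer(nrow),
         ncol = as.integer(ncol)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, %.6f deg/pixel, origin (%.5f, %.5f)\n",
              x$nrow, x$ncol, x$px, x$xmin, x$ymax))
  invisible(x)
}

#' @rdname grid_spec
#' @param g A `grid_spec`.
#' @export
grid_bounds <- function(g) {
  c(xmin = g$xmin, ymin = g$ymax - g$nrow * g$px,
    xmax = g$xmin + g$ncol * g$px, ymax = g$ymax)
}

#' Cell-center coordinates
#'
#' @param g A `grid_spec`.
#' @param row,col Cell indices (1-based); vectors are recycled.
#' @return A list with `lon` and `lat` vectors.
#' @export
cell_center <- function(g, row, col) {
  list(lon = g$xmin + (col - 0.5) * g$px,
       lat = g$ymax - (row - 0.5) * g$px)
}

# Degrees per meter under the equatorial 1 deg ~ 111 km conversion.
DEG_PER_M <- 1 / 111000

#' Build the common target grid
#'
#' Creates the harmonization grid: a regular geographic grid whose pixel
#' size in degrees is `resolution_m / 111000` (the 1 deg ~ 111 km
#' equatorial conversion; at 60 m this is approximately 0.00054 deg).
#' The grid is anchored at the north-west corner of `bounds` and extended
#' east/south by whole pixels to cover the bounds.
#'
#' @param bounds Numeric vector `c(xmin, ymin, xmax, ymax)` in degrees.
#' @param resolution_m Target resolution in meters (default 60).
#' @return A `grid_spec`.
#' @export
build_target_grid <- function(bounds, resolution_m = 60) {
  stopifnot(length(bounds) == 4)
  xmin <- bounds[[1]]; ymin <- bounds[[2]]
  xmax <- bounds[[3]]; ymax <- bounds[[4]]
  if (!(xmax > xmin && ymax > ymin))
    stop("degenerate bounds: need xmax > xmin and ymax > ymin", call. = FALSE)
  px <- resolution_m * DEG_PER_M
  ncol <- ceiling((xmax - xmin) / px - 1e-9)
  nrow <- ceiling((ymax - ymin) / px - 1e-9)
  grid_spec(xmin, ymax, px, nrow, ncol)
}

#' Bilinear resampling onto a target grid
#'
#' Resamples a source raster onto the cells of `target` by bilinear
#' interpolation at each target cell center: the value is the
#' distance-weighted average of the four nearest source cell centers.
#' Target cells whose interpolation point falls outside the source center
#' lattice, or any of whose positively weighted neighbors is missing, are
#' set to `NA` (missing neighbors with exactly zero weight are ignored, so
#' resampling a grid onto itself is the identity).
#'
#' @param values Source matrix (`src$nrow` x `src$ncol`); `NA` = missing.
#' @param src Source `grid_spec`.
#' @param target Target `grid_spec`.
#' @return Matrix of dimension `target$nrow` x `target$ncol`.
#' @export
resample_bilinear <- function(values, src, target) {
  stopifnot(inherits(src, "grid_spec"), inherits(target, "grid_spec"))
  if (!all(dim(values) == c(src$nrow, src$ncol)))
    stop("source values do not match source grid dimensions", call. = FALSE)
  sb <- grid_bounds(src); tb <- grid_bounds(target)
  if (tb["xmin"] >= sb["xmax"] || tb["xmax"] <= sb["xmin"] ||
      tb["ymin"] >= sb["ymax"] || tb["ymax"] <= sb["ymin"])
    stop("no overlap between source and target grids", call. = FALSE)

  tc <- expand.grid(row = seq_len(target$nrow), col = seq_len(target$ncol))
  ctr <- cell_center(target, tc$row, tc$col)
  # fractional position in source cell-center coordinates
  jf <- (ctr$lon - src$xmin) / src$px + 0.5
  if_ <- (src$ymax - ctr$lat) / src$px + 0.5
  # snap to the source lattice where rounding noise would otherwise put
  # epsilon weights on (possibly missing) neighbors
  snap <- function(x) ifelse(abs(x - round(x)) < 1e-7, round(x), x)
  jf <- snap(jf); if_ <- snap(if_)
  j0 <- floor(jf); i0 <- floor(if_)
  wx <- jf - j0; wy <- if_ - i0

  pick <- function(i, j, w) {
    v <- rep(NA_real_, length(i))
    inside <- i >= 1 & i <= src$nrow & j >= 1 & j <= src$ncol
    v[inside] <- values[cbind(i[inside], j[inside])]
    # zero-weight neighbors contribute 0 regardless of availability
    out <- v * w
    out[w == 0] <- 0
    out
  }
  acc <- pick(i0,     j0,     (1 - wx) * (1 - wy)) +
         pick(i0,     j0 + 1, wx * (1 - wy)) +
         pick(i0 + 1, j0,     (1 - wx) * wy) +
         pick(i0 + 1, j0 + 1, wx * wy)
  matrix(acc, nrow = target$nrow, ncol = target$ncol)
}

#' Rasterize labeled field polygons
#'
#' Burns polygons onto a grid by the cell-center rule: a cell gets the label
#' of the polygon containing its center (even-odd ray casting); cells
#' outside every polygon stay `NA` (background). Overlapping polygons are an
#' error naming the offending field ids.
#'
#' @param fields A `field_set` (see [field_set()]) or list with elements
#'   `id`, `class`, and `rings` (list of two-column lon/lat matrices).
#' @param g Target `grid_spec`.
#' @return List with `label` (character matrix) and `field_id` (integer
#'   matrix), both `NA` for background.
#' @export
rasterize_fields <- function(fields, g) {
  lab <- matrix(NA_character_, g$nrow, g$ncol)
  fid <- matrix(NA_integer_, g$nrow, g$ncol)
  if (length(fields$id) == 0) return(list(label = lab, field_id = fid))
  cc <- expand.grid(row = seq_len(g$nrow), col = seq_len(g$ncol))
  ctr <- cell_center(g, cc$row, cc$col)
  for (k in seq_along(fields$id)) {
    ring <- fields$rings[[k]]
    inside <- point_in_polygon(ctr$lon, ctr$lat, ring)
    idx <- cbind(cc$row[inside], cc$col[inside])
    clash <- !is.na(fid[idx])
    if (any(clash)) {
      other <- unique(fid[idx][clash])
      stop(sprintf("overlapping fields: %s and %s",
                   fields$id[k], paste(fields$id[match(other, fields$id)],
                                       collapse = ", ")), call. = FALSE)
    }
    lab[idx] <- fields$class[k]
    fid[idx] <- fields$id[k]
  }
  list(label = lab, field_id = fid)
}

#' Even-odd point-in-polygon test
#'
#' @param x,y Point coordinates (vectors).
#' @param ring Two-column matrix of polygon vertices (closing vertex
#'   optional).
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, ring) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) { ring <- ring[-n, , drop = FALSE]; n <- n - 1 }
  if (n < 3) return(rep(FALSE, length(x)))
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
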