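# Readers and writers: ESRI ASCII grids for rasters, GeoJSON for field
# polygons, CSV for series/summaries/confusion matrices, JSON for reports
# and run manifests. Scene files follow the `<sensor>_<YYYYDDD>` naming
# convention for date metadata.

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text georeferenced raster (ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA header plus row-wise values), readable by standard GIS
#' software.
#'
#' @param values Numeric matrix matching `g`.
#' @param g A `grid_spec`.
#' @param path Output path (conventionally `.asc`).
#' @param digits Significant digits written.
#' @export
write_ascii_grid <- function(values, g, path, digits = 7) {
  stopifnot(all(dim(values) == c(g$nrow, g$ncol)))
  b <- grid_bounds(g)
  hdr <- c(sprintf("ncols %d", g$ncol), sprintf("nrows %d", g$nrow),
           sprintf("xllcorner %.12f", b[["xmin"]]),
           sprintf("yllcorner %.12f", b[["ymin"]]),
           sprintf("cellsize %.15g", g$px), "NODATA_value -9999")
  v <- signif(values, digits)
  v[is.na(v)] <- -9999
  rows <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @return List with `values` (matrix, `NA` for no-data) and `grid`
#'   (`grid_spec`).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop(sprintf("not a georeferenced ASCII grid (missing %s): %s",
                 paste(setdiff(need, names(hdr)), collapse = ", "), path),
         call. = FALSE)
  nr <- hdr$nrows; nc <- hdr$ncols
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d: %s", nr * nc,
                 length(vals), path), call. = FALSE)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  nd <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nd] <- NA_real_
  g <- grid_spec(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize,
                 hdr$cellsize, nr, nc)
  list(values = m, grid = g)
}

#' Parse the sensor and date from a scene file name
#'
#' Scene files are named `<sensor>_<YYYYDDD>` (e.g. `sentinel_2022186`):
#' four-digit year followed by the three-digit day of year.
#'
#' @param path File name or path.
#' @return List with `sensor`, `year`, `doy`.
#' @export
parse_scene_name <- function(path) {
  base <- sub("\\.[A-Za-z]+$", "", basename(path))
  m <- regmatches(base, regexec("^([a-z]+)_([0-9]{4})([0-9]{3})$", base))[[1]]
  if (length(m) != 4)
    stop(sprintf("unparseable scene name (expected <sensor>_<YYYYDDD>): %s",
                 basename(path)), call. = FALSE)
  list(sensor = m[2], year = as.integer(m[3]), doy = as.integer(m[4]))
}

#' Read a scene raster with date metadata
#'
#' @param path Path to an ASCII-grid scene named `<sensor>_<YYYYDDD>.asc`.
#' @return List with `values`, `grid`, `sensor`, `year`, `doy`.
#' @export
read_scene <- function(path) {
  meta <- parse_scene_name(path)
  ras <- read_ascii_grid(path)
  c(ras, meta)
}

#' Read labeled field polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features carrying a `class`
#' property among the five crop/fallow labels. Rings are validated
#' (closure enforced, consecutive duplicate vertices dropped,
#' self-intersecting rings rejected); problems are reported per feature.
#'
#' @param path GeoJSON file.
#' @return A `field_set`.
#' @export
read_fields <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  ids <- integer(0); classes <- character(0); rings <- list()
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    cl <- f$properties$class
    if (is.null(cl) || !cl %in% CLASS_LEVELS)
      stop(sprintf("feature %d: unknown class label '%s'", k,
                   if (is.null(cl)) "<missing>" else cl), call. = FALSE)
    if (!identical(f$geometry$type, "Polygon"))
      stop(sprintf("feature %d: geometry type must be Polygon", k),
           call. = FALSE)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    ring <- repair_ring(ring, k)
    id <- if (!is.null(f$properties$id)) as.integer(f$properties$id) else k
    ids <- c(ids, id); classes <- c(classes, cl)
    rings[[length(rings) + 1]] <- ring
  }
  field_set(ids, classes, rings)
}

# Close the ring, drop consecutive duplicates, reject self-intersection.
repair_ring <- function(ring, feature_idx) {
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  dup <- c(FALSE, rowSums(abs(diff(ring))) == 0)
  if (any(dup)) {
    message(sprintf("feature %d: removed %d duplicate vertices",
                    feature_idx, sum(dup)))
    ring <- ring[!dup, , drop = FALSE]
  }
  if (nrow(ring) < 3)
    stop(sprintf("feature %d: degenerate ring (< 3 vertices)",
                 feature_idx), call. = FALSE)
  if (ring_self_intersects(ring))
    stop(sprintf("feature %d: self-intersecting ring rejected",
                 feature_idx), call. = FALSE)
  ring
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  idx <- rbind(cbind(1:n, c(2:n, 1)))
  for (a in seq_len(n - 2)) {
    for (b in (a + 2):n) {
      if (a == 1 && b == n) next  # adjacent via closure
      if (segments_cross(ring[idx[a, 1], ], ring[idx[a, 2], ],
                         ring[idx[b, 1], ], ring[idx[b, 2], ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Write field polygons as GeoJSON
#'
#' @param fields A `field_set`.
#' @param path Output path.
#' @export
write_fields <- function(fields, path) {
  feats <- lapply(seq_along(fields$id), function(k) {
    ring <- fields$rings[[k]]
    if (!all(ring[1, ] == ring[nrow(ring), ]))
      ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(id = fields$id[k], class = fields$class[k]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
}

#' Read a confusion-matrix CSV
#'
#' First column `class` (actual), remaining columns predicted counts in
#' the same class order.
#'
#' @param path CSV path.
#' @return Integer matrix with dimnames.
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Per-field pixel-date CSV export
#'
#' One row per pixel and observation date: longitude, latitude, DOY,
#' NDVI — the per-field time-series product of the extraction stage.
#'
#' @param obs Result of [stack_observations()].
#' @param pixels Pixel indices (column-major on the stack grid).
#' @param path Output CSV.
#' @export
write_field_series_csv <- function(obs, pixels, path) {
  g <- obs$grid
  rc <- arrayInd(pixels, c(g$nrow, g$ncol))
  ctr <- cell_center(g, rc[, 1], rc[, 2])
  rows <- do.call(rbind, lapply(seq_along(pixels), function(i) {
    v <- obs$ndvi[, pixels[i]]
    ok <- is.finite(v)
    data.frame(longitude = ctr$lon[i], latitude = ctr$lat[i],
               doy = obs$dates[ok], ndvi = v[ok])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
}

#' Write a run manifest
#'
#' Records the reproducibility envelope of a pipeline run: seed, a config
#' digest, timestamps and per-stage record counts.
#'
#' @param manifest Named list of counts/settings.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}
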