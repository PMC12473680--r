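# Synthetic landscape: rectangular fields aligned to the common 60 m grid,
# class labels with configured area proportions, per-field sampled
# phenology curves and a within-field spatial heterogeneity surface.

#' Field set
#'
#' Lightweight container for labeled field polygons.
#'
#' @param id Integer field ids.
#' @param class Character class labels.
#' @param rings List of two-column lon/lat vertex matrices.
#' @return A `field_set`.
#' @export
field_set <- function(id, class, rings) {
  stopifnot(length(id) == length(class), length(id) == length(rings))
  bad <- !class %in% CLASS_LEVELS
  if (any(bad))
    stop(sprintf("unknown class label(s): %s (field %s)",
                 paste(unique(class[bad]), collapse = ", "),
                 paste(id[bad], collapse = ", ")), call. = FALSE)
  structure(list(id = as.integer(id), class = class, rings = rings),
            class = "field_set")
}

#' Default landscape configuration
#'
#' The study conditions of the default synthetic scene: a 100 x 100 cell
#' target grid at 60 m, about 200 rectangular fields of 2-3 cells per side
#' aligned to the target grid, class counts proportional to the 2022
#' cropped-area shares (soybean 62\%, fallow 20\%, grain crops 10\%,
#' perennial grasses 4\%, buckwheat 4\%), within-field spatial sd 0.02
#' NDVI, and background NDVI 0.25.
#'
#' @param n_fields Number of fields (default 200).
#' @param grid_cells Target grid side length in cells (default 100).
#' @param resolution_m Target resolution (default 60 m).
#' @param class_proportions Named numeric area shares (normalized
#'   internally).
#' @param field_cells_range Min/max field side length in target cells.
#' @param spatial_sd Within-field NDVI sd (per 60 m cell).
#' @param background_ndvi Flat background NDVI.
#' @param class_models Named list of `class_phenology_model`s.
#' @param origin Lon/lat of the grid's north-west corner.
#' @return Configuration list for [simulate_landscape()].
#' @export
default_landscape_config <- function(n_fields = 200, grid_cells = 100,
                                     resolution_m = 60,
                                     class_proportions = c(
                                       soybean = 4537.52,
                                       grain_crops = 762.72,
                                       buckwheat = 260.12,
                                       perennial_grasses = 294.80,
                                       fallow = 1422.84),
                                     field_cells_range = c(2, 3),
                                     spatial_sd = 0.02,
                                     background_ndvi = 0.25,
                                     class_models = default_class_models(),
                                     origin = c(135.0, 48.5)) {
  list(n_fields = n_fields, grid_cells = grid_cells,
       resolution_m = resolution_m,
       class_proportions = class_proportions / sum(class_proportions),
       field_cells_range = field_cells_range, spatial_sd = spatial_sd,
       background_ndvi = background_ndvi, class_models = class_models,
       origin = origin)
}

# Largest-remainder apportionment of n among proportions, at least 2 each
# (grouped splitting and CV need >= 2 fields per class).
apportion_fields <- function(n, props) {
  if (n < 2 * length(props))
    stop(sprintf("need at least %d fields to give every class >= 2",
                 2 * length(props)), call. = FALSE)
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  while (any(base < 2)) {
    i <- which.min(base)
    j <- which.max(base)  # guaranteed > 2 since n >= 2 * length(props)
    base[i] <- base[i] + 1; base[j] <- base[j] - 1
  }
  base
}

#' Simulate a labeled agricultural landscape
#'
#' Places non-overlapping rectangular fields aligned to the target grid,
#' assigns class labels in the configured area proportions, samples one
#' seasonal NDVI curve per field from its class model, and draws a
#' per-cell spatial heterogeneity offset shared by all sensors.
#'
#' @param config See [default_landscape_config()].
#' @param rng_seed Integer seed; the landscape is fully reproducible from
#'   `(config, rng_seed)`.
#' @return A `simulated_landscape`: `grid` (60 m `grid_spec`), `fields`
#'   (`field_set`), `field_table` (id, class, cell rectangle, n_cells),
#'   `label`/`field_id` ground-truth grids, `curves` (per field),
#'   `offset` grid, `config`, `rng_seed`.
#' @export
simulate_landscape <- function(config = default_landscape_config(),
                               rng_seed = 1) {
  set.seed(rng_seed)
  g <- grid_spec(config$origin[1], config$origin[2],
                 config$resolution_m * DEG_PER_M,
                 config$grid_cells, config$grid_cells)
  counts <- apportion_fields(config$n_fields, config$class_proportions)
  classes <- sample(rep(names(counts), counts))

  occupied <- matrix(FALSE, g$nrow, g$ncol)
  rect <- matrix(NA_integer_, length(classes), 4,
                 dimnames = list(NULL, c("row0", "col0", "h", "w")))
  lo <- config$field_cells_range[1]; hi <- config$field_cells_range[2]
  for (k in seq_along(classes)) {
    placed <- FALSE
    for (try in 1:200) {
      h <- sample(lo:hi, 1); wd <- sample(lo:hi, 1)
      r0 <- sample(seq_len(g$nrow - h), 1)
      c0 <- sample(seq_len(g$ncol - wd), 1)
      # one-cell buffer so fields stay separated
      rr <- max(1, r0 - 1):min(g$nrow, r0 + h)
      cc <- max(1, c0 - 1):min(g$ncol, c0 + wd)
      if (!any(occupied[rr, cc])) {
        occupied[rr, cc] <- TRUE
        rect[k, ] <- c(r0, c0, h, wd)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place all fields; reduce n_fields or enlarge grid",
           call. = FALSE)
  }

  rings <- lapply(seq_along(classes), function(k) {
    r <- rect[k, ]
    x0 <- g$xmin + (r["col0"] - 1) * g$px
    x1 <- x0 + r["w"] * g$px
    y1 <- g$ymax - (r["row0"] - 1) * g$px
    y0 <- y1 - r["h"] * g$px
    cbind(lon = c(x0, x1, x1, x0, x0), lat = c(y1, y1, y0, y0, y1))
  })
  fields <- field_set(seq_along(classes), classes, rings)
  ras <- rasterize_fields(fields, g)

  curves <- lapply(seq_along(classes),
                   function(k) sample_phenology_curve(
                     config$class_models[[classes[k]]]))
  offset <- matrix(stats::rnorm(g$nrow * g$ncol, 0, config$spatial_sd),
                   g$nrow, g$ncol)

  structure(list(
    grid = g, fields = fields,
    field_table = data.frame(id = fields$id, class = classes,
                             row0 = rect[, "row0"], col0 = rect[, "col0"],
                             h = rect[, "h"], w = rect[, "w"],
                             n_cells = rect[, "h"] * rect[, "w"]),
    label = ras$label, field_id = ras$field_id, curves = curves,
    offset = offset, config = config, rng_seed = rng_seed),
    class = "simulated_landscape")
}

#' @export
print.simulated_landscape <- function(x, ...) {
  cat(sprintf("simulated_landscape: %d fields on a %d x %d grid (seed %d)\n",
              length(x$fields$id), x$grid$nrow, x$grid$ncol, x$rng_seed))
  print(table(x$field_table$class))
  invisible(x)
}
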