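#' Raster grid container
#'
#' A `raster_grid` is a rectangular, north-up, row-major grid of cell values
#' in a projected equal-area coordinate system. It is the universal covariate
#' container of the package: row 1 is the northernmost row, the origin is the
#' outer corner of the top-left cell, and all distances are Euclidean in
#' projected metres. Missing cells are held as `NA` in memory; the `nodata`
#' sentinel is only used on disk.
#'
#' @param values numeric matrix (row 1 = north). `NA` marks nodata cells.
#' @param cell_size cell edge length in metres (> 0); the analyses in this
#'   package assume square cells (default 30 m).
#' @param origin length-2 numeric, `(x, y)` of the outer corner of the
#'   top-left cell in projected metres.
#' @param nodata numeric sentinel used when the grid is written to disk.
#' @param crs_label free-text tag describing the projection.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 30, origin = c(0, 0),
                        nodata = -9999, crs_label = "albers-nad83") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_burnsel("`values` must be a numeric matrix")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop_burnsel("grid must be at least 1x1")
  }
  assert_scalar_num(cell_size, "cell_size")
  if (cell_size <= 0) stop_burnsel("`cell_size` must be positive")
  if (length(origin) != 2L || !all(is.finite(origin))) {
    stop_burnsel("`origin` must be two finite numbers (x, y)")
  }
  if (any(is.infinite(values))) stop_burnsel("grid values must be finite or NA")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata),
         crs_label = as.character(crs_label)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells, %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  cat(sprintf("  values: [%g, %g], %d nodata\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              sum(is.na(x$values))))
  invisible(x)
}

#' Categorical raster with a legend
#'
#' A `raster_grid` whose cells hold small non-negative integer class codes,
#' together with a legend mapping each code to a class name. Used for land
#' cover (eight classes along the elevation gradient) and burn classes
#' (new/old x high/low severity, fire skips, unburned).
#'
#' @param values integer matrix of class codes (`NA` = nodata).
#' @param legend named character vector: names are the codes (as strings),
#'   values the class names. Every non-`NA` code must appear.
#' @inheritParams raster_grid
#' @return an object of class `c("categorical_raster", "raster_grid")`.
#' @export
categorical_raster <- function(values, legend, cell_size = 30,
                               origin = c(0, 0), nodata = -9999,
                               crs_label = "albers-nad83") {
  mode(values) <- "numeric"
  g <- raster_grid(values, cell_size, origin, nodata, crs_label)
  codes <- sort(unique(as.vector(values)))
  codes <- codes[!is.na(codes)]
  if (any(codes < 0) || any(codes != round(codes))) {
    stop_burnsel("categorical codes must be non-negative integers")
  }
  if (is.null(names(legend))) stop_burnsel("`legend` must be named by code")
  missing <- setdiff(as.character(codes), names(legend))
  if (length(missing)) {
    stop_burnsel("codes absent from legend: ", paste(missing, collapse = ", "))
  }
  g$legend <- legend
  class(g) <- c("categorical_raster", "raster_grid")
  g
}

is_categorical <- function(g) inherits(g, "categorical_raster")

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$cell_size - b$cell_size) <= tol &&
    all(abs(a$origin - b$origin) <= tol)
}

#' Stack of co-registered rasters
#'
#' A named collection of rasters over one study area, all sharing shape,
#' origin and cell size. Layer names carry the focal-scale suffix convention:
#' no suffix = native 30 m cell, `_s` = 3x3 (90 m) window, `_l` = 27x27
#' (810 m) window.
#'
#' @param layers named list of `raster_grid` objects.
#' @return an object of class `landscape_stack`.
#' @export
landscape_stack <- function(layers) {
  if (!is.list(layers) || is.null(names(layers)) || any(names(layers) == "")) {
    stop_burnsel("`layers` must be a fully named list of raster_grid objects")
  }
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "raster_grid")) {
      stop_burnsel("layer `", nm, "` is not a raster_grid")
    }
  }
  ref <- layers[[1]]
  for (nm in names(layers)[-1]) {
    if (!same_geometry(ref, layers[[nm]])) {
      stop_burnsel("layer `", nm, "` geometry mismatch with `",
                   names(layers)[1], "`")
    }
  }
  structure(list(layers = layers), class = "landscape_stack")
}

#' @export
print.landscape_stack <- function(x, ...) {
  ref <- x$layers[[1]]
  cat(sprintf("<landscape_stack> %d layers, %d x %d cells at %g m\n",
              length(x$layers), nrow(ref$values), ncol(ref$values),
              ref$cell_size))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[[.landscape_stack` <- function(x, name) x$layers[[name]]

#' Add or replace a layer in a stack
#' @param stack a `landscape_stack`.
#' @param name layer name.
#' @param grid co-registered `raster_grid`.
#' @return the updated stack.
#' @export
stack_set <- function(stack, name, grid) {
  if (!same_geometry(stack$layers[[1]], grid)) {
    stop_burnsel("cannot insert layer `", name, "`: geometry mismatch")
  }
  stack$layers[[name]] <- grid
  stack
}

# cell centre coordinates; row 1 = north
cell_center_xy <- function(g, row, col) {
  cbind(x = g$origin[1] + (col - 0.5) * g$cell_size,
        y = g$origin[2] - (row - 0.5) * g$cell_size)
}

# containing cell of a projected point; NA row/col if off-grid
point_to_cell <- function(g, x, y) {
  col <- floor((x - g$origin[1]) / g$cell_size) + 1
  row <- floor((g$origin[2] - y) / g$cell_size) + 1
  bad <- row < 1 | row > nrow(g$values) | col < 1 | col > ncol(g$values)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}
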