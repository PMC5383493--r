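#' Read a single-band raster from disk
#'
#' Rasters are stored as ESRI ASCII grids (`.asc`) with a JSON sidecar
#' (`<path>.json`) carrying the CRS label and, for categorical layers, the
#' legend. Values are written at full double precision so a write/read
#' round trip reproduces values, cell size, origin and nodata cells exactly.
#'
#' @param path path to the `.asc` file.
#' @return a `raster_grid` (or `categorical_raster` when the sidecar carries
#'   a legend).
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop_burnsel("cannot read raster: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop_burnsel("malformed ASCII grid header in ", path)
  }
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop_burnsel("value count does not match header dimensions in ", path)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  origin <- c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize)
  side <- paste0(path, ".json")
  crs_label <- "albers-nad83"
  legend <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    crs_label <- meta$crs_label %||% crs_label
    if (!is.null(meta$legend)) legend <- unlist(meta$legend)
  }
  if (is.null(legend)) {
    raster_grid(m, hdr$cellsize, origin, hdr$nodata_value, crs_label)
  } else {
    categorical_raster(m, legend, hdr$cellsize, origin, hdr$nodata_value,
                       crs_label)
  }
}

#' Write a single-band raster to disk
#'
#' @param grid a `raster_grid` or `categorical_raster`.
#' @param path output path (`.asc`); a JSON sidecar `<path>.json` is written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  if (!inherits(grid, "raster_grid")) stop_burnsel("not a raster_grid")
  v <- grid$values
  if (any(v == grid$nodata, na.rm = TRUE)) {
    stop_burnsel("grid contains cells equal to the nodata sentinel ",
                 grid$nodata, "; choose a different sentinel")
  }
  v[is.na(v)] <- grid$nodata
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", grid$origin[1]),
    sprintf("yllcorner %.17g", grid$origin[2] - nr * grid$cell_size),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", grid$nodata)
  )
  body <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  meta <- list(crs_label = grid$crs_label)
  if (is_categorical(grid)) meta$legend <- as.list(grid$legend)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write every layer of a stack to a directory
#' @param stack a `landscape_stack`.
#' @param dir output directory (created if absent).
#' @return named vector of file paths, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(stack$layers), function(nm) {
    write_raster(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
    file.path(dir, paste0(nm, ".asc"))
  }, character(1))
  invisible(paths)
}

#' Read a directory of rasters as a stack
#' @param dir directory containing `.asc` layers written by [write_stack()].
#' @return a `landscape_stack`.
#' @export
read_stack <- function(dir) {
  files <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  if (!length(files)) stop_burnsel("no .asc layers in ", dir)
  layers <- lapply(files, read_raster)
  names(layers) <- sub("\\.asc$", "", basename(files))
  landscape_stack(layers)
}
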