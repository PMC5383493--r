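# Euclidean distance transforms. The exact transform itself comes from
# EBImage::distmap; everything here is the cell/metre bookkeeping and the
# masking semantics of the burn-edge and nibble operations.

# distance (in cells) from every cell to the nearest TRUE cell of `target`
dist_to_true_cells <- function(target) {
  if (!any(target)) stop_burnsel("no target cells")
  # distmap measures distance to the nearest 0-valued pixel
  as.matrix(EBImage::distmap(1 - (target + 0), metric = "euclidean"))
}

#' Distance to the nearest cell of given classes
#'
#' Per-cell Euclidean (centre-to-centre) distance in metres to the nearest
#' cell whose code is in `target_codes`; 0 on target cells. Used for the
#' distance-to-draw covariate, among others.
#'
#' @param mask a `categorical_raster`.
#' @param target_codes integer codes defining the target set.
#' @return a `raster_grid` of distances in metres (`NA` where `mask` is
#'   nodata).
#' @export
distance_to_class <- function(mask, target_codes) {
  v <- mask$values
  target <- !is.na(v) & v %in% target_codes
  if (!any(target)) stop_burnsel("no cells with the target codes")
  d <- dist_to_true_cells(target) * mask$cell_size
  d[is.na(v)] <- NA
  g <- mask
  g$values <- d
  g$legend <- NULL
  class(g) <- "raster_grid"
  g
}

#' Distance from burn cells to the nearest burn edge
#'
#' Defined inside the burn only: the distance to the nearest non-burn cell,
#' with the map boundary also counting as edge (so a burn covering the whole
#' grid still has finite distances). By default any unburned cell is edge,
#' including interior fire skips; set `skips_are_edge = FALSE` to treat cells
#' with codes in `skip_codes` as burn interior for this metric.
#'
#' @param burn a `categorical_raster` of burn classes.
#' @param burn_codes codes counted as burned (default: every code except 0
#'   and `skip_codes`). Pass `c(1:5)` to measure distance to the fire
#'   perimeter itself, treating skips as burn interior.
#' @param skips_are_edge logical; if `FALSE`, codes in `skip_codes` do not
#'   act as edge.
#' @param skip_codes codes of fire skips (default 5, see [burn_legend()]).
#' @return a `raster_grid`: distance in metres inside the burn, `NA`
#'   elsewhere.
#' @export
burn_edge_distance <- function(burn, burn_codes = NULL,
                               skips_are_edge = TRUE, skip_codes = 5) {
  v <- burn$values
  codes <- sort(unique(v[!is.na(v)]))
  if (is.null(burn_codes)) burn_codes <- setdiff(codes, c(0, skip_codes))
  inside <- !is.na(v) & v %in% burn_codes
  if (!any(inside)) stop_burnsel("burn mask is empty")
  interior <- inside
  if (!skips_are_edge) {
    interior <- interior | (!is.na(v) & v %in% skip_codes)
  }
  # pad with an edge ring so the map boundary counts as edge
  nr <- nrow(v); nc <- ncol(v)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- interior
  d <- dist_to_true_cells(!pad)[2:(nr + 1L), 2:(nc + 1L)] * burn$cell_size
  d[!inside] <- NA
  g <- burn
  g$values <- d
  g$legend <- NULL
  class(g) <- "raster_grid"
  g
}

#' Reassign masked cells to the nearest surrounding class (nibble)
#'
#' Every cell whose code is in `fill_codes` receives the code of the nearest
#' cell with a valid (non-fill) code, mirroring the GIS "nibble" cleanup of
#' "disturbed" land-cover pixels. Distances are Euclidean between cell
#' centres; exact distance ties between different classes are broken in
#' favour of the lower class code (and same-class ties are immaterial).
#'
#' @param landcover a `categorical_raster`.
#' @param fill_codes codes to be replaced.
#' @return a `categorical_raster` with no `fill_codes` cells remaining.
#' @export
nibble_reassign <- function(landcover, fill_codes) {
  v <- landcover$values
  valid <- !is.na(v) & !(v %in% fill_codes)
  if (!any(valid)) stop_burnsel("no non-fill cells to nibble from")
  fill <- !is.na(v) & v %in% fill_codes
  out <- v
  if (any(fill)) {
    src_codes <- sort(unique(v[valid]))
    best <- matrix(Inf, nrow(v), ncol(v))
    for (k in src_codes) {       # ascending: strict < keeps the lower code on ties
      dk <- dist_to_true_cells(!is.na(v) & v == k)
      take <- fill & (dk < best)
      out[take] <- k
      best <- pmin(best, dk)
    }
  }
  g <- landcover
  g$values <- out
  g$legend <- landcover$legend[!(names(landcover$legend) %in%
                                   as.character(fill_codes))]
  g
}
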