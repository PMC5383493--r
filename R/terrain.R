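# Terrain covariates: slope/aspect, heat load, D8 flow accumulation and the
# compound topographic index. Conventions: north-up grids, aspect measured
# clockwise from north as the downslope azimuth, flat cells flagged with the
# sentinel below.

#' Sentinel aspect value for flat cells
#' @export
FLAT_ASPECT <- -1

# shift a matrix by (dr, dc), padding with NA
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Slope and aspect from a DEM
#'
#' Central differences in the grid interior and one-sided differences on the
#' map edge. Slope is in degrees from horizontal; aspect is the downslope
#' azimuth in degrees clockwise from north, with flat cells (zero gradient)
#' set to [FLAT_ASPECT].
#'
#' @param dem a `raster_grid` of elevations in metres (at least 3x3 cells).
#' @return a list with `slope` and `aspect` raster grids.
#' @export
slope_aspect <- function(dem) {
  z <- dem$values
  if (nrow(z) < 3L || ncol(z) < 3L) stop_burnsel("dem must be at least 3x3")
  if (all(is.na(z))) stop_burnsel("dem is entirely nodata")
  cs <- dem$cell_size
  east <- shift_mat(z, 0L, 1L); west <- shift_mat(z, 0L, -1L)
  north <- shift_mat(z, -1L, 0L); south <- shift_mat(z, 1L, 0L)
  # central differences, degrading to one-sided where a neighbour is missing
  gx <- (east - west) / (2 * cs)
  gx[is.na(gx)] <- ((east - z) / cs)[is.na(gx)]
  gx[is.na(gx)] <- ((z - west) / cs)[is.na(gx)]
  gy <- (north - south) / (2 * cs)   # positive northward
  gy[is.na(gy)] <- ((north - z) / cs)[is.na(gy)]
  gy[is.na(gy)] <- ((z - south) / cs)[is.na(gy)]
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  flat <- !is.na(slope) & slope == 0
  aspect[flat] <- FLAT_ASPECT
  aspect[is.na(slope)] <- NA
  sg <- dem; sg$values <- slope
  ag <- dem; ag$values <- aspect
  list(slope = sg, aspect = ag)
}

#' Heat load index
#'
#' Terrain proxy for incident heat combining latitude, slope and aspect
#' folded about southwest (225 deg), so that southwest-facing slopes score
#' highest and northeast-facing lowest at equal steepness. Uses the
#' exponential-form folded-aspect equation
#' `exp(-1.467 + 1.582 cos(L) cos(S) - 1.500 cos(A') sin(S) sin(L)
#'      - 0.262 sin(L) sin(S) + 0.607 sin(A') sin(S))`
#' with `A' = |180 - |aspect - 225||` (variant tag `"mccune-keon-exp"`,
#' recorded in the returned grid's `hli_equation` attribute). Flat cells are
#' aspect-invariant because every aspect term is scaled by `sin(S)`.
#'
#' @param slope_deg slope grid in degrees.
#' @param aspect_deg aspect grid in degrees clockwise from north
#'   ([FLAT_ASPECT] allowed on flat cells).
#' @param latitude_deg site latitude in decimal degrees, in (0, 60).
#' @return a `raster_grid` of unitless heat-load values.
#' @export
heat_load_index <- function(slope_deg, aspect_deg, latitude_deg) {
  assert_scalar_num(latitude_deg, "latitude_deg")
  if (latitude_deg <= 0 || latitude_deg >= 60) {
    stop_burnsel("`latitude_deg` must be in (0, 60)")
  }
  if (!same_geometry(slope_deg, aspect_deg)) {
    stop_burnsel("slope and aspect grids are not co-registered")
  }
  s <- slope_deg$values * pi / 180
  a <- aspect_deg$values
  a[a == FLAT_ASPECT] <- 0  # immaterial: sin(S) = 0 on flat cells
  af <- abs(180 - abs(a - 225)) * pi / 180
  l <- latitude_deg * pi / 180
  v <- exp(-1.467 + 1.582 * cos(l) * cos(s) -
             1.500 * cos(af) * sin(s) * sin(l) -
             0.262 * sin(l) * sin(s) + 0.607 * sin(af) * sin(s))
  g <- slope_deg
  g$values <- v
  attr(g, "hli_equation") <- "mccune-keon-exp"
  g
}

# D8 neighbour offsets, clockwise from north (the tie-break order)
D8_DR <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
D8_DC <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

#' D8 flow accumulation
#'
#' Single-direction (D8) routing: each cell drains to the neighbour with the
#' steepest downhill drop (drop / centre distance), ties going to the first
#' neighbour in clockwise-from-north order. Cells on a flat with no strictly
#' lower neighbour drain iteratively toward the nearest cell that does have
#' a lower neighbour; true pits keep everything they receive. Accumulation
#' is the upstream contributing area in square metres, own cell included.
#'
#' @param dem a `raster_grid` of elevations (at least 3x3).
#' @return a `raster_grid` of contributing areas in square metres.
#' @export
flow_accumulation <- function(dem) {
  z <- dem$values
  if (nrow(z) < 3L || ncol(z) < 3L) stop_burnsel("dem must be at least 3x3")
  if (all(is.na(z))) stop_burnsel("dem is entirely nodata")
  nr <- nrow(z); nc <- ncol(z); n <- nr * nc
  cs <- dem$cell_size
  idx <- matrix(seq_len(n), nr, nc)
  recv <- integer(n)          # 0 = sink / unresolved
  best <- rep(-Inf, n)
  for (k in seq_along(D8_DR)) {
    zn <- shift_mat(z, D8_DR[k], D8_DC[k])
    nb <- shift_mat(idx + 0, D8_DR[k], D8_DC[k])
    d <- cs * sqrt(D8_DR[k]^2 + D8_DC[k]^2)
    grad <- as.vector((z - zn) / d)
    take <- which(!is.na(grad) & grad > 0 & grad > best)  # strict: first in order wins ties
    recv[take] <- as.integer(nb[take])
    best[take] <- grad[take]
  }
  # flats: route to an equal-elevation neighbour that is already resolved,
  # preferring the earliest resolved wave (i.e. nearest exit), then the
  # clockwise-from-north neighbour order
  flat <- which(recv == 0L & !is.na(z))
  repeat {
    changed <- FALSE
    for (i in flat) {
      if (recv[i] != 0L) next
      r <- (i - 1L) %% nr + 1L; cc <- (i - 1L) %/% nr + 1L
      for (k in seq_along(D8_DR)) {
        r2 <- r + D8_DR[k]; c2 <- cc + D8_DC[k]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        j <- idx[r2, c2]
        if (!is.na(z[j]) && z[j] == z[i] && recv[j] != 0L && recv[j] != i) {
          recv[i] <- j
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  # Kahn accumulation over the (acyclic) receiver forest
  acc <- rep(1, n); acc[is.na(as.vector(z))] <- NA
  indeg <- tabulate(recv[recv > 0L], nbins = n)
  queue <- integer(n)
  ready <- which(indeg == 0L & !is.na(as.vector(z)))
  queue[seq_along(ready)] <- ready
  tail <- length(ready); head <- 1L
  while (head <= tail) {
    i <- queue[head]; head <- head + 1L
    j <- recv[i]
    if (j > 0L) {
      acc[j] <- acc[j] + acc[i]
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) {
        tail <- tail + 1L
        queue[tail] <- j
      }
    }
  }
  g <- dem
  g$values <- matrix(acc * cs^2, nr, nc)
  g
}

#' Compound topographic index (wetness)
#'
#' `CTI = ln(a / tan(beta))` with `a` the specific contributing area
#' (contributing area divided by cell width, m^2 per m) and `beta` the slope,
#' floored at `slope_floor_rad` so flat cells take the capped maximum rather
#' than dividing by zero.
#'
#' @param flow_acc contributing-area grid from [flow_accumulation()] (m^2).
#' @param slope_deg slope grid in degrees.
#' @param slope_floor_rad minimum slope in radians (default 0.001).
#' @return a `raster_grid` of wetness-index values.
#' @export
compound_topographic_index <- function(flow_acc, slope_deg,
                                       slope_floor_rad = 0.001) {
  if (!same_geometry(flow_acc, slope_deg)) {
    stop_burnsel("flow accumulation and slope grids are not co-registered")
  }
  a <- flow_acc$values / flow_acc$cell_size
  beta <- pmax(slope_deg$values * pi / 180, slope_floor_rad)
  g <- flow_acc
  g$values <- log(a / tan(beta))
  g
}

#' Draw (convergent-drainage) mask
#'
#' A "draw" is operationalised as a cell whose flow accumulation is at or
#' above a high quantile of the study-area distribution; the distance to the
#' nearest such cell is the distance-to-draw covariate.
#'
#' @param flow_acc contributing-area grid.
#' @param quantile_threshold quantile defining draws (default 0.95).
#' @return a `categorical_raster` (1 = draw, 0 = not).
#' @export
draw_mask <- function(flow_acc, quantile_threshold = 0.95) {
  v <- flow_acc$values
  thr <- stats::quantile(v, quantile_threshold, na.rm = TRUE, names = FALSE)
  m <- (v >= thr) + 0
  categorical_raster(m, c("0" = "other", "1" = "draw"), flow_acc$cell_size,
                     flow_acc$origin, flow_acc$nodata, flow_acc$crs_label)
}
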