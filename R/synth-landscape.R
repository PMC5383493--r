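# Synthetic fire-mosaic landscapes. Every categorical layer is allocated by
# rank-thresholding a correlated Gaussian field, which (i) yields spatially
# coherent patches and (ii) hits the requested area fractions to within one
# cell. A master seed streams fixed per-layer offsets so layers are
# individually reproducible.

LANDCOVER_LEGEND <- c(
  "1" = "lodgepole", "2" = "sprucefir", "3" = "dryforest",
  "4" = "mixedforest", "5" = "deciduous", "6" = "grassy_meadow",
  "7" = "shrubby_meadow", "8" = "barren"
)

default_landcover_proportions <- function() {
  # rows = elevation bands (low -> high), columns = the eight cover classes;
  # dry forest dominates the low band, spruce-fir the top band
  p <- rbind(
    low  = c(lodgepole = 0.10, sprucefir = 0.02, dryforest = 0.40,
             mixedforest = 0.20, deciduous = 0.10, grassy_meadow = 0.10,
             shrubby_meadow = 0.05, barren = 0.03),
    mid  = c(lodgepole = 0.30, sprucefir = 0.20, dryforest = 0.10,
             mixedforest = 0.20, deciduous = 0.05, grassy_meadow = 0.05,
             shrubby_meadow = 0.07, barren = 0.03),
    high = c(lodgepole = 0.25, sprucefir = 0.45, dryforest = 0.02,
             mixedforest = 0.05, deciduous = 0.01, grassy_meadow = 0.07,
             shrubby_meadow = 0.05, barren = 0.10)
  )
  p
}

#' Configuration for a synthetic fire-mosaic landscape
#'
#' The two shipped presets encode the published within-perimeter burn-class
#' compositions: `"tripod"` (new 2006 burn: 63 % high severity, 8 % low
#' severity, 21 % fire skips, 8 % older 1994 burn) and `"whiteface"`
#' (old 1994 burn: 82 % high, 10 % low, 8 % skip). Elevations span
#' 855-2390 m for tripod and 1280-2222 m for whiteface.
#'
#' @param preset `"tripod"`, `"whiteface"`, or `NULL` for explicit values.
#' @param shape grid dimensions `(rows, cols)`.
#' @param cell_size cell edge in metres.
#' @param seed master integer seed.
#' @param latitude_deg site latitude.
#' @param elevation_range `(min, max)` elevation in metres.
#' @param burn_fractions named fractions over
#'   `new_high, new_low, old_high, old_low, skip` of the area inside the
#'   fire perimeter; each in \[0,1\], summing to at most 1 (any remainder is
#'   treated as additional skip).
#' @param perimeter_fraction target fraction of the map inside the burn
#'   perimeter.
#' @param landcover_proportions matrix (elevation bands x 8 classes), rows
#'   summing to 1.
#' @param correlation_lengths named list of field correlation scales in
#'   metres (`dem`, `perimeter`, `burn`, `landcover`, `canopy`, `precip`).
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(preset = NULL, shape = c(300, 300),
                             cell_size = 30, seed = 1, latitude_deg = 48.5,
                             elevation_range = c(855, 2390),
                             burn_fractions = c(new_high = 0.63,
                                                new_low = 0.08,
                                                old_high = 0.08,
                                                old_low = 0,
                                                skip = 0.21),
                             perimeter_fraction = 0.5,
                             landcover_proportions =
                               default_landcover_proportions(),
                             correlation_lengths = list(
                               dem = 3000, perimeter = 4000, burn = 600,
                               landcover = 400, canopy = 300, precip = 1500)) {
  if (!is.null(preset)) {
    presets <- list(
      tripod = list(elevation_range = c(855, 2390),
                    burn_fractions = c(new_high = 0.63, new_low = 0.08,
                                       old_high = 0.08, old_low = 0,
                                       skip = 0.21)),
      whiteface = list(elevation_range = c(1280, 2222),
                       burn_fractions = c(new_high = 0, new_low = 0,
                                          old_high = 0.82, old_low = 0.10,
                                          skip = 0.08))
    )
    if (!preset %in% names(presets)) {
      stop_burnsel("unknown preset `", preset, "`; valid presets: ",
                   paste(names(presets), collapse = ", "))
    }
    elevation_range <- presets[[preset]]$elevation_range
    burn_fractions <- presets[[preset]]$burn_fractions
  }
  need <- c("new_high", "new_low", "old_high", "old_low", "skip")
  if (!all(need %in% names(burn_fractions))) {
    stop_burnsel("`burn_fractions` must name: ", paste(need, collapse = ", "))
  }
  burn_fractions <- burn_fractions[need]
  if (any(burn_fractions < 0 | burn_fractions > 1) ||
      sum(burn_fractions) > 1 + 1e-9) {
    stop_burnsel("burn fractions must lie in [0,1] and sum to at most 1")
  }
  if (any(abs(rowSums(landcover_proportions) - 1) > 1e-8)) {
    stop_burnsel("each land-cover band's proportions must sum to 1")
  }
  if (any(unlist(correlation_lengths) <= cell_size)) {
    stop_burnsel("all correlation lengths must exceed the cell size")
  }
  structure(list(
    preset = preset, shape = as.integer(shape), cell_size = cell_size,
    seed = as.integer(seed), latitude_deg = latitude_deg,
    elevation_range = elevation_range, burn_fractions = burn_fractions,
    perimeter_fraction = perimeter_fraction,
    landcover_proportions = landcover_proportions,
    correlation_lengths = correlation_lengths
  ), class = "landscape_config")
}

#' Generate a synthetic DEM
#'
#' Smooth correlated surface rescaled linearly so its minimum and maximum
#' equal the configured elevation bounds exactly.
#'
#' @param config a [landscape_config()].
#' @return a `raster_grid` of elevations in metres.
#' @export
generate_dem <- function(config) {
  f <- generate_field(config$shape, config$correlation_lengths$dem,
                      derive_seed(config$seed, 1L), config$cell_size)
  rescale_grid(f, config$elevation_range[1], config$elevation_range[2])
}

# assign ranked field values to classes with given cell counts;
# `order_codes` fixes which class occupies the low end of the field
allocate_by_rank <- function(field_vals, counts, codes) {
  stopifnot(length(counts) == length(codes))
  out <- rep(NA_real_, length(field_vals))
  ord <- order(field_vals)
  pos <- 1L
  for (i in seq_along(codes)) {
    if (counts[i] > 0L) {
      out[ord[pos:(pos + counts[i] - 1L)]] <- codes[i]
      pos <- pos + counts[i]
    }
  }
  out
}

#' Generate a fire-mosaic burn raster
#'
#' Builds a simply connected fire perimeter (the largest connected blob of a
#' long-range correlated field, morphologically closed and hole-filled) and
#' allocates burn classes inside it by rank-thresholding a second correlated
#' field, so the within-perimeter class fractions hit their targets to
#' within one cell. Any fraction left over after the named classes becomes
#' additional skip (unburned-inside) area.
#'
#' @param dem DEM grid (supplies the geometry).
#' @param config a [landscape_config()].
#' @return a `categorical_raster` with codes 0 = outside the perimeter,
#'   1-4 = the burn classes of [burn_legend()], 5 = fire skip.
#' @export
generate_burn_mosaic <- function(dem, config) {
  fr <- config$burn_fractions
  if (sum(fr) > 1 + 1e-9) stop_burnsel("infeasible burn fractions")
  per_field <- generate_field(config$shape, config$correlation_lengths$perimeter,
                              derive_seed(config$seed, 2L), config$cell_size)
  v <- per_field$values
  thr <- stats::quantile(v, 1 - config$perimeter_fraction, names = FALSE)
  cand <- v >= thr
  lab <- EBImage::bwlabel(cand + 0)
  tab <- tabulate(as.vector(lab)[as.vector(lab) > 0])
  biggest <- which.max(tab)
  blob <- (lab == biggest) + 0
  blob <- EBImage::closing(blob, EBImage::makeBrush(5, shape = "disc"))
  blob <- EBImage::fillHull(blob)
  perimeter <- as.matrix(blob) > 0
  n_in <- sum(perimeter)
  if (n_in < 10L) stop_burnsel("degenerate fire perimeter; adjust config")
  # Each class takes the top-ranked cells of its own correlated field among
  # the cells still unassigned, so the spatial patterns of, say, fire skips
  # and high-severity burn are driven by independent processes (as fuel
  # moisture and fire weather are) rather than being rank-complements of
  # one another. Classes are placed smallest-first; the largest class
  # absorbs the remaining cells, keeping every fraction exact to one cell.
  codes <- c(skip = 5, old_high = 3, old_low = 4, new_low = 2,
             new_high = 1)
  fracs <- c(fr[["skip"]] + max(0, 1 - sum(fr)), fr[["old_high"]],
             fr[["old_low"]], fr[["new_low"]], fr[["new_high"]])
  counts <- floor(fracs * n_in)
  counts[which.max(fracs)] <- counts[which.max(fracs)] +
    (n_in - sum(counts))  # rounding remainder to the largest class
  out <- matrix(0, config$shape[1], config$shape[2])
  remaining <- which(perimeter)
  ord <- order(counts)
  for (i in ord[-length(ord)]) {
    if (counts[i] == 0L) next
    f <- generate_field(config$shape, config$correlation_lengths$burn,
                        derive_seed(config$seed, 30L + i), config$cell_size)
    take <- remaining[order(-f$values[remaining])[seq_len(counts[i])]]
    out[take] <- codes[i]
    remaining <- setdiff(remaining, take)
  }
  out[remaining] <- codes[ord[length(ord)]]
  categorical_raster(out, burn_legend(with_skip = TRUE), config$cell_size,
                     dem$origin, crs_label = dem$crs_label)
}

#' Generate land cover along the elevation gradient
#'
#' Splits the DEM into as many elevation bands as the configured proportion
#' matrix has rows (equal-count quantile bands) and allocates the eight
#' cover classes inside each band by rank-thresholding a correlated field,
#' so band-wise class proportions are achieved to within one cell.
#'
#' @param dem DEM grid.
#' @param config a [landscape_config()].
#' @return a `categorical_raster` with legend `LANDCOVER_LEGEND`.
#' @export
generate_landcover <- function(dem, config) {
  p <- config$landcover_proportions
  nb <- nrow(p)
  z <- as.vector(dem$values)
  qs <- stats::quantile(z, probs = seq(0, 1, length.out = nb + 1L),
                        names = FALSE)
  band <- findInterval(z, qs[-c(1, nb + 1L)]) + 1L  # 1..nb
  f <- generate_field(config$shape, config$correlation_lengths$landcover,
                      derive_seed(config$seed, 4L), config$cell_size)
  fv <- as.vector(f$values)
  out <- rep(NA_real_, length(z))
  for (b in seq_len(nb)) {
    cells <- which(band == b)
    counts <- floor(p[b, ] * length(cells))
    counts[which.max(counts)] <- counts[which.max(counts)] +
      (length(cells) - sum(counts))
    out[cells] <- allocate_by_rank(fv[cells], as.integer(counts), 1:8)
  }
  categorical_raster(matrix(out, config$shape[1], config$shape[2]),
                     LANDCOVER_LEGEND, config$cell_size, dem$origin,
                     crs_label = dem$crs_label)
}

#' Generate canopy cover and growing-season precipitation
#'
#' Canopy cover (percent) is a correlated baseline surface in which
#' new high-severity burn cells are overwritten with draws from a
#' low-canopy distribution (blackened snags), new low-severity and old burn
#' cells with intermediate cover, and fire skips keep the intact baseline.
#' Growing-season precipitation increases linearly with elevation plus
#' correlated noise.
#'
#' @param dem DEM grid.
#' @param burn burn-mosaic raster from [generate_burn_mosaic()].
#' @param config a [landscape_config()].
#' @return list with `canopy_pct` and `gs_precip` raster grids.
#' @export
generate_canopy_and_climate <- function(dem, burn, config) {
  # Class-conditional canopy distributions overlap substantially (residual
  # trees and patchy regeneration keep some cover even after severe fire,
  # and intact stands vary widely), as the corresponding GIS layers do; the
  # class means still order as severity dictates.
  base <- rescale_grid(
    generate_field(config$shape, config$correlation_lengths$canopy,
                   derive_seed(config$seed, 5L), config$cell_size), 30, 95)
  low <- rescale_grid(
    generate_field(config$shape, config$correlation_lengths$canopy,
                   derive_seed(config$seed, 6L), config$cell_size), 0, 45)
  regen <- rescale_grid(
    generate_field(config$shape, config$correlation_lengths$canopy,
                   derive_seed(config$seed, 8L), config$cell_size), 20, 75)
  canopy <- base$values
  b <- burn$values
  canopy[b == 1] <- low$values[b == 1]                 # new high severity
  canopy[b == 2] <- 0.70 * canopy[b == 2] + 5          # new low severity
  canopy[b == 3] <- regen$values[b == 3]               # old high, regenerating
  canopy[b == 4] <- 0.85 * canopy[b == 4] + 5          # old low
  canopy <- pmin(pmax(canopy, 0), 100)
  cg <- dem; cg$values <- canopy
  noise <- generate_field(config$shape, config$correlation_lengths$precip,
                          derive_seed(config$seed, 7L), config$cell_size)
  elev_norm <- (dem$values - config$elevation_range[1]) /
    diff(config$elevation_range)
  pg <- dem
  pg$values <- 200 + 400 * elev_norm + 40 * noise$values
  list(canopy_pct = cg, gs_precip = pg)
}

#' Build the full covariate stack for a synthetic landscape
#'
#' Runs every generator and every covariate derivation, producing the
#' co-registered stack the habitat models consume: terrain (slope, heat
#' load, wetness), burn structure (class fractions at the 3x3 `_s` and
#' 27x27 `_l` focal scales, distance to the burn edge, distance to the
#' nearest draw), land-cover composition, canopy cover and growing-season
#' precipitation.
#'
#' @param config a [landscape_config()].
#' @param scales window widths (cells) for the focal scales, default
#'   `c(s = 3, l = 27)`.
#' @param draw_quantile flow-accumulation quantile defining draws.
#' @return a `landscape_stack`.
#' @export
build_landscape <- function(config, scales = c(s = 3, l = 27),
                            draw_quantile = 0.95) {
  dem <- generate_dem(config)
  sa <- slope_aspect(dem)
  hli <- heat_load_index(sa$slope, sa$aspect, config$latitude_deg)
  fa <- flow_accumulation(dem)
  cti <- compound_topographic_index(fa, sa$slope)
  burn <- generate_burn_mosaic(dem, config)
  lc0 <- generate_landcover(dem, config)
  cc <- generate_canopy_and_climate(dem, burn, config)
  edge <- burn_edge_distance(burn, burn_codes = c(1, 2, 3, 4, 5))
  draws <- draw_mask(fa, draw_quantile)
  ddraw <- distance_to_class(draws, 1)
  layers <- list(
    dem = dem, slope = sa$slope, aspect = sa$aspect, hli = hli, cti = cti,
    burn_class = burn, landcover = lc0, canopy = cc$canopy_pct,
    gs_precip = cc$gs_precip, dist_edge = edge, dist_draw = ddraw
  )
  frac_specs <- list(
    frac_new_high = 1, frac_new_low = 2, frac_old = c(3, 4), frac_skip = 5
  )
  lc_specs <- list(frac_sprucefir = 2, frac_dryforest = 3)
  for (sc in names(scales)) {
    w <- scales[[sc]]
    layers[[paste0("canopy_", sc)]] <- focal_mean(cc$canopy_pct, w)
    for (nm in names(frac_specs)) {
      layers[[paste0(nm, "_", sc)]] <-
        focal_fraction(burn, frac_specs[[nm]], w)
    }
    for (nm in names(lc_specs)) {
      layers[[paste0(nm, "_", sc)]] <-
        focal_fraction(lc0, lc_specs[[nm]], w)
    }
  }
  landscape_stack(layers)
}
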