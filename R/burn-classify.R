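# Burn-class codes used throughout the package. Severity follows the canopy
# cover loss rule: 1-50 % loss = low severity, above 50 % = high severity
# (the published cut prints "1-50%" and ">51%", leaving (50, 51] undefined;
# low <= 50 < high makes the partition exhaustive). "New" vs "old" splits on
# fire age relative to the analysis year.

#' Legend of burn classes
#'
#' @param with_skip include the fire-skip code (5) used by the mosaic
#'   generator, where "skip" means unburned forest inside the fire perimeter.
#' @return named character vector mapping code to class name.
#' @export
burn_legend <- function(with_skip = FALSE) {
  l <- c("0" = "unburned", "1" = "new_high", "2" = "new_low",
         "3" = "old_high", "4" = "old_low")
  if (with_skip) l <- c(l, "5" = "skip")
  l
}

#' Classify burn severity and age
#'
#' Combines per-cell canopy cover loss with the year each cell last burned
#' into the four burn categories (new/old x high/low severity) plus
#' unburned. Cells with zero canopy loss, or that never burned
#' (`burn_year = 0`), are unburned.
#'
#' @param canopy_loss_pct `raster_grid` of canopy cover loss, percent
#'   in \[0, 100\].
#' @param burn_year_map `categorical_raster` of the year each cell burned
#'   (0 = never burned).
#' @param analysis_year year of the analysis (e.g. the telemetry midpoint).
#' @param new_age_max maximum age in years for a burn to count as "new"
#'   (default 10; e.g. a 2006 fire is new and a 1994 fire old for
#'   2007-2013 telemetry).
#' @return a `categorical_raster` with legend [burn_legend()].
#' @export
classify_burn <- function(canopy_loss_pct, burn_year_map, analysis_year,
                          new_age_max = 10) {
  if (!same_geometry(canopy_loss_pct, burn_year_map)) {
    stop_burnsel("canopy-loss and burn-year grids are not co-registered")
  }
  loss <- canopy_loss_pct$values
  if (any(loss < 0 | loss > 100, na.rm = TRUE)) {
    stop_burnsel("canopy loss must be within [0, 100] percent")
  }
  yr <- burn_year_map$values
  burned <- !is.na(yr) & yr > 0 & !is.na(loss) & loss > 0
  is_new <- burned & (analysis_year - yr) <= new_age_max
  is_high <- loss > 50
  out <- matrix(0, nrow(loss), ncol(loss))
  out[burned & is_new & is_high] <- 1
  out[burned & is_new & !is_high] <- 2
  out[burned & !is_new & is_high] <- 3
  out[burned & !is_new & !is_high] <- 4
  out[is.na(loss) | is.na(yr)] <- NA
  categorical_raster(out, burn_legend(), canopy_loss_pct$cell_size,
                     canopy_loss_pct$origin, canopy_loss_pct$nodata,
                     canopy_loss_pct$crs_label)
}
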