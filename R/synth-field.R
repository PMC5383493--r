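# Correlated Gaussian random fields by spectral synthesis: white noise is
# filtered in the Fourier domain with a Gaussian kernel, giving an
# approximately Gaussian-covariance stationary field in O(n log n). The
# field is periodic across the map edge, which is harmless for synthetic
# landscapes and keeps the variance exactly controllable.

#' Generate a correlated Gaussian random field
#'
#' Zero-mean, unit-variance stationary random surface whose spatial
#' correlation decays on the scale of `correlation_length`. Identical seeds
#' give identical fields.
#'
#' @param shape integer vector `(rows, cols)`.
#' @param correlation_length correlation scale in metres (must exceed the
#'   cell size).
#' @param seed integer seed.
#' @param cell_size cell edge in metres (default 30).
#' @param amplitude standard deviation of the output (default 1; 0 gives a
#'   flat zero surface).
#' @param origin,crs_label passed to [raster_grid()].
#' @return a `raster_grid` with standardized values scaled by `amplitude`.
#' @export
generate_field <- function(shape, correlation_length, seed, cell_size = 30,
                           amplitude = 1, origin = c(0, 0),
                           crs_label = "albers-nad83") {
  if (length(shape) != 2L || any(shape < 2)) {
    stop_burnsel("`shape` must be (rows, cols), both >= 2")
  }
  assert_scalar_num(correlation_length, "correlation_length")
  if (correlation_length <= cell_size) {
    stop_burnsel("`correlation_length` must exceed the cell size")
  }
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  w <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  # Gaussian spectral filter; wavenumbers in cycles per metre
  fr <- c(seq(0, floor(nr / 2)), seq(-ceiling(nr / 2) + 1, -1)) / (nr * cell_size)
  fc <- c(seq(0, floor(nc / 2)), seq(-ceiling(nc / 2) + 1, -1)) / (nc * cell_size)
  k2 <- outer(fr^2, fc^2, `+`)
  filt <- exp(-(pi * correlation_length)^2 * k2)
  f <- Re(stats::fft(stats::fft(w) * filt, inverse = TRUE)) / (nr * nc)
  f <- (f - mean(f)) / stats::sd(f) * amplitude
  raster_grid(f, cell_size, origin, crs_label = crs_label)
}

# rescale a grid's values linearly onto [lo, hi] (exactly attained)
rescale_grid <- function(grid, lo, hi) {
  v <- grid$values
  rng <- range(v, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    v[] <- (lo + hi) / 2
  } else {
    v <- lo + (v - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
  }
  grid$values <- v
  grid
}
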