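#' Spatially intensity-weighted subsample
#'
#' Splits the points into a training fraction and a holdout, with per-point
#' inclusion probability weighted by the inverse of the local point density
#' (a Gaussian kernel intensity estimate on the projected coordinates).
#' Spatially clustered points are thus thinned out of the training set,
#' reducing the weight of oversampled neighbourhoods; under a uniform
#' pattern every point is included with probability ~= `fraction`.
#'
#' @param table a data frame with `x`, `y` columns (rows = points).
#' @param fraction training fraction (default 0.8, leaving 20 % as an
#'   independent validation set).
#' @param seed integer seed.
#' @param bandwidth kernel bandwidth in metres; the default smooths at a
#'   quarter of the mean bounding-box side, broad enough that the sampling
#'   noise of a homogeneous pattern is not mistaken for structure while
#'   genuine clusters still stand out.
#' @return list with integer row indices `train` and `holdout`
#'   (disjoint, exhaustive; `length(train) == round(fraction * n)`).
#' @export
spatial_subsample <- function(table, fraction = 0.8, seed = 1,
                              bandwidth = NULL) {
  n <- nrow(table)
  if (n < 5) stop_burnsel("need at least 5 points to subsample")
  if (fraction <= 0 || fraction >= 1) {
    stop_burnsel("`fraction` must be in (0, 1)")
  }
  x <- table$x; y <- table$y
  if (is.null(bandwidth)) {
    bandwidth <- mean(c(diff(range(x)), diff(range(y)))) / 4
  }
  if (bandwidth <= 0) bandwidth <- 1
  # Gaussian kernel intensity at each point (including itself), with a
  # box-window edge correction so boundary points are not spuriously
  # down-weighted (the correction divides by the kernel mass falling inside
  # the points' bounding box)
  dx <- outer(x, x, `-`) / bandwidth
  dy <- outer(y, y, `-`) / bandwidth
  edge <- (stats::pnorm((max(x) - x) / bandwidth) -
             stats::pnorm((min(x) - x) / bandwidth)) *
    (stats::pnorm((max(y) - y) / bandwidth) -
       stats::pnorm((min(y) - y) / bandwidth))
  intensity <- rowMeans(exp(-0.5 * (dx^2 + dy^2))) / pmax(edge, 1e-12)
  w <- 1 / pmax(intensity, .Machine$double.eps)
  n_train <- round(fraction * n)
  with_seed(seed, {
    train <- sort(sample.int(n, n_train, prob = w))
    list(train = train, holdout = setdiff(seq_len(n), train))
  })
}
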