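# GPS telemetry simulation with a known selection function, and the
# used/available sampling design: study areas delineated by buffering step
# paths, used points extracted from fixes, and equal-count random available
# points.

#' Movement / selection simulation parameters
#'
#' Defaults encode the study conditions of the emulated telemetry: 4-hour
#' fix schedule with a mean straight-line step of 766 m between fix
#' attempts and a 72 % fix success rate. Selection strength is expressed as
#' coefficients on standardized covariate layers, the synthetic ground
#' truth against which the habitat models are validated.
#'
#' @param beta named numeric vector of selection coefficients; names must be
#'   stack layer names. Coefficients act on layers standardized over the
#'   study area (zero mean, unit sd).
#' @param step_mean mean step length in metres (default 766).
#' @param step_shape gamma shape of the step-length distribution (default 2;
#'   positive and right-skewed, as movement steps are).
#' @param n_candidates candidate endpoints per step (default 20).
#' @param fix_success probability a chosen location is actually recorded
#'   (default 0.72).
#' @param n_steps number of 4-hour steps to simulate (default 2190, one
#'   year).
#' @param n_animals number of animals (default 1).
#' @param seed integer seed.
#' @return a `movement_config` list.
#' @export
movement_config <- function(beta = c(), step_mean = 766, step_shape = 2,
                            n_candidates = 20, fix_success = 0.72,
                            n_steps = 2190, n_animals = 1, seed = 1) {
  if (fix_success <= 0 || fix_success > 1) {
    stop_burnsel("`fix_success` must be in (0, 1]")
  }
  if (n_candidates < 2) stop_burnsel("`n_candidates` must be >= 2")
  structure(list(beta = beta, step_mean = step_mean, step_shape = step_shape,
                 n_candidates = as.integer(n_candidates),
                 fix_success = fix_success, n_steps = as.integer(n_steps),
                 n_animals = as.integer(n_animals), seed = as.integer(seed)),
            class = "movement_config")
}

# standardized layer matrices for the coefficients' layers
standardized_layers <- function(stack, layer_names) {
  miss <- setdiff(layer_names, names(stack$layers))
  if (length(miss)) {
    stop_burnsel("beta names a layer not in the stack: ",
                 paste(miss, collapse = ", "))
  }
  lapply(stack$layers[layer_names], function(g) {
    v <- g$values
    (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  })
}

#' Simulate a GPS telemetry track over a landscape
#'
#' Discrete-choice movement: at each 4-hour step, `n_candidates` candidate
#' endpoints are drawn (gamma step length, uniform heading; candidates off
#' the map or on nodata cells are redrawn) and one is chosen with
#' probability proportional to `exp(sum(beta * covariates))` at the
#' candidate. The chosen location is recorded as a fix with probability
#' `fix_success`; missed fixes leave gaps, as real collars do.
#'
#' @param stack a `landscape_stack` of covariates.
#' @param config a [movement_config()].
#' @param start optional `(x, y)` start; defaults to the centre-most valid
#'   cell.
#' @param animal_id id token for the output (default `"A1"`).
#' @return a `telemetry_track`: data frame of recorded fixes
#'   (`animal_id`, `time` in hours, `x`, `y`) with attributes `n_attempts`,
#'   `n_recorded` and `step_lengths` (all realized movement steps).
#' @export
simulate_track <- function(stack, config, start = NULL, animal_id = "A1") {
  ref <- stack$layers[[1]]
  zl <- standardized_layers(stack, names(config$beta))
  valid <- !Reduce(`|`, c(list(matrix(FALSE, nrow(ref$values), ncol(ref$values))),
                          lapply(stack$layers[names(config$beta)],
                                 function(g) is.na(g$values))))
  if (is.null(start)) {
    ctr <- c(nrow(ref$values), ncol(ref$values)) / 2
    cand <- which(valid, arr.ind = TRUE)
    if (!nrow(cand)) stop_burnsel("no valid start cell")
    i <- which.min((cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2)
    start <- as.numeric(cell_center_xy(ref, cand[i, 1], cand[i, 2]))
  }
  rc0 <- point_to_cell(ref, start[1], start[2])
  if (any(is.na(rc0)) || !valid[rc0[1, "row"], rc0[1, "col"]]) {
    stop_burnsel("start location is off-map or on a nodata cell")
  }
  K <- config$n_candidates
  scale <- config$step_mean / config$step_shape
  with_seed(config$seed, {
    pos <- start
    xs <- numeric(config$n_steps); ys <- numeric(config$n_steps)
    rec <- logical(config$n_steps)
    steps <- numeric(config$n_steps)
    for (t in seq_len(config$n_steps)) {
      # Off-map / nodata candidates redraw the heading but keep the sampled
      # length, so map edges do not truncate the step-length distribution;
      # a length that fits in no direction is redrawn entirely.
      len <- stats::rgamma(K, shape = config$step_shape, scale = scale)
      ang <- stats::runif(K, 0, 2 * pi)
      cx <- cy <- numeric(K); cr <- cc <- integer(K)
      ok <- rep(FALSE, K)
      tries <- 0L
      while (!all(ok)) {
        idx <- which(!ok)
        px <- pos[1] + len[idx] * sin(ang[idx])
        py <- pos[2] + len[idx] * cos(ang[idx])
        rc <- point_to_cell(ref, px, py)
        good <- !is.na(rc[, "row"]) &
          valid[cbind(rc[, "row"], rc[, "col"])]
        hit <- idx[good]
        cx[hit] <- px[good]; cy[hit] <- py[good]
        cr[hit] <- rc[good, "row"]; cc[hit] <- rc[good, "col"]
        ok[hit] <- TRUE
        tries <- tries + 1L
        if (!all(ok)) {
          idx <- which(!ok)
          ang[idx] <- stats::runif(length(idx), 0, 2 * pi)
          if (tries %% 60L == 0L) {
            len[idx] <- stats::rgamma(length(idx),
                                      shape = config$step_shape,
                                      scale = scale)
          }
          if (tries > 1000L) stop_burnsel("cannot place candidates on the map")
        }
      }
      eta <- rep(0, K)
      for (nm in names(config$beta)) {
        eta <- eta + config$beta[[nm]] * zl[[nm]][cbind(cr, cc)]
      }
      w <- exp(eta - max(eta))
      pick <- sample.int(K, 1L, prob = w)
      steps[t] <- sqrt((cx[pick] - pos[1])^2 + (cy[pick] - pos[2])^2)
      pos <- c(cx[pick], cy[pick])
      xs[t] <- pos[1]; ys[t] <- pos[2]
      rec[t] <- stats::runif(1) < config$fix_success
    }
    out <- data.frame(animal_id = animal_id,
                      time = 4 * seq_len(config$n_steps)[rec],
                      x = xs[rec], y = ys[rec])
    attr(out, "n_attempts") <- config$n_steps
    attr(out, "n_recorded") <- sum(rec)
    attr(out, "step_lengths") <- steps
    class(out) <- c("telemetry_track", "data.frame")
    out
  })
}

#' Simulate tracks for several animals
#'
#' @inheritParams simulate_track
#' @return a combined `telemetry_track` for `config$n_animals` animals
#'   (per-animal sub-seeds streamed from `config$seed`).
#' @export
simulate_tracks <- function(stack, config, start = NULL) {
  tracks <- lapply(seq_len(config$n_animals), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 100L + i)
    simulate_track(stack, cfg, start = start,
                   animal_id = sprintf("A%d", i))
  })
  out <- do.call(rbind, lapply(tracks, as.data.frame))
  attr(out, "n_attempts") <- sum(vapply(tracks, attr, 0, "n_attempts"))
  attr(out, "n_recorded") <- sum(vapply(tracks, attr, 0, "n_recorded"))
  attr(out, "step_lengths") <- unlist(lapply(tracks, attr, "step_lengths"))
  class(out) <- c("telemetry_track", "data.frame")
  out
}

# distance from points to a segment
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx^2 + dy^2
  t <- if (l2 == 0) rep(0, length(px)) else {
    pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / l2))
  }
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Delineate a study area by buffering the step path
#'
#' Connects sequential fixes of each animal with straight lines and buffers
#' the lines by the average step length (766 m by default); the union of the
#' segment buffers, rasterized on `grid` (cell centres inside the buffer),
#' is the study-area mask, optionally intersected with a clip mask such as a
#' fire perimeter.
#'
#' @param track a `telemetry_track` (>= 2 fixes).
#' @param grid a `raster_grid` supplying the output geometry.
#' @param buffer_m buffer radius in metres (default 766).
#' @param clip_mask optional `raster_grid` mask (cells with value 1 kept).
#' @return a `raster_grid` mask: 1 inside the study area, 0 outside.
#' @export
delineate_study_area <- function(track, grid, buffer_m = 766,
                                 clip_mask = NULL) {
  if (nrow(track) < 2L) stop_burnsel("need at least 2 fixes to buffer a path")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cell_size
  xs <- grid$origin[1] + (seq_len(nc) - 0.5) * cs
  ys <- grid$origin[2] - (seq_len(nr) - 0.5) * cs
  inside <- matrix(FALSE, nr, nc)
  for (id in unique(track$animal_id)) {
    tr <- track[track$animal_id == id, ]
    tr <- tr[order(tr$time), ]
    if (nrow(tr) < 2L) next
    for (i in seq_len(nrow(tr) - 1L)) {
      x1 <- tr$x[i]; y1 <- tr$y[i]; x2 <- tr$x[i + 1L]; y2 <- tr$y[i + 1L]
      cr <- which(ys >= min(y1, y2) - buffer_m - cs &
                    ys <= max(y1, y2) + buffer_m + cs)
      cc <- which(xs >= min(x1, x2) - buffer_m - cs &
                    xs <= max(x1, x2) + buffer_m + cs)
      if (!length(cr) || !length(cc)) next
      px <- rep(xs[cc], each = length(cr))
      py <- rep(ys[cr], times = length(cc))
      d <- point_segment_distance(px, py, x1, y1, x2, y2)
      inside[cr, cc] <- inside[cr, cc] |
        matrix(d <= buffer_m, length(cr), length(cc))
    }
  }
  if (!any(inside)) stop_burnsel("buffered path covers no cell centres")
  out <- grid
  out$values <- inside + 0
  out$legend <- NULL
  class(out) <- "raster_grid"
  if (!is.null(clip_mask)) {
    if (!same_geometry(out, clip_mask)) stop_burnsel("clip mask mismatch")
    out$values <- out$values * (clip_mask$values == 1)
  }
  out
}

# cells where a mask raster equals 1
mask_which <- function(mask) which(!is.na(mask$values) & mask$values == 1)

#' Extract the used points falling inside a mask
#'
#' @param track a `telemetry_track`.
#' @param mask a `raster_grid` mask (1 = inside), e.g. a burn mask.
#' @return data frame of the fixes (columns of `track`) whose containing
#'   cell lies in the mask.
#' @export
extract_used_points <- function(track, mask) {
  rc <- point_to_cell(mask, track$x, track$y)
  ok <- !is.na(rc[, "row"])
  keep <- rep(FALSE, nrow(track))
  keep[ok] <- !is.na(mask$values[rc[ok, , drop = FALSE]]) &
    mask$values[rc[ok, , drop = FALSE]] == 1
  track[keep, , drop = FALSE]
}

#' Sample random available points uniformly over a mask
#'
#' Availability is a design distribution: points are drawn with replacement
#' over the mask's cells (uniform over area) with uniform jitter inside each
#' cell, so available points may share cells with used points.
#'
#' @param mask a `raster_grid` mask (1 = available area).
#' @param n number of points; by design equal to the number of used points.
#' @param seed integer seed.
#' @return data frame with columns `x`, `y`.
#' @export
sample_available <- function(mask, n, seed) {
  if (n < 1) stop_burnsel("`n` must be >= 1")
  cells <- mask_which(mask)
  if (!length(cells)) stop_burnsel("availability mask is empty")
  nr <- nrow(mask$values)
  with_seed(seed, {
    pick <- cells[sample.int(length(cells), n, replace = TRUE)]
    row <- (pick - 1L) %% nr + 1L
    col <- (pick - 1L) %/% nr + 1L
    cs <- mask$cell_size
    data.frame(
      x = mask$origin[1] + (col - 1L) * cs + stats::runif(n) * cs,
      y = mask$origin[2] - (row - 1L) * cs - stats::runif(n) * cs
    )
  })
}

#' Sample used points by a point-level selection function
#'
#' Draws locations over a mask with probability proportional to
#' `exp(sum(beta * z))`, `z` the standardized covariates — the known-truth
#' generator for parameter-recovery experiments, complementing the movement
#' simulator.
#'
#' @param stack a `landscape_stack`.
#' @param beta named coefficients on standardized layers.
#' @param n number of points.
#' @param seed integer seed.
#' @param mask optional availability mask (default: all cells valid on
#'   every `beta` layer).
#' @return data frame with columns `x`, `y`.
#' @export
sample_used_points <- function(stack, beta, n, seed, mask = NULL) {
  zl <- standardized_layers(stack, names(beta))
  ref <- stack$layers[[1]]
  ok <- !Reduce(`|`, lapply(stack$layers[names(beta)],
                            function(g) is.na(g$values)))
  if (!is.null(mask)) ok <- ok & !is.na(mask$values) & mask$values == 1
  cells <- which(ok)
  if (!length(cells)) stop_burnsel("no valid cells to sample from")
  eta <- rep(0, length(cells))
  for (nm in names(beta)) eta <- eta + beta[[nm]] * zl[[nm]][cells]
  w <- exp(eta - max(eta))
  nr <- nrow(ref$values)
  with_seed(seed, {
    pick <- cells[sample.int(length(cells), n, replace = TRUE, prob = w)]
    row <- (pick - 1L) %% nr + 1L
    col <- (pick - 1L) %/% nr + 1L
    cs <- ref$cell_size
    data.frame(
      x = ref$origin[1] + (col - 1L) * cs + stats::runif(n) * cs,
      y = ref$origin[2] - (row - 1L) * cs - stats::runif(n) * cs
    )
  })
}

#' Build the used/available model table
#'
#' Extracts every requested covariate at the cell containing each point and
#' stacks used (response 1) over available (response 0) rows. Rows with any
#' missing covariate are dropped, then the larger class is down-sampled at
#' the given seed so the equal-count design survives the drops.
#'
#' @param used data frame of used points (`x`, `y`).
#' @param available data frame of available points (`x`, `y`).
#' @param stack a `landscape_stack`.
#' @param layers character vector of layer names to extract (default: all
#'   non-categorical layers).
#' @param seed seed for the re-balancing down-sample.
#' @return a data frame with columns `response` (1 used / 0 available),
#'   `x`, `y`, and one column per covariate; attribute `covariates` lists
#'   the covariate columns, attribute `n_dropped` the rows lost to nodata.
#' @export
build_table <- function(used, available, stack, layers = NULL, seed = 1) {
  if (is.null(layers)) {
    layers <- names(stack$layers)[!vapply(stack$layers, is_categorical,
                                          TRUE)]
  }
  extract <- function(pts) {
    ref <- stack$layers[[1]]
    rc <- point_to_cell(ref, pts$x, pts$y)
    cov <- vapply(layers, function(nm) {
      v <- rep(NA_real_, nrow(pts))
      ok <- !is.na(rc[, "row"])
      v[ok] <- stack$layers[[nm]]$values[rc[ok, , drop = FALSE]]
      v
    }, numeric(nrow(pts)))
    cov <- matrix(cov, nrow = nrow(pts),
                  dimnames = list(NULL, layers))
    cbind(pts[, c("x", "y")], as.data.frame(cov))
  }
  u <- cbind(response = 1, extract(used))
  a <- cbind(response = 0, extract(available))
  tab <- rbind(u, a)
  complete <- stats::complete.cases(tab[, layers, drop = FALSE])
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    warning(sprintf("dropped %d point(s) with missing covariates", n_dropped))
  }
  tab <- tab[complete, , drop = FALSE]
  n1 <- sum(tab$response == 1); n0 <- sum(tab$response == 0)
  m <- min(n1, n0)
  if (m < 1) stop_burnsel("one class has no complete rows")
  tab <- with_seed(seed, {
    keep1 <- sample(which(tab$response == 1), m)
    keep0 <- sample(which(tab$response == 0), m)
    tab[sort(c(keep1, keep0)), , drop = FALSE]
  })
  rownames(tab) <- NULL
  attr(tab, "covariates") <- layers
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Percentage of locations inside the burn
#'
#' @param n_inside count of locations inside burned areas.
#' @param n_total total location count (> 0).
#' @return list with `n_total`, `n_inside`, `pct` (exact), `pct_1dp` (one
#'   decimal) and `pct_whole` (whole percent).
#' @export
burn_use_pct <- function(n_inside, n_total) {
  if (n_total <= 0) stop_burnsel("`n_total` must be positive")
  p <- 100 * n_inside / n_total
  list(n_total = n_total, n_inside = n_inside, pct = p,
       pct_1dp = round(p, 1), pct_whole = round(p))
}

#' Summarise how much of a track lies inside the burn
#'
#' @param track a `telemetry_track`.
#' @param burn_mask a `raster_grid` mask (1 = burned).
#' @return see [burn_use_pct()].
#' @export
burn_use_summary <- function(track, burn_mask) {
  if (nrow(track) == 0) stop_burnsel("track has no fixes")
  inside <- extract_used_points(track, burn_mask)
  burn_use_pct(nrow(inside), nrow(track))
}
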