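# Brute-force oracles, written as plain loops so they stay independent of
# the vectorized implementations they check.

bf_slope_aspect <- function(z, cs) {
  nr <- nrow(z); nc <- ncol(z)
  slope <- aspect <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      gx <- if (c > 1 && c < nc) (z[r, c + 1] - z[r, c - 1]) / (2 * cs)
            else if (c < nc) (z[r, c + 1] - z[r, c]) / cs
            else (z[r, c] - z[r, c - 1]) / cs
      gy <- if (r > 1 && r < nr) (z[r - 1, c] - z[r + 1, c]) / (2 * cs)
            else if (r > 1) (z[r - 1, c] - z[r, c]) / cs
            else (z[r, c] - z[r + 1, c]) / cs
      slope[r, c] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
      aspect[r, c] <- if (gx == 0 && gy == 0) -1 else
        (atan2(-gx, -gy) * 180 / pi) %% 360
    }
  }
  list(slope = slope, aspect = aspect)
}

bf_focal_mean <- function(m, w) {
  half <- (w - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (is.na(m[r, c])) next
      vals <- c()
      for (dr in -half:half) for (dc in -half:half) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && !is.na(m[r2, c2])) {
          vals <- c(vals, m[r2, c2])
        }
      }
      out[r, c] <- mean(vals)
    }
  }
  out
}

# distance in cells from every cell to the nearest TRUE cell
bf_distance <- function(target) {
  nr <- nrow(target); nc <- ncol(target)
  tg <- which(target, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      out[r, c] <- sqrt(min((tg[, 1] - r)^2 + (tg[, 2] - c)^2))
    }
  }
  out
}

# nearest-source class assignment with lower-code tie-break
bf_nibble <- function(v, fill_codes) {
  nr <- nrow(v); nc <- ncol(v)
  src <- which(!is.na(v) & !(v %in% fill_codes), arr.ind = TRUE)
  out <- v
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (is.na(v[r, c]) || !(v[r, c] %in% fill_codes)) next
      d2 <- (src[, 1] - r)^2 + (src[, 2] - c)^2
      best <- which(d2 == min(d2))
      out[r, c] <- min(v[src[best, , drop = FALSE]])
    }
  }
  out
}

# simple gridded test rasters
toy_grid <- function(m, cs = 30) raster_grid(m, cell_size = cs)

smooth_surface <- function(nr, nc, cs = 30, seed = 1) {
  set.seed(seed)
  x <- outer(seq_len(nr), seq_len(nc), function(r, c) {
    50 * sin(r / 4) + 40 * cos(c / 5) + 0.3 * r * c / nc
  })
  raster_grid(x + matrix(rnorm(nr * nc, sd = 0.5), nr, nc), cell_size = cs)
}

# balanced synthetic used/available table: `k_inf` informative covariates
# (shifted between classes by `effect`), remainder pure noise
synth_table <- function(n = 400, k_inf = 2, k_noise = 4, effect = 1,
                        seed = 1) {
  set.seed(seed)
  resp <- rep(c(1, 0), each = n / 2)
  covs <- matrix(rnorm(n * (k_inf + k_noise)), n)
  colnames(covs) <- c(sprintf("inf%d", seq_len(k_inf)),
                      sprintf("noise%d", seq_len(k_noise)))
  for (j in seq_len(k_inf)) covs[resp == 1, j] <- covs[resp == 1, j] + effect
  tab <- data.frame(response = resp,
                    x = runif(n, 0, 1000), y = runif(n, 0, 1000), covs)
  attr(tab, "covariates") <- colnames(covs)
  tab
}
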