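# Grid model, I/O round trips and the deterministic covariate derivations.

test_that("raster I/O round-trips values, geometry and nodata exactly", {
  tmp <- withr::local_tempfile(fileext = ".asc")
  g <- raster_grid(matrix(1, 5, 5), cell_size = 30, origin = c(1000, 2000))
  write_raster(g, tmp)
  g2 <- read_raster(tmp)
  expect_identical(g2$values, g$values)
  expect_identical(g2$cell_size, 30)
  expect_identical(g2$origin, c(1000, 2000))

  set.seed(4)
  m <- matrix(rnorm(30), 5, 6)   # arbitrary doubles, full precision
  m[c(2, 9, 17)] <- NA
  g <- raster_grid(m, cell_size = 30, origin = c(-5.25, 11.5),
                   nodata = -9999)
  write_raster(g, tmp)
  g2 <- read_raster(tmp)
  expect_identical(g2$values, m)
  expect_identical(which(is.na(g2$values)), c(2L, 9L, 17L))
  expect_identical(g2$nodata, -9999)
})

test_that("categorical rasters keep their legend through I/O", {
  tmp <- withr::local_tempfile(fileext = ".asc")
  cr <- categorical_raster(matrix(c(1, 2, 2, 1), 2, 2),
                           legend = c("1" = "lodgepole", "2" = "sprucefir"))
  write_raster(cr, tmp)
  cr2 <- read_raster(tmp)
  expect_s3_class(cr2, "categorical_raster")
  expect_identical(cr2$legend, cr$legend)
})

test_that("malformed inputs are rejected with descriptive errors", {
  expect_error(read_raster(file.path(tempdir(), "absent.asc")), "cannot read")
  expect_error(raster_grid(matrix(Inf, 2, 2)), "finite")
  expect_error(raster_grid(matrix(1, 2, 2), cell_size = 0), "positive")
  g1 <- raster_grid(matrix(1, 2, 2))
  g2 <- raster_grid(matrix(1, 3, 3))
  expect_error(landscape_stack(list(a = g1, b = g2)), "geometry")
  expect_error(categorical_raster(matrix(3, 2, 2), c("1" = "x")),
               "absent from legend")
})

test_that("slope and aspect match the analytic plane and the brute-force oracle", {
  flat <- toy_grid(matrix(100, 5, 5))
  sa <- slope_aspect(flat)
  expect_true(all(sa$slope$values == 0))
  expect_true(all(sa$aspect$values == FLAT_ASPECT))

  # plane rising 1 m per 30 m cell due north
  plane <- toy_grid(outer(10:1, rep(1, 8)))
  sa <- slope_aspect(plane)
  inner <- sa$slope$values[2:9, 2:7]
  expect_equal(unique(as.vector(inner)), atan(1 / 30) * 180 / pi,
               tolerance = 1e-12)
  expect_true(all(sa$aspect$values == 180))

  rs <- smooth_surface(12, 9)
  sa <- slope_aspect(rs)
  bf <- bf_slope_aspect(rs$values, 30)
  expect_equal(sa$slope$values, bf$slope, tolerance = 1e-9)
  expect_equal(sa$aspect$values, bf$aspect, tolerance = 1e-9)

  expect_error(slope_aspect(toy_grid(matrix(NA_real_, 4, 4))), "nodata")
})

test_that("heat load index is folded about southwest and aspect-free when flat", {
  mk <- function(slope, aspect) {
    heat_load_index(toy_grid(matrix(slope, 2, 2)),
                    toy_grid(matrix(aspect, 2, 2)), 48)$values[1, 1]
  }
  expect_equal(mk(0, 0), mk(0, 225))                       # flat
  expect_equal(mk(20, 180), mk(20, 270), tolerance = 1e-12) # fold symmetry
  expect_gt(mk(20, 225), mk(20, 45))                       # SW > NE
  # direct hand evaluation of the published folded-aspect equation
  s <- 20 * pi / 180; l <- 48 * pi / 180
  af <- abs(180 - abs(225 - 225)) * pi / 180
  expected <- exp(-1.467 + 1.582 * cos(l) * cos(s) -
                    1.500 * cos(af) * sin(s) * sin(l) -
                    0.262 * sin(l) * sin(s) + 0.607 * sin(af) * sin(s))
  expect_equal(mk(20, 225), expected, tolerance = 1e-9)
  expect_error(mk_bad <- heat_load_index(toy_grid(matrix(1, 2, 2)),
                                         toy_grid(matrix(1, 2, 2)), 75),
               "latitude")
})

test_that("flow accumulation routes D8 water as the hand-worked cases say", {
  # inclined plane: accumulation non-decreasing downslope along each column
  plane <- toy_grid(outer(10:1, rep(1, 6)) * 5)
  acc <- flow_accumulation(plane)$values
  expect_true(all(apply(acc, 2, diff) >= 0))
  # a cell with no upstream neighbours holds exactly its own area
  expect_equal(acc[1, 3], 900)
  # single central pit collects the whole 5x5 basin
  z <- matrix(10, 5, 5); z[3, 3] <- 1
  for (r in 1:5) for (c in 1:5) {
    z[r, c] <- z[r, c] + max(abs(r - 3), abs(c - 3))  # bowl toward centre
  }
  z[3, 3] <- 1
  acc <- flow_accumulation(toy_grid(z))$values
  expect_equal(acc[3, 3], 25 * 900)
  expect_equal(sum(acc == 900), 16)  # the outer ring only drains inward
})

test_that("compound topographic index follows ln(a / tan b) with the slope floor", {
  fa <- toy_grid(matrix(30 * 1 * 30, 2, 2))  # a = 30 m^2/m after /cellwidth
  sl <- toy_grid(matrix(45, 2, 2))           # tan 45 = 1... a/tan = 30
  expect_equal(compound_topographic_index(fa, sl)$values[1, 1], log(30))
  # a / tan(beta) = 1 -> 0
  fa1 <- toy_grid(matrix(30 * tan(5 * pi / 180), 2, 2))
  sl5 <- toy_grid(matrix(5, 2, 2))
  expect_equal(compound_topographic_index(fa1, sl5)$values[1, 1], 0,
               tolerance = 1e-12)
  # scalar oracle: a = 1000 m^2/m at 5 degrees
  fa2 <- toy_grid(matrix(1000 * 30, 2, 2))
  expect_equal(compound_topographic_index(fa2, sl5)$values[1, 1],
               log(1000 / tan(5 * pi / 180)), tolerance = 1e-12)
  # flat slope hits the epsilon cap
  sl0 <- toy_grid(matrix(0, 2, 2))
  expect_equal(compound_topographic_index(fa2, sl0)$values[1, 1],
               log(1000 / tan(0.001)), tolerance = 1e-12)
  # monotonicity
  expect_gt(compound_topographic_index(toy_grid(matrix(2000 * 30, 2, 2)),
                                       sl5)$values[1, 1],
            compound_topographic_index(fa2, sl5)$values[1, 1])
  expect_lt(compound_topographic_index(fa2, toy_grid(matrix(10, 2, 2)))$values[1, 1],
            compound_topographic_index(fa2, sl5)$values[1, 1])
})

test_that("distance transforms agree with the exhaustive oracle", {
  leg <- c("0" = "bg", "1" = "target")
  m <- matrix(0, 10, 10); m[4, 7] <- 1
  cr <- categorical_raster(m, leg)
  d <- distance_to_class(cr, 1)$values
  expect_equal(d, bf_distance(m == 1) * 30, tolerance = 1e-9)
  expect_equal(d[4, 7], 0)
  expect_equal(d[5, 8], 30 * sqrt(2))   # diagonal neighbour
  # all-target grid is all zeros
  expect_true(all(distance_to_class(categorical_raster(matrix(1, 4, 4),
                                                       leg), 1)$values == 0))
  expect_error(distance_to_class(cr, 9), "target")
})

test_that("burn edge distance treats unburned cells and the map boundary as edge", {
  leg <- burn_legend(with_skip = TRUE)
  m <- matrix(1, 6, 6); m[1, 1] <- 0
  d <- burn_edge_distance(categorical_raster(m, leg))$values
  expect_true(is.na(d[1, 1]))
  expect_equal(d[1, 2], 30)    # adjacent to an unburned cell
  # burn covering the whole grid: boundary is the edge
  full <- categorical_raster(matrix(1, 5, 5), leg)
  d <- burn_edge_distance(full)$values
  expect_equal(d[1, 1], 30)
  expect_equal(d[3, 3], 90)
  # single-pixel burn is 30 m from its unburned ring
  single <- matrix(0, 5, 5); single[3, 3] <- 1
  d <- burn_edge_distance(categorical_raster(single, leg))$values
  expect_equal(d[3, 3], 30)
  expect_true(all(is.na(d[single == 0])))
  # toy mosaic against the exhaustive oracle (with boundary padding)
  set.seed(9)
  mosaic <- matrix(rbinom(144, 1, 0.6), 12, 12)
  cr <- categorical_raster(mosaic, leg)
  d <- burn_edge_distance(cr)$values
  pad <- matrix(TRUE, 14, 14)
  pad[2:13, 2:13] <- mosaic == 0
  bf <- bf_distance(pad)[2:13, 2:13] * 30
  bf[mosaic == 0] <- NA
  expect_equal(d, bf, tolerance = 1e-9)
  # interior skips optionally excluded from the edge set
  sk <- matrix(1, 7, 7); sk[4, 4] <- 5
  d_edge <- burn_edge_distance(categorical_raster(sk, leg))$values
  d_noedge <- burn_edge_distance(categorical_raster(sk, leg),
                                 skips_are_edge = FALSE)$values
  expect_equal(d_edge[4, 5], 30)
  expect_gt(d_noedge[4, 5], 30)
})

test_that("focal statistics match brute-force window averaging", {
  set.seed(2)
  m <- matrix(rnorm(36), 6, 6)
  m[c(5, 22)] <- NA
  g <- toy_grid(m)
  expect_equal(focal_mean(g, 3)$values, bf_focal_mean(m, 3),
               tolerance = 1e-9)
  # constant grid stays constant
  expect_true(all(focal_mean(toy_grid(matrix(7, 8, 8)), 3)$values == 7))
  # shift-invariance: focal_mean(g + c) = focal_mean(g) + c
  g2 <- g; g2$values <- g2$values + 5
  expect_equal(focal_mean(g2, 3)$values, focal_mean(g, 3)$values + 5,
               tolerance = 1e-9)
  expect_error(focal_mean(g, 4), "odd")
  # fractions: absent code gives zeros; pooled codes sum correctly
  leg <- c("0" = "a", "1" = "b", "2" = "c")
  cm <- categorical_raster(matrix(c(0, 1, 2), 6, 6), leg)
  expect_true(all(focal_fraction(cm, 7, 3)$values == 0))
  total <- focal_fraction(cm, 0, 3)$values + focal_fraction(cm, 1, 3)$values +
    focal_fraction(cm, 2, 3)$values
  expect_equal(total, matrix(1, 6, 6), tolerance = 1e-9)
  expect_equal(focal_fraction(cm, c(1, 2), 3)$values,
               focal_fraction(cm, 1, 3)$values +
                 focal_fraction(cm, 2, 3)$values, tolerance = 1e-9)
})

test_that("nibble reassigns disturbed cells to the nearest surrounding class", {
  leg <- c("1" = "lodgepole", "2" = "sprucefir", "9" = "disturbed")
  m <- matrix(1, 3, 3); m[2, 2] <- 9
  out <- nibble_reassign(categorical_raster(m, leg), 9)
  expect_equal(out$values[2, 2], 1)
  expect_false("9" %in% names(out$legend))
  # two source classes with a disturbed stripe: exhaustive oracle
  m <- cbind(matrix(1, 10, 4), matrix(9, 10, 3), matrix(2, 10, 3))
  out <- nibble_reassign(categorical_raster(m, leg), 9)
  expect_equal(out$values, bf_nibble(m, 9))
  # exact tie between two classes resolves to the lower code
  m <- matrix(c(2, 9, 1), 1, 3)
  g <- categorical_raster(rbind(m, m, m), leg)
  expect_equal(nibble_reassign(g, 9)$values[2, 2], 1)
  expect_error(nibble_reassign(categorical_raster(matrix(9, 2, 2),
                                                  leg), 9), "non-fill")
})

test_that("burn classification follows the severity and age rules", {
  yr_leg <- c("0" = "never", "1994" = "old fire", "2006" = "new fire")
  mk <- function(loss, year) {
    classify_burn(toy_grid(matrix(loss, 2, 2)),
                  categorical_raster(matrix(year, 2, 2), yr_leg),
                  analysis_year = 2010)$values[1, 1]
  }
  expect_equal(mk(0, 2006), 0)     # no canopy loss -> unburned
  expect_equal(mk(50, 2006), 2)    # 50 % -> low severity (boundary: low <= 50)
  expect_equal(mk(51, 2006), 1)    # 51 % -> high severity
  expect_equal(mk(80, 1994), 3)
  expect_equal(mk(30, 1994), 4)
  expect_equal(mk(70, 0), 0)       # never burned
  expect_error(mk(120, 2006), "\\[0, 100\\]")
  # all four combinations on one toy grid
  loss <- toy_grid(matrix(c(80, 20, 80, 20), 2, 2))
  yr <- categorical_raster(matrix(c(2006, 2006, 1994, 1994), 2, 2), yr_leg)
  out <- classify_burn(loss, yr, 2010)
  expect_equal(as.vector(out$values), c(1, 2, 3, 4))
  expect_s3_class(out, "categorical_raster")
})
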