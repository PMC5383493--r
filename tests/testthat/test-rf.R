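# Screens, spatial subsampling and the Random-Forest model-development
# procedure: MIR selection, permutation significance, partial dependence.

test_that("the Spearman screen flags monotone redundancy and spares independence", {
  tab <- synth_table(n = 500, k_inf = 1, k_noise = 3, seed = 2)
  tab$dup <- tab$inf1                      # identical copy: rho = 1
  tab$cubed <- tab$noise1^3                # monotone transform: rho = 1
  attr(tab, "covariates") <- c(attr(tab, "covariates"), "dup", "cubed")
  rep <- spearman_screen(tab, seed = 5, n_trees = 100)
  pair_of <- function(a, b) {
    any((rep$collinear_pairs$var1 == a & rep$collinear_pairs$var2 == b) |
          (rep$collinear_pairs$var1 == b & rep$collinear_pairs$var2 == a))
  }
  expect_true(pair_of("inf1", "dup"))
  expect_true(pair_of("noise1", "cubed"))
  expect_true(all(abs(rep$collinear_pairs$rho) > 0.8))
  # one member of each flagged pair is removed, never both
  expect_true(xor("inf1" %in% rep$removed, "dup" %in% rep$removed))
  # independent uniforms at n = 500 produce no flags
  set.seed(31)
  ind <- data.frame(response = rep(c(1, 0), 250),
                    x = runif(500), y = runif(500),
                    matrix(runif(5000), 500,
                           dimnames = list(NULL, paste0("u", 1:10))))
  attr(ind, "covariates") <- paste0("u", 1:10)
  expect_equal(nrow(spearman_screen(ind, seed = 1,
                                    n_trees = 50)$collinear_pairs), 0)
  # constant columns are reported separately
  tab$flat <- 1
  attr(tab, "covariates") <- c(attr(tab, "covariates"), "flat")
  expect_true("flat" %in% spearman_screen(tab, seed = 5,
                                          n_trees = 50)$constant)
})

test_that("the redundancy screen detects linear dependence by rank", {
  tab <- synth_table(n = 300, k_inf = 2, k_noise = 3, seed = 4)
  tab$combo <- tab$inf1 + tab$inf2
  attr(tab, "covariates") <- c(attr(tab, "covariates"), "combo")
  rep <- redundancy_screen(tab)
  expect_equal(length(rep$redundant_vars), 1)
  expect_true(rep$redundant_vars %in% c("inf1", "inf2", "combo"))
  tab$dup <- tab$noise1
  attr(tab, "covariates") <- c(attr(tab, "covariates"), "dup")
  expect_equal(length(redundancy_screen(tab)$redundant_vars), 2)
  # full-rank random matrix: nothing flagged
  clean <- synth_table(n = 300, k_inf = 2, k_noise = 6, seed = 9)
  expect_equal(length(redundancy_screen(clean)$redundant_vars), 0)
  tiny <- synth_table(n = 4, k_inf = 2, k_noise = 4, seed = 1)
  expect_error(redundancy_screen(tiny), "rows")
})

test_that("the spatial subsample is disjoint, exhaustive and density-weighted", {
  tab <- synth_table(n = 200, seed = 6)
  sp <- spatial_subsample(tab, seed = 3)
  expect_equal(sort(c(sp$train, sp$holdout)), 1:200)
  expect_equal(length(sp$train), 160)
  expect_length(intersect(sp$train, sp$holdout), 0)
  # uniform pattern: every point included about 80 % of the time
  set.seed(12)
  unif <- data.frame(x = runif(150, 0, 5000), y = runif(150, 0, 5000))
  inc <- rowMeans(vapply(1:200, function(s) {
    seq_len(150) %in% spatial_subsample(unif, seed = s)$train
  }, logical(150)))
  expect_lt(max(abs(inc - 0.8)), 0.05 + 0.12)  # binomial noise on 200 seeds
  expect_lt(abs(mean(inc) - 0.8), 0.01)
  # a dense cluster is thinned relative to sparse background
  set.seed(13)
  clust <- rbind(data.frame(x = rnorm(100, 100, 10), y = rnorm(100, 100, 10)),
                 data.frame(x = runif(100, 0, 5000), y = runif(100, 0, 5000)))
  inc_c <- rowMeans(vapply(1:100, function(s) {
    seq_len(200) %in% spatial_subsample(clust, seed = s)$train
  }, logical(200)))
  expect_lt(mean(inc_c[1:100]), mean(inc_c[101:200]))
  expect_error(spatial_subsample(synth_table(n = 4, seed = 1)), "at least 5")
})

test_that("forest fits separate the separable, stay at chance on noise, and repeat", {
  sep <- synth_table(n = 400, k_inf = 1, k_noise = 3, effect = 8, seed = 21)
  f <- fit_rf(sep, n_trees = 300, seed = 1)
  expect_lt(f$oob_error, 0.02)
  expect_equal(names(which.max(f$importance)), "inf1")
  null <- synth_table(n = 400, k_inf = 0, k_noise = 6, seed = 22)
  fn <- fit_rf(null, n_trees = 300, seed = 1)
  expect_lt(abs(fn$oob_error - 0.5), 0.05)
  f2 <- fit_rf(sep, n_trees = 300, seed = 1)
  expect_identical(f$importance, f2$importance)
  expect_identical(f$oob_error, f2$oob_error)
  one_class <- sep[sep$response == 1, ]
  attr(one_class, "covariates") <- attr(sep, "covariates")
  expect_error(fit_rf(one_class, n_trees = 50, seed = 1), "single class")
})

test_that("MIR rescales importances onto [0, 1] with the top variable at 1", {
  expect_equal(unname(model_improvement_ratio(c(a = 4, b = 2, c = 1))),
               c(1, 0.5, 0.25))
  expect_equal(unname(model_improvement_ratio(c(a = 3, b = 3))), c(1, 1))
  expect_equal(unname(model_improvement_ratio(c(a = 5, b = -2))), c(1, 0))
  expect_error(model_improvement_ratio(c(a = -1, b = 0)), "positive")
})

test_that("MIR selection traces 11 nested thresholds and recovers signal", {
  tab <- synth_table(n = 600, k_inf = 2, k_noise = 6, effect = 1.2,
                     seed = 31)
  sel <- mir_model_selection(tab, n_trees = 200, seed = 2)
  expect_equal(nrow(sel$trace), 11)
  expect_equal(sel$trace$threshold, seq(0, 1, 0.1))
  expect_equal(sel$retained[[1]], names(sel$mir))  # threshold 0 keeps all
  sizes <- vapply(sel$retained, length, 1L)
  expect_true(all(diff(sizes) <= 0))               # nested, non-increasing
  for (i in 2:11) {
    expect_true(all(sel$retained[[i]] %in% sel$retained[[i - 1]]))
  }
  expect_true(all(c("inf1", "inf2") %in% sel$selected_vars))
  # recovery across seeds: both informative variables in the chosen set
  hits <- vapply(1:5, function(s) {
    tb <- synth_table(n = 400, k_inf = 2, k_noise = 6, effect = 1.2,
                      seed = 100 + s)
    all(c("inf1", "inf2") %in%
          mir_model_selection(tb, n_trees = 150, seed = s)$selected_vars)
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("permutation significance is bounded, extreme for signal, deterministic", {
  tab <- synth_table(n = 300, k_inf = 1, k_noise = 3, effect = 6, seed = 41)
  ps <- permutation_significance(tab, B = 99, n_trees = 100, seed = 3)
  expect_equal(ps$p_value, 1 / 100)     # strong signal: minimal p
  expect_gte(ps$p_value, 1 / (ps$B + 1))
  expect_length(ps$null_accuracy, 99)
  ps2 <- permutation_significance(tab, B = 99, n_trees = 100, seed = 3)
  expect_identical(ps$null_accuracy, ps2$null_accuracy)
  expect_error(permutation_significance(tab, B = 10), "at least 19")
})

test_that("partial dependence equals brute-force substitution averaging", {
  tab <- synth_table(n = 50, k_inf = 1, k_noise = 2, effect = 2, seed = 51)
  f <- fit_rf(tab, n_trees = 100, seed = 2)
  pd <- partial_dependence(f, tab, "inf1", n_grid = 7)
  for (i in seq_len(nrow(pd))) {
    tb <- tab
    tb$inf1 <- pd$value[i]
    preds <- vapply(seq_len(nrow(tb)), function(r) {
      predict_use(f, tb[r, , drop = FALSE])
    }, numeric(1))
    expect_equal(pd$p_used[i], mean(preds), tolerance = 1e-12)
  }
  expect_true(all(pd$p_used >= 0 & pd$p_used <= 1))
  expect_true(!is.unsorted(pd$value))
  # monotone generating effect gives a monotone-trending curve
  pd2 <- partial_dependence(f, tab, "inf1", n_grid = 15)
  expect_gt(cor(pd2$value, pd2$p_used, method = "spearman"), 0.9)
  expect_error(partial_dependence(f, tab, "absent"), "not a model variable")
})
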