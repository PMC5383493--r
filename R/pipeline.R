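#' Configuration for the burn habitat model pipeline
#'
#' @param n_trees trees for the model fits (default 4000).
#' @param n_trees_screen trees for the collinearity pre-screen forest.
#' @param permutations label permutations for the significance test
#'   (default 1000).
#' @param perm_trees trees per permutation refit (default `n_trees`; the
#'   test is commonly run with a reduced count).
#' @param subsample_fraction training fraction of the spatial subsample.
#' @param r_threshold Spearman collinearity threshold.
#' @param redundancy_tol rank tolerance of the redundancy screen.
#' @param within_class_stat `"max"` or `"mean"` within-class error.
#' @param layers covariate layers to model (default: every non-categorical
#'   stack layer except `dem`, `aspect` and point-scale `canopy`, whose
#'   focal-scale versions carry the structure signal).
#' @param pd_grid grid size of the partial-dependence curves.
#' @param run_permutation logical; skip the permutation stage when `FALSE`.
#' @return a `burn_model_config` list.
#' @export
burn_model_config <- function(n_trees = 4000, n_trees_screen = 500,
                              permutations = 1000, perm_trees = n_trees,
                              subsample_fraction = 0.8, r_threshold = 0.8,
                              redundancy_tol = 1e-7,
                              within_class_stat = "max", layers = NULL,
                              pd_grid = 25, run_permutation = TRUE) {
  structure(list(n_trees = n_trees, n_trees_screen = n_trees_screen,
                 permutations = permutations, perm_trees = perm_trees,
                 subsample_fraction = subsample_fraction,
                 r_threshold = r_threshold, redundancy_tol = redundancy_tol,
                 within_class_stat = within_class_stat, layers = layers,
                 pd_grid = pd_grid, run_permutation = run_permutation),
            class = "burn_model_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_burnsel(sprintf("[stage %s] %s", name, conditionMessage(e)))
  })
}

#' Run the full burn habitat-selection model
#'
#' Orchestrates the whole model-development procedure on one study area:
#' equal-count available sampling within the burn, covariate extraction,
#' redundancy and Spearman collinearity screens, the spatially weighted
#' 80/20 subsample, MIR threshold model selection, the final fit, holdout
#' validation, the permutation significance test, and partial-dependence
#' curves for every selected variable. Fully reproducible from
#' `(stack, used, seed, config)`.
#'
#' @param stack a `landscape_stack` including a `burn_class` layer.
#' @param used data frame of used points (`x`, `y`), e.g. the fixes inside
#'   the burn.
#' @param seed master integer seed; per-stage sub-seeds use fixed offsets.
#' @param config a [burn_model_config()].
#' @param area_mask availability mask (default: cells inside the fire
#'   perimeter, i.e. `burn_class != 0`).
#' @return a `habitat_model_result`: list with `table`, `screens`,
#'   `split`, `selection` (the [mir_model_selection()] trace), `fit`,
#'   `selected_vars`, `importances`, `mir`, `oob_error`, `class_errors`,
#'   `holdout_accuracy`, `permutation` (p-value and null accuracies, or
#'   `NULL` when skipped) and `partial_dependence` (named list of curves).
#' @export
run_burn_model <- function(stack, used, seed = 1,
                           config = burn_model_config(),
                           area_mask = NULL) {
  if (is.null(area_mask)) {
    bc <- stack[["burn_class"]]
    if (is.null(bc)) stop_burnsel("stack has no `burn_class` layer and no ",
                                  "`area_mask` was given")
    area_mask <- bc
    area_mask$values <- (!is.na(bc$values) & bc$values != 0) + 0
    area_mask$legend <- NULL
    class(area_mask) <- "raster_grid"
  }
  layers <- config$layers %||% setdiff(
    names(stack$layers)[!vapply(stack$layers, is_categorical, TRUE)],
    c("dem", "aspect", "canopy"))
  avail <- stage("sample_available",
                 sample_available(area_mask, nrow(used),
                                  derive_seed(seed, 1L)))
  tab <- stage("build_table",
               build_table(used, avail, stack, layers = layers,
                           seed = derive_seed(seed, 2L)))
  red <- stage("redundancy_screen",
               redundancy_screen(tab, tolerance = config$redundancy_tol))
  keep <- red$kept
  attr(tab, "covariates") <- keep
  sp <- stage("spearman_screen",
              spearman_screen(tab, r_threshold = config$r_threshold,
                              seed = derive_seed(seed, 3L),
                              n_trees = config$n_trees_screen))
  keep <- intersect(keep, sp$kept)
  if (length(keep) < 1) stop_burnsel("[stage screens] no covariates survive")
  attr(tab, "covariates") <- keep
  split <- stage("spatial_subsample",
                 spatial_subsample(tab, fraction = config$subsample_fraction,
                                   seed = derive_seed(seed, 4L)))
  train <- tab[split$train, , drop = FALSE]
  holdout <- tab[split$holdout, , drop = FALSE]
  attr(train, "covariates") <- keep
  sel <- stage("mir_model_selection",
               mir_model_selection(train, n_trees = config$n_trees,
                                   seed = derive_seed(seed, 5L),
                                   vars = keep,
                                   within_class_stat = config$within_class_stat))
  fit <- stage("final_fit",
               fit_rf(train, n_trees = config$n_trees,
                      seed = derive_seed(seed, 6L),
                      vars = sel$selected_vars))
  hold_acc <- if (nrow(holdout)) {
    p <- predict_use(fit, holdout)
    mean((p > 0.5) == (holdout$response == 1))
  } else NA_real_
  perm <- if (config$run_permutation) {
    stage("permutation_significance",
          permutation_significance(train, vars = sel$selected_vars,
                                   B = config$permutations,
                                   n_trees = config$perm_trees,
                                   seed = derive_seed(seed, 7L)))
  } else NULL
  pd <- stage("partial_dependence", {
    curves <- lapply(sel$selected_vars, function(v) {
      partial_dependence(fit, train, v, n_grid = config$pd_grid)
    })
    names(curves) <- sel$selected_vars
    curves
  })
  structure(list(
    table = tab, screens = list(redundancy = red, spearman = sp),
    split = split, selection = sel, fit = fit,
    selected_vars = sel$selected_vars, importances = fit$importance,
    mir = sel$mir, oob_error = fit$oob_error,
    class_errors = fit$class_errors, holdout_accuracy = hold_acc,
    permutation = perm, partial_dependence = pd,
    seed = seed, config = config
  ), class = "habitat_model_result")
}

#' @export
print.habitat_model_result <- function(x, ...) {
  cat("<habitat_model_result>\n")
  cat(sprintf("  rows: %d (balanced), covariates screened to %d\n",
              nrow(x$table), length(attr(x$table, "covariates"))))
  cat(sprintf("  selected (MIR threshold %.1f): %s\n",
              x$selection$chosen_threshold,
              paste(x$selected_vars, collapse = ", ")))
  cat(sprintf("  OOB error %.3f | class errors: available %.3f, used %.3f\n",
              x$oob_error, x$class_errors[["available"]],
              x$class_errors[["used"]]))
  cat(sprintf("  holdout accuracy %.3f\n", x$holdout_accuracy))
  if (!is.null(x$permutation)) {
    cat(sprintf("  permutation p = %.4g (B = %d)\n",
                x$permutation$p_value, x$permutation$B))
  }
  invisible(x)
}

# slope sign of a partial-dependence curve (Spearman of curve vs grid)
pd_slope_sign <- function(curve) {
  if (stats::sd(curve$p_used) == 0) return(0)
  sign(stats::cor(curve$value, curve$p_used, method = "spearman"))
}
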