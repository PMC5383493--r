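# Random-Forest fitting and the model-development procedure built around
# it: Model Improvement Ratio (MIR) thresholding with refits at eleven
# thresholds, a label-permutation significance test on out-of-bag accuracy,
# and partial-dependence curves. The base ensemble learner is ranger
# (probability forests, permutation importances, seeded and single-threaded
# for exact reproducibility); the procedure around it lives here.

rf_response_factor <- function(y) {
  factor(ifelse(y == 1, "used", "available"),
         levels = c("available", "used"))
}

#' Fit a Random-Forest habitat model
#'
#' Probability forest on the balanced used/available table with
#' permutation-style variable importances. Out-of-bag class assignments
#' (probability threshold 0.5) give the OOB error, per-class errors and OOB
#' accuracy. Deterministic for a fixed seed.
#'
#' @param table a used/available table (`response` column plus covariates).
#' @param n_trees number of bootstrap trees (default 4000, the
#'   full-analysis setting; tests and permutation refits use fewer via this
#'   argument).
#' @param seed integer seed.
#' @param vars covariates to use (default: all of `attr(table,
#'   "covariates")`).
#' @param mtry variables tried per split (default: ranger's square-root
#'   rule).
#' @param importance compute permutation importances (default `TRUE`;
#'   refits that only need error estimates skip them for speed).
#' @return an `rf_fit`: list with `model`, `vars`, `importance` (named,
#'   permutation; `NULL` when not computed), `oob_error`, `oob_accuracy`,
#'   `class_errors` (named by class), `n_trees`.
#' @export
fit_rf <- function(table, n_trees = 4000, seed = 1, vars = NULL,
                   mtry = NULL, importance = TRUE) {
  vars <- vars %||% attr(table, "covariates") %||%
    setdiff(names(table), c("response", "x", "y"))
  y <- rf_response_factor(table$response)
  if (length(unique(y)) < 2) {
    stop_burnsel("response has a single class; cannot fit")
  }
  df <- data.frame(.resp = y, table[, vars, drop = FALSE],
                   check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".resp", data = df,
    num.trees = n_trees, mtry = mtry, probability = TRUE,
    importance = if (importance) "permutation" else "none",
    seed = seed, num.threads = 1,
    verbose = FALSE
  )
  p_used <- fit$predictions[, "used"]
  pred <- ifelse(p_used > 0.5, "used", "available")
  ok <- !is.na(p_used)
  oob_error <- mean(pred[ok] != as.character(y)[ok])
  class_errors <- vapply(levels(y), function(cl) {
    sel <- ok & y == cl
    if (!any(sel)) return(NA_real_)
    mean(pred[sel] != cl)
  }, numeric(1))
  structure(list(model = fit, vars = vars,
                 importance = if (importance) fit$variable.importance
                              else NULL,
                 oob_error = oob_error, oob_accuracy = 1 - oob_error,
                 class_errors = class_errors, n_trees = n_trees),
            class = "rf_fit")
}

#' Predict the probability of use
#' @param fit an `rf_fit`.
#' @param newdata data frame containing the fit's covariates.
#' @return numeric vector of predicted probabilities of the "used" class.
#' @export
predict_use <- function(fit, newdata) {
  pr <- stats::predict(fit$model, data = newdata[, fit$vars, drop = FALSE],
                       num.threads = 1)$predictions
  pr[, "used"]
}

#' Model Improvement Ratio
#'
#' Each variable's importance divided by the maximum importance, with
#' negative importances floored at zero, so the top variable scores exactly
#' 1 and every score lies in \[0, 1\].
#'
#' @param importances named numeric importances (at least one positive).
#' @return named MIR scores.
#' @export
model_improvement_ratio <- function(importances) {
  imp <- pmax(importances, 0)
  if (max(imp) <= 0) {
    stop_burnsel("no variable has positive importance; MIR undefined")
  }
  imp / max(imp)
}

#' MIR threshold model selection
#'
#' Fits a forest on all covariates, computes MIR scores, then for each
#' threshold 0, 0.1, ..., 1 refits using only the variables with MIR at or
#' above the threshold (the retained sets are nested and non-increasing).
#' The final set minimises, lexicographically, the out-of-bag error, the
#' within-class error (by default the larger of the two class errors) and
#' the number of variables; remaining ties go to the larger threshold.
#'
#' @param table a used/available table.
#' @param n_trees trees per fit.
#' @param seed integer seed (one seed stream: base fit and the 11 refits
#'   use fixed offsets).
#' @param vars candidate covariates (default: table's covariates).
#' @param within_class_stat `"max"` (default) or `"mean"` of the per-class
#'   errors.
#' @return a `model_selection_trace`: list with `trace` (data frame of 11
#'   rows: threshold, n_vars, oob_error, class error columns,
#'   within_class_error, feasible), `retained` (list of variable sets),
#'   `mir`, `chosen_threshold`, `selected_vars`, `base_fit`.
#' @export
mir_model_selection <- function(table, n_trees = 4000, seed = 1,
                                vars = NULL,
                                within_class_stat = c("max", "mean")) {
  within_class_stat <- match.arg(within_class_stat)
  base <- fit_rf(table, n_trees = n_trees, seed = derive_seed(seed, 0L),
                 vars = vars)
  mir <- model_improvement_ratio(base$importance)
  thresholds <- seq(0, 1, by = 0.1)
  rows <- vector("list", length(thresholds))
  retained <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    t <- thresholds[i]
    keep <- names(mir)[mir >= t]
    retained[[i]] <- keep
    if (!length(keep)) {
      rows[[i]] <- data.frame(threshold = t, n_vars = 0L,
                              oob_error = NA_real_,
                              err_available = NA_real_, err_used = NA_real_,
                              within_class_error = NA_real_,
                              feasible = FALSE)
      next
    }
    f <- fit_rf(table, n_trees = n_trees, seed = derive_seed(seed, i),
                vars = keep, importance = FALSE)
    wce <- if (within_class_stat == "max") max(f$class_errors)
           else mean(f$class_errors)
    rows[[i]] <- data.frame(threshold = t, n_vars = length(keep),
                            oob_error = f$oob_error,
                            err_available = f$class_errors[["available"]],
                            err_used = f$class_errors[["used"]],
                            within_class_error = wce, feasible = TRUE)
  }
  trace <- do.call(rbind, rows)
  feas <- which(trace$feasible)
  ord <- feas[order(trace$oob_error[feas], trace$within_class_error[feas],
                    trace$n_vars[feas], -trace$threshold[feas])]
  best <- ord[1]
  structure(list(trace = trace, retained = retained, mir = mir,
                 chosen_threshold = trace$threshold[best],
                 selected_vars = retained[[best]], base_fit = base),
            class = "model_selection_trace")
}

#' @export
print.model_selection_trace <- function(x, ...) {
  cat("<model_selection_trace>\n")
  print(x$trace, row.names = FALSE, digits = 4)
  cat(sprintf("chosen threshold: %.1f -> %d variable(s): %s\n",
              x$chosen_threshold, length(x$selected_vars),
              paste(x$selected_vars, collapse = ", ")))
  invisible(x)
}

#' Permutation test of model significance
#'
#' Randomizes the used/available labels `B` times, refits the forest on the
#' permuted labels, and compares the observed out-of-bag accuracy with the
#' resulting null distribution of model accuracy:
#' `p = (1 + #\{null >= observed\}) / (B + 1)`.
#'
#' @param table a used/available table.
#' @param vars covariates of the (selected) model.
#' @param B number of label permutations (default 1000; at least 19 so p
#'   can resolve below 0.05).
#' @param n_trees trees per refit.
#' @param seed integer seed.
#' @return list with `p_value`, `observed_accuracy`, `null_accuracy`
#'   (length `B`), `B`.
#' @export
permutation_significance <- function(table, vars = NULL, B = 1000,
                                     n_trees = 4000, seed = 1) {
  if (B < 19) stop_burnsel("B must be at least 19 for a usable p resolution")
  vars <- vars %||% attr(table, "covariates")
  obs <- fit_rf(table, n_trees = n_trees, seed = derive_seed(seed, 0L),
                vars = vars, importance = FALSE)$oob_accuracy
  null_acc <- numeric(B)
  for (b in seq_len(B)) {
    tb <- table
    tb$response <- with_seed(derive_seed(seed, b), sample(table$response))
    null_acc[b] <- fit_rf(tb, n_trees = n_trees,
                          seed = derive_seed(seed, b), vars = vars,
                          importance = FALSE)$oob_accuracy
  }
  p <- (1 + sum(null_acc >= obs)) / (B + 1)
  list(p_value = p, observed_accuracy = obs, null_accuracy = null_acc, B = B)
}

#' Partial-dependence curve
#'
#' The functional relationship between one covariate and the predicted
#' probability of use when every other covariate is averaged over: for each
#' grid value `v`, the focal column of the table is set to `v` in every row
#' and the predictions are averaged.
#'
#' @param fit an `rf_fit`.
#' @param table the table the model was fit on (or any reference table).
#' @param variable the focal covariate (must be in the model).
#' @param n_grid number of grid values spanning the observed range
#'   (default 25; collapses to the unique values when fewer).
#' @return a `partial_dependence_curve` data frame with columns `value` and
#'   `p_used`; attribute `variable`.
#' @export
partial_dependence <- function(fit, table, variable, n_grid = 25) {
  if (!variable %in% fit$vars) {
    stop_burnsel("`", variable, "` is not a model variable")
  }
  obs <- table[[variable]]
  u <- sort(unique(obs))
  grid <- if (length(u) <= n_grid) u else {
    seq(min(obs), max(obs), length.out = n_grid)
  }
  p <- vapply(grid, function(v) {
    tb <- table
    tb[[variable]] <- v
    mean(predict_use(fit, tb))
  }, numeric(1))
  out <- data.frame(value = grid, p_used = p)
  attr(out, "variable") <- variable
  class(out) <- c("partial_dependence_curve", "data.frame")
  out
}
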