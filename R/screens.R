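# Pre-model variable screens: multivariate redundancy (rank-revealing QR)
# and pairwise Spearman collinearity at |rho| > 0.8.

covariate_matrix <- function(table, vars = NULL) {
  vars <- vars %||% attr(table, "covariates") %||%
    setdiff(names(table), c("response", "x", "y"))
  as.matrix(table[, vars, drop = FALSE])
}

#' Screen for pairwise rank collinearity
#'
#' Flags every covariate pair whose Spearman rank correlation exceeds the
#' threshold in absolute value (monotone redundancy survives any monotone
#' transform, hence ranks). From each flagged pair the member with the lower
#' univariate permutation importance in a quick pre-screen forest is
#' removed. Constant columns, whose rank correlation is undefined, are
#' reported separately (and removed).
#'
#' @param table a used/available table from [build_table()].
#' @param r_threshold absolute Spearman threshold (default 0.8).
#' @param seed seed for the pre-screen forest.
#' @param n_trees trees in the pre-screen forest (default 500).
#' @return a `screen_report`: list with `collinear_pairs` (data frame
#'   `var1`, `var2`, `rho`), `constant`, `removed`, `kept`.
#' @export
spearman_screen <- function(table, r_threshold = 0.8, seed = 1,
                            n_trees = 500) {
  x <- covariate_matrix(table)
  sds <- apply(x, 2, stats::sd)
  constant <- colnames(x)[is.na(sds) | sds == 0]
  vars <- setdiff(colnames(x), constant)
  pairs <- data.frame(var1 = character(), var2 = character(),
                      rho = numeric())
  removed <- constant
  if (length(vars) >= 2) {
    rho <- stats::cor(x[, vars, drop = FALSE], method = "spearman")
    idx <- which(abs(rho) > r_threshold & upper.tri(rho), arr.ind = TRUE)
    if (nrow(idx)) {
      pairs <- data.frame(var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
                          rho = rho[idx])
      pairs <- pairs[order(-abs(pairs$rho)), , drop = FALSE]
      imp <- fit_rf(table, n_trees = n_trees, seed = seed,
                    vars = vars)$importance
      alive <- vars
      for (i in seq_len(nrow(pairs))) {
        v1 <- pairs$var1[i]; v2 <- pairs$var2[i]
        if (v1 %in% alive && v2 %in% alive) {
          drop <- if (imp[[v1]] < imp[[v2]]) v1 else v2
          alive <- setdiff(alive, drop)
          removed <- c(removed, drop)
        }
      }
    }
  }
  structure(list(collinear_pairs = pairs, constant = constant,
                 removed = removed, kept = setdiff(colnames(x), removed)),
            class = "screen_report")
}

#' Screen for multivariate redundancy
#'
#' Flags covariates that are (near-)exact linear combinations of the
#' others, detected by rank-revealing QR on the column-standardized
#' covariate matrix: columns beyond the numerical rank are redundant and
#' removed. Requires more rows than columns.
#'
#' @param table a used/available table.
#' @param tolerance relative pivot tolerance for the rank decision
#'   (default 1e-7).
#' @return a `screen_report`: list with `redundant_vars`, `removed`,
#'   `kept`.
#' @export
redundancy_screen <- function(table, tolerance = 1e-7) {
  x <- covariate_matrix(table)
  if (nrow(x) < ncol(x)) {
    stop_burnsel("need at least as many rows as covariates")
  }
  sds <- apply(x, 2, stats::sd)
  xs <- sweep(x, 2, colMeans(x))
  xs[, sds > 0] <- sweep(xs[, sds > 0, drop = FALSE], 2, sds[sds > 0], "/")
  qrd <- qr(xs, tol = tolerance)
  redundant <- colnames(x)[qrd$pivot[seq_len(ncol(x)) > qrd$rank]]
  structure(list(redundant_vars = redundant, removed = redundant,
                 kept = setdiff(colnames(x), redundant)),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  if (!is.null(x$collinear_pairs) && nrow(x$collinear_pairs)) {
    cat("  collinear pairs (|rho| over threshold):\n")
    print(x$collinear_pairs, row.names = FALSE)
  }
  if (length(x$redundant_vars %||% character())) {
    cat("  redundant:", paste(x$redundant_vars, collapse = ", "), "\n")
  }
  cat("  removed:", if (length(x$removed)) paste(x$removed, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
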