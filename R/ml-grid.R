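#' RBF grid search for C and gamma
#'
#' Evaluates repeated cross-validation at every point of a log2-spaced
#' (C, gamma) grid, extends the grid when the best point lies on a border,
#' refines the step size around the best point once a peak is found, and
#' returns the argmax of the selection metric (MCC by default; a pluggable
#' combined-score hook over ACC, MCC and AUC is accepted). Ties break
#' toward the smallest (C, gamma) in scan order.
#'
#' @param log2c,log2g Numeric vectors of log2(C) and log2(gamma) grid
#'   points. Defaults: log2(C) from -5 to 15, log2(gamma) from -15 to 3,
#'   exponent step 2.
#' @param metric Selection metric: `"mcc"`, `"acc"`, `"auc"`, or a
#'   function `(acc, mcc, auc) -> score` to maximize.
#' @param folds,reps Cross-validation shape used to score each grid point
#'   (kept small by default; the final model is evaluated separately).
#' @param seed CV seed per grid point.
#' @param extend Extend the grid when the maximum lies on a border.
#' @param refine Refine the step around the peak (one halving).
#' @param max_extensions Cap on border extensions per direction.
#' @return A `GridSpec` list.
#' @export
grid_spec <- function(log2c = seq(-5, 15, by = 2),
                      log2g = seq(-15, 3, by = 2),
                      metric = "mcc", folds = 5L, reps = 2L, seed = 1L,
                      extend = TRUE, refine = TRUE, max_extensions = 3L) {
  list(log2c = log2c, log2g = log2g, metric = metric, folds = folds,
       reps = reps, seed = seed, extend = extend, refine = refine,
       max_extensions = max_extensions)
}

.grid_metric_value <- function(spec, agg) {
  if (is.function(spec$metric))
    spec$metric(agg$acc[["mean"]], agg$mcc[["mean"]], agg$auc[["mean"]])
  else agg[[spec$metric]][["mean"]]
}

#' Grid search over SVM-RBF hyperparameters
#'
#' @param x Feature matrix.
#' @param labels Binary labels.
#' @param spec A [grid_spec()].
#' @return List with `log2c`, `log2g`, `cost`, `gamma`, `score`, `metric`
#'   and `table` (one row per evaluated point, scan order), plus
#'   `extended` (logical).
#' @export
grid_search <- function(x, labels, spec = grid_spec()) {
  evaluated <- new.env(parent = emptyenv())
  tab <- data.frame()
  eval_points <- function(points) {
    for (i in seq_len(nrow(points))) {
      key <- sprintf("%.6g_%.6g", points$log2c[i], points$log2g[i])
      if (!is.null(evaluated[[key]])) next
      res <- tryCatch(
        repeated_cv(x, labels, algorithm = "svm_rbf",
                    params = list(cost = 2^points$log2c[i],
                                  gamma = 2^points$log2g[i]),
                    k = spec$folds, reps = spec$reps, seed = spec$seed),
        error = function(e) NULL)
      row <- data.frame(log2c = points$log2c[i], log2g = points$log2g[i],
                        acc = NA_real_, mcc = NA_real_, auc = NA_real_,
                        score = NA_real_)
      if (!is.null(res)) {
        row$acc <- res$aggregate$acc[["mean"]]
        row$mcc <- res$aggregate$mcc[["mean"]]
        row$auc <- res$aggregate$auc[["mean"]]
        sc <- .grid_metric_value(spec, res$aggregate)
        row$score <- if (is.finite(sc)) sc else NA_real_
      }
      evaluated[[key]] <- TRUE
      tab <<- rbind(tab, row)
    }
  }
  # scan order: log2g fastest, ascending log2c outer
  init <- expand.grid(log2g = spec$log2g, log2c = spec$log2c)[, c(2, 1)]
  eval_points(init)
  step_c <- if (length(spec$log2c) > 1) diff(spec$log2c)[1] else 2
  step_g <- if (length(spec$log2g) > 1) diff(spec$log2g)[1] else 2
  extended <- FALSE

  best_row <- function() {
    ok <- which(!is.na(tab$score))
    if (!length(ok)) stop("all grid points failed")
    # ties break toward the earliest evaluated (smallest in scan order)
    ok[which.max(tab$score[ok])]
  }

  if (isTRUE(spec$extend)) {
    for (iter in seq_len(spec$max_extensions)) {
      b <- tab[best_row(), ]
      new_pts <- NULL
      rng_c <- range(tab$log2c); rng_g <- range(tab$log2g)
      if (b$log2c == rng_c[1])
        new_pts <- rbind(new_pts, expand.grid(
          log2c = rng_c[1] - step_c * (1:2), log2g = unique(tab$log2g)))
      if (b$log2c == rng_c[2])
        new_pts <- rbind(new_pts, expand.grid(
          log2c = rng_c[2] + step_c * (1:2), log2g = unique(tab$log2g)))
      if (b$log2g == rng_g[1])
        new_pts <- rbind(new_pts, expand.grid(
          log2c = unique(tab$log2c), log2g = rng_g[1] - step_g * (1:2)))
      if (b$log2g == rng_g[2])
        new_pts <- rbind(new_pts, expand.grid(
          log2c = unique(tab$log2c), log2g = rng_g[2] + step_g * (1:2)))
      if (is.null(new_pts)) break
      extended <- TRUE
      eval_points(new_pts)
    }
  }
  if (isTRUE(spec$refine)) {
    b <- tab[best_row(), ]
    ref <- expand.grid(
      log2c = b$log2c + step_c / 2 * (-1:1),
      log2g = b$log2g + step_g / 2 * (-1:1))
    eval_points(ref)
  }
  b <- tab[best_row(), ]
  list(log2c = b$log2c, log2g = b$log2g,
       cost = 2^b$log2c, gamma = 2^b$log2g,
       score = b$score,
       metric = if (is.function(spec$metric)) "combined" else spec$metric,
       table = tab, extended = extended)
}
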