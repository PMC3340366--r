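#' Repeated stratified cross-validation
#'
#' Every experiment is a k-fold cross-validation repeated `reps` times
#' with different fold seeds; the reported value of each metric is the
#' mean (with standard deviation) over the `reps * k` cells. Folds are
#' stratified by label; feature z-scoring happens inside each training
#' fold only (no information leaks into the held-out fold).
#'
#' @name cv
NULL

# stratified fold assignment: returns integer fold id per instance
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Run repeated stratified k-fold cross-validation
#'
#' @param x Feature matrix (rows = islands).
#' @param labels For classification, `"methylated"`/`"unmethylated"`; for
#'   regression, methylation fractions in \[0, 1\].
#' @param algorithm Registry algorithm name (classification) or ignored
#'   for `task = "regression"` (SVR is used).
#' @param params Algorithm parameters passed to the learner.
#' @param k Folds; default 10.
#' @param reps Repetitions with different seeds; default 10.
#' @param seed Master seed; the run is fully reproducible from it.
#' @param task `"classification"` or `"regression"`.
#' @return An `EvaluationResult`: list with `cells` (one row per
#'   repetition x fold: confusion counts and ACC/MCC/AUC, or AAE),
#'   `aggregate` (mean and sd per metric), `k`, `reps`, `seed`.
#' @export
repeated_cv <- function(x, labels, algorithm = "svm_rbf", params = list(),
                        k = 10L, reps = 10L, seed = 1L,
                        task = c("classification", "regression")) {
  task <- match.arg(task)
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of instances")
  if (task == "classification") {
    y <- .as_label_factor(labels)
    if (min(table(y)) < k)
      stop("fewer than k instances in one class; stratified k-fold ",
           "cross-validation impossible")
  }
  cells <- list()
  for (rep_i in seq_len(reps)) {
    set.seed(seed + rep_i - 1L)
    fold <- if (task == "classification") stratified_folds(labels, k)
            else rep_len(seq_len(k), n)[sample(n)]
    for (f in seq_len(k)) {
      tr <- fold != f
      te <- !tr
      if (task == "classification") {
        model <- train_classifier(x[tr, , drop = FALSE], labels[tr],
                                  algorithm, params)
        d <- decision_scores(model, x[te, , drop = FALSE])
        pred <- ifelse(d > 0, "methylated", "unmethylated")
        cc <- confusion_counts(labels[te], pred)
        auc <- tryCatch(auc_score(d, labels[te]), error = function(e) NA_real_)
        cells[[length(cells) + 1L]] <- data.frame(
          rep = rep_i, fold = f, tp = cc$tp, fp = cc$fp, tn = cc$tn,
          fn = cc$fn, acc = accuracy(cc), mcc = mcc(cc), auc = auc)
      } else {
        model <- train_regressor(x[tr, , drop = FALSE], labels[tr], params)
        pred <- predict_fraction(model, x[te, , drop = FALSE])
        cells[[length(cells) + 1L]] <- data.frame(
          rep = rep_i, fold = f, aae = aae(labels[te], pred))
      }
    }
  }
  cells <- do.call(rbind, cells)
  metrics <- if (task == "classification") c("acc", "mcc", "auc") else "aae"
  aggregate <- lapply(metrics, function(m) {
    c(mean = mean(cells[[m]], na.rm = TRUE),
      sd = stats::sd(cells[[m]], na.rm = TRUE))
  })
  names(aggregate) <- metrics
  structure(list(cells = cells, aggregate = aggregate, k = k, reps = reps,
                 seed = seed, task = task, algorithm = algorithm,
                 params = params),
            class = "EvaluationResult")
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat(sprintf("EvaluationResult: %s, %d x %d-fold CV (seed %d)\n",
              x$task, x$reps, x$k, x$seed))
  for (m in names(x$aggregate))
    cat(sprintf("  %s: %.4f +/- %.4f\n", toupper(m),
                x$aggregate[[m]]["mean"], x$aggregate[[m]]["sd"]))
  invisible(x)
}
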