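#' Classifier training with a pluggable algorithm registry
#'
#' Seven binary classification algorithms are registered: `svm_rbf` and
#' `svm_linear` (libsvm via e1071), `random_forest`, `knn`,
#' `decision_tree` (rpart), `naive_bayes` and `kstar` (a simple
#' instance-based learner with exponential distance weighting in the
#' spirit of entropic instance-based classification). Every model stores
#' the z-scoring parameters of its training matrix; prediction returns
#' both a hard label and a real-valued decision score oriented so that
#' positive means methylated.
#'
#' @name train
NULL

.std_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}
.std_apply <- function(x, std) {
  sweep(sweep(x, 2, std$mu), 2, std$sd, "/")
}

.as_label_factor <- function(labels) {
  factor(labels, levels = c("unmethylated", "methylated"))
}

# each entry: fit(x, y, params) -> inner model; score(inner, x) -> numeric
# decision values (positive = methylated)
.algorithms <- new.env(parent = emptyenv())

.register <- function(name, fit, score) {
  assign(name, list(fit = fit, score = score), envir = .algorithms)
}

.svm_decision <- function(inner, x) {
  p <- stats::predict(inner, x, decision.values = TRUE)
  d <- attr(p, "decision.values")
  # libsvm orients the decision value toward the first training label;
  # flip when that label is the negative class
  if (grepl("^unmethylated", colnames(d)[1])) -d[, 1] else d[, 1]
}

.register("svm_rbf",
  fit = function(x, y, params) {
    e1071::svm(x, y, kernel = "radial",
               cost = params$cost %||% 1,
               gamma = params$gamma %||% (1 / ncol(x)),
               scale = FALSE)
  },
  score = .svm_decision)

.register("svm_linear",
  fit = function(x, y, params) {
    e1071::svm(x, y, kernel = "linear", cost = params$cost %||% 1,
               scale = FALSE)
  },
  score = .svm_decision)

.register("random_forest",
  fit = function(x, y, params) {
    randomForest::randomForest(x, y, ntree = params$ntree %||% 500)
  },
  score = function(inner, x) {
    p <- stats::predict(inner, x, type = "prob")
    p[, "methylated"] - 0.5
  })

.register("knn",
  fit = function(x, y, params) {
    list(x = x, y = y, k = params$k %||% 5)
  },
  score = function(inner, x) {
    p <- class::knn(inner$x, x, inner$y, k = inner$k, prob = TRUE)
    pr <- attr(p, "prob")
    ifelse(p == "methylated", pr, 1 - pr) - 0.5
  })

.register("decision_tree",
  fit = function(x, y, params) {
    df <- data.frame(y = y, x)
    rpart::rpart(y ~ ., data = df, method = "class",
                 control = rpart::rpart.control(
                   minsplit = params$minsplit %||% 10,
                   cp = params$cp %||% 0.01))
  },
  score = function(inner, x) {
    p <- stats::predict(inner, data.frame(x), type = "prob")
    p[, "methylated"] - 0.5
  })

.register("naive_bayes",
  fit = function(x, y, params) {
    e1071::naiveBayes(x, y)
  },
  score = function(inner, x) {
    p <- stats::predict(inner, x, type = "raw")
    p[, "methylated"] - 0.5
  })

.register("kstar",
  fit = function(x, y, params) {
    # bandwidth from the median pairwise training distance
    d <- stats::dist(x[sample(nrow(x), min(nrow(x), 100L)), , drop = FALSE])
    list(x = x, y = y, b = max(stats::median(d), 1e-8))
  },
  score = function(inner, x) {
    vapply(seq_len(nrow(x)), function(i) {
      d2 <- colSums((t(inner$x) - x[i, ])^2)
      w <- exp(-sqrt(d2) / inner$b)
      sum(w[inner$y == "methylated"]) / sum(w) - 0.5
    }, numeric(1))
  })

#' List the registered classification algorithms
#' @return Character vector of registry names.
#' @export
list_algorithms <- function() sort(ls(.algorithms))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a binary methylation classifier
#'
#' Features are z-scored with statistics of the training matrix; the same
#' transform is applied at prediction time.
#'
#' @param x Numeric feature matrix (rows = islands).
#' @param labels `"methylated"` / `"unmethylated"` per row.
#' @param algorithm Registry name (see [list_algorithms()]).
#' @param params Named list of algorithm parameters (e.g. `cost`, `gamma`,
#'   `k`, `ntree`).
#' @return A `cgi_model`.
#' @export
train_classifier <- function(x, labels, algorithm = "svm_rbf",
                             params = list()) {
  if (!algorithm %in% list_algorithms())
    stop("unknown algorithm '", algorithm, "'; registered: ",
         paste(list_algorithms(), collapse = ", "))
  x <- as.matrix(x)
  y <- .as_label_factor(labels)
  if (any(is.na(y))) stop("labels must be methylated/unmethylated")
  std <- .std_fit(x)
  entry <- get(algorithm, envir = .algorithms)
  inner <- entry$fit(.std_apply(x, std), y, params)
  structure(list(algorithm = algorithm, inner = inner, std = std,
                 params = params, features = colnames(x),
                 task = "classification"),
            class = "cgi_model")
}

#' Decision scores of a trained model
#'
#' @param model A `cgi_model`.
#' @param x Feature matrix with the training schema.
#' @return Numeric decision values (positive = methylated).
#' @export
decision_scores <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(model$features) && !is.null(colnames(x)) &&
      !identical(colnames(x), model$features))
    stop("feature schema mismatch between model and matrix")
  entry <- get(model$algorithm, envir = .algorithms)
  as.numeric(entry$score(model$inner, .std_apply(x, model$std)))
}

#' Predict labels with per-mille certainty scores
#'
#' The certainty of each prediction is its absolute decision value scaled
#' to 0--1000 by the maximum absolute decision value in the predicted
#' batch (`round(1000 * |d_i| / max_j |d_j|)`); with all decision values 0
#' every certainty is 0.
#'
#' @param model A `cgi_model`.
#' @param x Feature matrix.
#' @return Data frame with `label`, `certainty` (integer 0--1000) and
#'   `decision` columns.
#' @export
predict_with_certainty <- function(model, x) {
  d <- decision_scores(model, x)
  mx <- max(abs(d))
  cert <- if (mx == 0) rep(0L, length(d))
          else as.integer(round(1000 * abs(d) / mx))
  data.frame(label = ifelse(d > 0, "methylated", "unmethylated"),
             certainty = cert, decision = d,
             stringsAsFactors = FALSE)
}

#' Train a support-vector-regression model on methylation fractions
#'
#' @param x Feature matrix.
#' @param fractions Methylation fractions in \[0, 1\].
#' @param params List with optional `cost`, `gamma`, `epsilon`.
#' @return A `cgi_model` with `task = "regression"`.
#' @export
train_regressor <- function(x, fractions, params = list()) {
  stopifnot(all(fractions >= 0 & fractions <= 1))
  x <- as.matrix(x)
  std <- .std_fit(x)
  inner <- if (stats::sd(fractions) == 0) {
    # degenerate constant target: libsvm keeps no support vectors
    list(constant = fractions[1])
  } else {
    e1071::svm(.std_apply(x, std), fractions,
               type = "eps-regression", kernel = "radial",
               cost = params$cost %||% 1,
               gamma = params$gamma %||% (1 / ncol(x)),
               epsilon = params$epsilon %||% 0.1,
               scale = FALSE)
  }
  structure(list(algorithm = "svr_rbf", inner = inner, std = std,
                 params = params, features = colnames(x),
                 task = "regression"),
            class = "cgi_model")
}

#' Predict methylation fractions with a regression model
#'
#' @param model A regression `cgi_model`.
#' @param x Feature matrix.
#' @return Numeric predictions clipped to \[0, 1\].
#' @export
predict_fraction <- function(model, x) {
  stopifnot(model$task == "regression")
  x <- as.matrix(x)
  if (!is.null(model$inner$constant))
    return(rep(model$inner$constant, nrow(x)))
  p <- stats::predict(model$inner, .std_apply(x, model$std))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
print.cgi_model <- function(x, ...) {
  cat(sprintf("cgi_model: %s (%s), %d feature(s)\n", x$algorithm, x$task,
              length(x$features)))
  invisible(x)
}
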