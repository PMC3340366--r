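test_that("metric closed forms hold for perfect, inverse and constant predictions", {
  perfect <- confusion(tp = 50, fp = 0, tn = 50, fn = 0)
  expect_equal(accuracy(perfect), 1)
  expect_equal(mcc(perfect), 1)

  inverse <- confusion(tp = 0, fp = 50, tn = 0, fn = 50)
  expect_equal(mcc(inverse), -1)

  # constant-unmethylated classifier on 71% unmethylated labels
  constant <- confusion(tp = 0, fp = 0, tn = 71, fn = 29)
  expect_equal(accuracy(constant), 0.71)
  expect_equal(mcc(constant), 0)
})

test_that("MCC is antisymmetric under prediction flip and bounded", {
  set.seed(13)
  for (i in 1:30) {
    truth <- sample(c("methylated", "unmethylated"), 40, replace = TRUE)
    pred <- sample(c("methylated", "unmethylated"), 40, replace = TRUE)
    cc <- confusion_counts(truth, pred)
    flipped <- confusion_counts(truth,
                                ifelse(pred == "methylated",
                                       "unmethylated", "methylated"))
    expect_equal(mcc(cc), -mcc(flipped))
    expect_true(abs(mcc(cc)) <= 1)
    expect_true(accuracy(cc) >= 0 && accuracy(cc) <= 1)
  }
})

test_that("AUC is the midrank statistic and flips with score negation", {
  labels <- c("methylated", "methylated", "unmethylated", "unmethylated")
  expect_equal(auc_score(c(4, 3, 2, 1), labels), 1)
  expect_equal(auc_score(c(1, 2, 3, 4), labels), 0)
  expect_equal(auc_score(c(2, 2, 2, 2), labels), 0.5)  # all ties
  set.seed(19)
  s <- rnorm(30)
  l <- sample(c("methylated", "unmethylated"), 30, replace = TRUE,
              prob = c(0.4, 0.6))
  expect_equal(auc_score(s, l), 1 - auc_score(-s, l))
  expect_error(auc_score(1:3, rep("methylated", 3)), "single class")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(20)
  s <- rnorm(50)
  l <- sample(c("methylated", "unmethylated"), 50, replace = TRUE)
  want <- as.numeric(pROC::auc(pROC::roc(
    response = factor(l, levels = c("unmethylated", "methylated")),
    predictor = s, quiet = TRUE, direction = "<")))
  expect_equal(auc_score(s, l), want)
})

test_that("average absolute error matches hand-computed cases", {
  expect_equal(aae(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(aae(c(0.1, 0.5, 0.9), c(0.2, 0.6, 1.0)), 0.1)
  expect_equal(aae(c(0, 1), c(1, 0)), 1)
  expect_error(aae(1:3 / 3, 1:2 / 2), "equal length")
})

make_sep_data <- function(n = 60, p_meth = 0.4, seed = 1) {
  set.seed(seed)
  y <- ifelse(runif(n) < p_meth, "methylated", "unmethylated")
  x <- cbind(sig = ifelse(y == "methylated", 1, 0) + rnorm(n, 0, 0.01),
             noise = rnorm(n))
  list(x = x, y = y)
}

test_that("the registry lists seven algorithms and rejects unknown ones", {
  expect_gte(length(list_algorithms()), 7L)
  expect_true(all(c("svm_rbf", "svm_linear", "random_forest", "knn",
                    "decision_tree", "naive_bayes", "kstar") %in%
                    list_algorithms()))
  d <- make_sep_data()
  expect_error(train_classifier(d$x, d$y, "boosted_stumps"), "unknown")
})

test_that("every registered algorithm separates a trivially separable set", {
  d <- make_sep_data(n = 80, seed = 2)
  for (alg in list_algorithms()) {
    model <- train_classifier(d$x, d$y, alg,
                              params = list(k = 1, gamma = 0.5))
    p <- predict_with_certainty(model, d$x)
    cc <- confusion_counts(d$y, p$label)
    expect_equal(mcc(cc), 1)
  }
})

test_that("repeated CV is reproducible, and scores reflect separability", {
  d <- make_sep_data(n = 60, seed = 3)
  a <- repeated_cv(d$x, d$y, "svm_linear", k = 5, reps = 3, seed = 7)
  b <- repeated_cv(d$x, d$y, "svm_linear", k = 5, reps = 3, seed = 7)
  expect_identical(a$cells, b$cells)
  expect_equal(nrow(a$cells), 15L)
  expect_equal(a$aggregate$mcc[["mean"]], 1)
  expect_equal(a$aggregate$mcc[["mean"]], mean(a$cells$mcc))

  # shuffled labels -> MCC near zero
  set.seed(8)
  y_perm <- sample(d$y)
  r <- repeated_cv(d$x, y_perm, "svm_rbf", k = 5, reps = 3, seed = 7)
  expect_lt(abs(r$aggregate$mcc[["mean"]]), 0.35)

  expect_error(repeated_cv(d$x, d$y, k = 100), "exceeds|fewer")
  expect_error(repeated_cv(d$x[1:12, ], d$y[1:12], k = 10), "fewer than k")
})

test_that("per-mille certainty scales decision values by the batch maximum", {
  d <- make_sep_data(n = 50, seed = 4)
  model <- train_classifier(d$x, d$y, "svm_linear")
  p <- predict_with_certainty(model, d$x)
  expect_equal(max(p$certainty), 1000L)
  i_max <- which.max(abs(p$decision))
  expect_equal(p$certainty[i_max], 1000L)
  expect_equal(p$certainty,
               as.integer(round(1000 * abs(p$decision) /
                                  max(abs(p$decision)))))
  # single instance is its own maximum
  p1 <- predict_with_certainty(model, d$x[1, , drop = FALSE])
  expect_equal(p1$certainty, 1000L)
  # hand-scaled pair
  fake <- p$decision[1:2]
  expect_equal(as.integer(round(1000 * abs(c(1, 0.5)) / 1)), c(1000L, 500L))
})

test_that("grid search returns the table argmax and extends at borders", {
  d <- make_sep_data(n = 50, seed = 5)
  spec <- grid_spec(log2c = c(-1, 1, 3), log2g = c(-5, -3, -1),
                    folds = 5, reps = 1, seed = 2, extend = FALSE,
                    refine = FALSE)
  res <- grid_search(d$x, d$y, spec)
  expect_equal(res$score, max(res$table$score, na.rm = TRUE))
  expect_equal(res$score, 1)

  # constant features: all points tie at MCC 0 -> smallest point returned
  x0 <- matrix(1, 40, 3)
  y0 <- rep(c("methylated", "unmethylated"), each = 20)
  res0 <- grid_search(x0, y0, spec)
  expect_equal(res0$log2c, -1)
  expect_equal(res0$log2g, -5)

  # a grid whose best point sits on the border triggers extension
  spec_b <- grid_spec(log2c = c(-9, -7), log2g = c(-9, -7), folds = 5,
                      reps = 1, seed = 2, extend = TRUE, refine = FALSE,
                      max_extensions = 2)
  res_b <- grid_search(d$x, d$y, spec_b)
  expect_true(res_b$extended)
  expect_gt(nrow(res_b$table), 4)
})

test_that("SVR predicts fractions and is scored by AAE", {
  set.seed(9)
  n <- 60
  x <- cbind(a = rnorm(n), b = rnorm(n))
  yconst <- rep(0.4, n)
  m <- train_regressor(x, yconst)
  expect_lt(aae(yconst, predict_fraction(m, x)), 0.05)

  # 9%-methylated-style skewed targets: a constant mean predictor has
  # AAE equal to the mean absolute deviation
  y <- rbeta(n, 1, 10)
  expect_equal(aae(y, rep(mean(y), n)), mean(abs(y - mean(y))))

  cv <- repeated_cv(x, yconst, k = 5, reps = 2, seed = 3,
                    task = "regression")
  expect_lt(cv$aggregate$aae[["mean"]], 0.06)
})

test_that("decision scores refuse a mismatched feature schema", {
  d <- make_sep_data()
  model <- train_classifier(d$x, d$y, "svm_rbf")
  x_bad <- d$x
  colnames(x_bad) <- c("wrong", "names")
  expect_error(decision_scores(model, x_bad), "schema mismatch")
})
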