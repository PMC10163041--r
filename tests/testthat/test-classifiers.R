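test_that("NN layer sizes follow the architecture rule", {
  expect_equal(unname(nn_layer_sizes(11)), c(24L, 12L))
  expect_equal(unname(nn_layer_sizes(4)), c(10L, 5L))
  expect_equal(unname(nn_layer_sizes(1)), c(4L, 2L))
  expect_error(nn_layer_sizes(0), ">= 1")
})

test_that("linear SVM separates linearly separable toy data perfectly", {
  X <- rbind(matrix(rnorm(40, -3), 20), matrix(rnorm(40, 3), 20))
  colnames(X) <- c("a", "b")
  y <- rep(c(0L, 1L), each = 20)
  m <- fit_classifier(classifier_spec("linear_svm"), X, y)
  expect_equal(balanced_accuracy(y, predict(m, X)$label), 1.0)
})

test_that("depth-1 forests cannot represent XOR structure", {
  withr::local_seed(4)
  g <- expand.grid(a = c(0, 1), b = c(0, 1))
  X <- as.matrix(g[rep(1:4, each = 25), ]) + matrix(rnorm(200, sd = 0.05), 100)
  y <- as.integer(xor(X[, 1] > 0.5, X[, 2] > 0.5))
  Xt <- as.matrix(g[rep(1:4, each = 50), ]) + matrix(rnorm(400, sd = 0.05), 200)
  yt <- as.integer(xor(Xt[, 1] > 0.5, Xt[, 2] > 0.5))
  m <- fit_classifier(classifier_spec("random_forest", seed = 1), X, y)
  ba <- balanced_accuracy(yt, predict(m, Xt)$label)
  expect_lt(abs(ba - 0.5), 0.1) # stumps are axis-aligned single splits
})

test_that("fits are deterministic given the seed", {
  ds <- gaussian_cohort(30, 30, shifts = c(1, 0, 0.5), seed = 2)
  X <- cohort_matrix(ds); y <- cohort_sex(ds)
  for (a in c("random_forest", "deep_nn")) {
    m1 <- fit_classifier(classifier_spec(a, seed = 77), X, y)
    m2 <- fit_classifier(classifier_spec(a, seed = 77), X, y)
    expect_equal(predict(m1, X)$score, predict(m2, X)$score)
  }
})

test_that("predictions expose consistent labels, scores, and shapes", {
  ds <- gaussian_cohort(25, 25, shifts = c(1.5, 0), seed = 5)
  X <- cohort_matrix(ds); y <- cohort_sex(ds)
  for (a in c("random_forest", "logistic_regression", "lda", "deep_nn")) {
    m <- fit_classifier(classifier_spec(a, seed = 3), X, y)
    pr <- predict(m, X)
    expect_true(all(pr$label %in% 0:1))
    expect_identical(pr$label, as.integer(pr$score > 0.5))
    empty <- predict(m, X[0, , drop = FALSE])
    expect_equal(nrow(empty), 0)
  }
  m <- fit_classifier(classifier_spec("lda"), X, y)
  expect_error(predict(m, X[, 1, drop = FALSE]), "feature")
  expect_error(fit_classifier(classifier_spec("lda"), X, rep(1L, nrow(X))),
               "binary")
})

test_that("single-feature designs work across the bank", {
  ds <- gaussian_cohort(30, 30, shifts = 2, seed = 6)
  X <- cohort_matrix(ds); y <- cohort_sex(ds)
  for (a in c("linear_svm", "random_forest", "logistic_regression", "lda", "deep_nn")) {
    m <- fit_classifier(classifier_spec(a, seed = 2), X, y)
    expect_gt(balanced_accuracy(y, predict(m, X)$label), 0.75)
  }
})

test_that("importance weights rank a dominant variable first", {
  ds <- gaussian_cohort(60, 60, shifts = c(2.5, 0, 0, 0), seed = 7)
  X <- cohort_matrix(ds); y <- cohort_sex(ds)
  for (a in c("linear_svm", "random_forest", "logistic_regression", "lda")) {
    m <- fit_classifier(classifier_spec(a, seed = 2), X, y)
    imp <- feature_importance(m)
    expect_named(imp, colnames(X))
    expect_equal(names(which.max(imp)), "v1")
  }
  nn <- fit_classifier(classifier_spec("deep_nn", seed = 2), X, y)
  expect_error(feature_importance(nn), "importance")
})

test_that("grid tuning returns the best-scoring point, first on ties", {
  ds <- gaussian_cohort(40, 40, shifts = c(1.2, 0), seed = 8)
  X <- cohort_matrix(ds); y <- cohort_sex(ds)

  single <- tune_classifier(classifier_spec("lda"), X, y,
                            scheme = cv_scheme(3, 1, seed = 1))
  expect_equal(single$algorithm, "lda")

  tuned <- tune_classifier(classifier_spec("linear_svm", seed = 4), X, y,
                           grid = data.frame(cost = c(0.01, 1, 100)),
                           scheme = cv_scheme(3, 1, seed = 1))
  scores <- attr(tuned, "cv_scores")
  expect_length(scores, 3)
  expect_equal(attr(tuned, "cv_score"), max(scores))
  expect_equal(tuned$params$cost, c(0.01, 1, 100)[which.max(scores)])

  again <- tune_classifier(classifier_spec("linear_svm", seed = 4), X, y,
                           grid = data.frame(cost = c(0.01, 1, 100)),
                           scheme = cv_scheme(3, 1, seed = 1))
  expect_identical(tuned$params, again$params)

  expect_error(tune_classifier(classifier_spec("lda"), X, y, grid = list(),
                               scheme = cv_scheme(3, 1, seed = 1)),
               "empty tuning grid")
})

test_that("the linear-activation NN tracks logistic regression on linear data", {
  ds <- gaussian_cohort(60, 60, shifts = c(1, 0.8, 0, 0), seed = 9)
  X <- cohort_matrix(ds); y <- cohort_sex(ds)
  test <- gaussian_cohort(50, 50, shifts = c(1, 0.8, 0, 0), seed = 10)
  Xt <- cohort_matrix(test); yt <- cohort_sex(test)
  nn <- fit_classifier(classifier_spec("deep_nn", seed = 1), X, y)
  lr <- fit_classifier(classifier_spec("logistic_regression"), X, y)
  ba_nn <- balanced_accuracy(yt, predict(nn, Xt)$label)
  ba_lr <- balanced_accuracy(yt, predict(lr, Xt)$label)
  expect_lt(abs(ba_nn - ba_lr), 0.12)
})
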