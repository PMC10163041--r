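test_that("univariate filters are calibrated and nested", {
  ds <- gaussian_cohort(60, 60, shifts = c(3, 0), seed = 1)
  X <- cohort_matrix(ds); y <- cohort_sex(ds)
  sel <- univariate_fpr_select(X, y, alpha = 0.05)
  expect_true(sel[["v1"]])
  expect_identical(unname(univariate_fpr_select(X, y, alpha = 0)),
                   c(FALSE, FALSE))

  # type-I calibration on pure noise
  withr::local_seed(2)
  Xn <- matrix(rnorm(100 * 400), 100, 400)
  colnames(Xn) <- paste0("n", 1:400)
  yn <- rep(0:1, each = 50)
  rate <- mean(univariate_fpr_select(Xn, yn, alpha = 0.05))
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)

  # Bonferroni filter is strictly nested in the uncorrected filter
  fpr <- univariate_fpr_select(Xn, yn, alpha = 0.05)
  fwe <- univariate_fwe_select(Xn, yn, alpha = 0.05)
  expect_true(all(fpr[fwe]))
  expect_lt(sum(fwe), sum(fpr))

  # single variable: the two filters coincide
  X1 <- Xn[, 1, drop = FALSE]
  expect_identical(univariate_fpr_select(X1, yn), univariate_fwe_select(X1, yn))

  # constant variables are never selected
  Xc <- cbind(Xn[, 1:2], const = 1)
  expect_false(univariate_fpr_select(Xc, yn)[["const"]])
})

test_that("the vectorised F statistic agrees with anova(lm())", {
  withr::local_seed(3)
  X <- matrix(rnorm(80 * 3), 80, 3)
  X[, 1] <- X[, 1] + rep(c(0, 0.8), each = 40)
  colnames(X) <- c("a", "b", "c")
  y <- rep(0:1, each = 40)
  fs <- painsex:::f_statistic(X, y)
  for (j in 1:3) {
    a <- anova(lm(X[, j] ~ factor(y)))
    expect_equal(fs$statistic[j], a$`F value`[1])
    expect_equal(fs$p_value[j], a$`Pr(>F)`[1])
  }
})

test_that("top-k F selection finds the informative variable and honours the grid", {
  ds <- gaussian_cohort(50, 50, shifts = c(2, 0, 0, 0), seed = 4)
  X <- cohort_matrix(ds); y <- cohort_sex(ds)
  clf <- classifier_spec("lda")
  scheme <- cv_scheme(3, 1, seed = 5)
  sel <- top_k_f_select(X, y, clf, scheme = scheme)
  expect_true(sel[["v1"]])

  all_k <- top_k_f_select(X, y, clf, scheme = scheme, k_grid = ncol(X))
  expect_true(all(all_k))

  expect_identical(top_k_f_select(X, y, clf, scheme = scheme),
                   top_k_f_select(X, y, clf, scheme = scheme))
  expect_error(top_k_f_select(X, y, clf, scheme = scheme, k_grid = integer(0)),
               "empty k grid")
  expect_error(top_k_f_select(X, y, clf, scheme = scheme, k_grid = 99),
               "outside")
})

test_that("select-from-model keeps above-mean importances only", {
  ds <- gaussian_cohort(50, 50, shifts = c(2.5, 0, 0, 0, 0, 0), seed = 6)
  X <- cohort_matrix(ds); y <- cohort_sex(ds)
  sel <- model_importance_select(X, y, classifier_spec("logistic_regression"),
                                 scheme = cv_scheme(3, 1, seed = 2))
  expect_true(sel[["v1"]])
  expect_lt(sum(sel), ncol(X)) # mean threshold always excludes some variable
})

test_that("RFE retains informative pairs and handles one variable", {
  ds <- gaussian_cohort(50, 50, shifts = c(1.5, 1.5, 0, 0, 0), seed = 7)
  X <- cohort_matrix(ds); y <- cohort_sex(ds)
  sel <- rfe_select(X, y, classifier_spec("lda"), scheme = cv_scheme(3, 2, seed = 3))
  expect_true(sel[["v1"]] && sel[["v2"]])

  X1 <- X[, 1, drop = FALSE]
  sel1 <- rfe_select(X1, y, classifier_spec("lda"), scheme = cv_scheme(3, 1, seed = 3))
  expect_true(sel1[["v1"]])
})

test_that("sequential selection matches exhaustive subset search on 3 variables", {
  ds <- gaussian_cohort(40, 40, shifts = c(3, 1, 0), seed = 8)
  X <- cohort_matrix(ds); y <- cohort_sex(ds)
  clf <- classifier_spec("lda")
  scheme <- cv_scheme(4, 1, seed = 9)
  folds <- cv_folds(y, scheme)

  subset_score <- function(feats) {
    mean(vapply(folds, function(f) {
      m <- fit_classifier(clf, X[f$train, feats, drop = FALSE], y[f$train])
      balanced_accuracy(y[f$test], predict(m, X[f$test, feats, drop = FALSE])$label)
    }, numeric(1)))
  }
  subsets <- unlist(lapply(1:3, function(k) combn(3, k, simplify = FALSE)),
                    recursive = FALSE)
  scores <- vapply(subsets, subset_score, numeric(1))
  best <- subsets[[which.max(scores)]]

  fwd <- sfs_select(X, y, clf, direction = "forward", scheme = scheme)
  bwd <- sfs_select(X, y, clf, direction = "backward", scheme = scheme)
  expect_setequal(which(fwd), best)
  expect_setequal(which(bwd), best)
})

test_that("forward selection starts with a perfectly predictive variable", {
  withr::local_seed(10)
  n <- 60
  y <- rep(0:1, each = n / 2)
  X <- cbind(perfect = y + rnorm(n, sd = 0.01), noise1 = rnorm(n), noise2 = rnorm(n))
  sel <- sfs_select(X, y, classifier_spec("lda"), direction = "forward",
                    scheme = cv_scheme(3, 1, seed = 11))
  expect_true(sel[["perfect"]])
})

test_that("permutation importance flags predictive variables and rejects n = 0", {
  withr::local_seed(12)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- cbind(signal = y + rnorm(n, sd = 0.05), noise = rnorm(n))
  sel <- permutation_importance_select(X, y, classifier_spec("lda"),
                                       n_repeats = 20,
                                       scheme = cv_scheme(4, 1, seed = 13))
  expect_true(sel[["signal"]])
  expect_error(
    permutation_importance_select(X, y, classifier_spec("lda"), n_repeats = 0,
                                  scheme = cv_scheme(4, 1, seed = 13)),
    "n_repeats")
})

test_that("selection matrix has the full roster and consistent vote sums", {
  cfg <- cohort_config(n_male = 35, n_female = 30)
  ds <- simulate_cohort(cfg, seed = 14) |> impute_censored() |> log10_transform()
  scheme <- cv_scheme(2, 1, seed = 15)
  sel <- build_selection_matrix(ds, scheme = scheme)
  expect_equal(ncol(sel$votes), 26)
  expect_equal(nrow(sel$votes), 11)
  expect_true(all(sel$votes %in% 0:1))
  expect_equal(sel$row_sums, rowSums(sel$votes))
  expect_true(all(c("fpr", "fwe") %in% colnames(sel$votes)))
  expect_equal(sum(grepl("_lda$", colnames(sel$votes))), 6)

  # the strongest simulated effect collects the most votes
  expect_equal(names(which.max(sel$row_sums)), "pressure_blunt")

  td <- tidy(sel)
  expect_equal(nrow(td), 11 * 26)
  g <- glance(sel)
  expect_equal(g$n_methods, 26)
  expect_equal(g$n_folds, 2)
})
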