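test_that("balanced accuracy matches hand-computed confusion rates", {
  expect_equal(balanced_accuracy(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(balanced_accuracy(c(1, 1, 0, 0), c(1, 1, 1, 1)), 0.5)
  # TP = 3, FN = 1, TN = 2, FP = 2 -> (0.75 + 0.5) / 2
  y_true <- c(1, 1, 1, 1, 0, 0, 0, 0)
  y_pred <- c(1, 1, 1, 0, 0, 0, 1, 1)
  expect_equal(balanced_accuracy(y_true, y_pred), 0.625)
  expect_error(balanced_accuracy(c(1, 1), c(1, 0)), "single-class")
  expect_error(balanced_accuracy(c(1, 0), c(1, 0, 1)), "length")
})

test_that("ROC-AUC equals the exhaustive pair-comparison oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  withr::local_seed(1)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    s <- round(rnorm(n), 1) # coarse scores force ties
    expect_equal(roc_auc(y, s), auc_oracle(y, s))
  }
  expect_error(roc_auc(c(1, 1), c(0.1, 0.2)), "single-class")

  # independent library cross-check
  withr::local_seed(4)
  y <- rep(0:1, each = 40)
  s <- rnorm(80) + y
  expect_equal(roc_auc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<", levels = c(0, 1)))))
})

test_that("performance summaries report median, percentile CI, and success flag", {
  s <- summarize_performance(rep(0.8, 5))
  expect_equal(s$median, 0.8)
  expect_equal(c(s$ci_low, s$ci_high), c(0.8, 0.8))
  expect_true(s$trained_successfully)

  sym <- summarize_performance(c(0.3, 0.4, 0.5, 0.6, 0.7))
  expect_false(sym$trained_successfully)

  withr::local_seed(2)
  u <- summarize_performance(runif(2000))
  expect_lt(abs(u$ci_low - 0.025), 0.02)
  expect_lt(abs(u$ci_high - 0.975), 0.02)

  expect_error(summarize_performance(numeric(0)), "no samples")
})

test_that("the validation experiment draws the right subsamples and reproduces", {
  ds <- simulate_cohort(cohort_config(), seed = 20) |>
    impute_censored() |> log10_transform()
  sp <- optimal_split(ds, n_candidates = 200, seed = 21)
  spec <- classifier_spec("lda")

  one <- run_validation_experiment(ds, sp, "pressure_blunt", spec, n_runs = 1,
                                   seed = 22)
  expect_equal(nrow(one$samples), 1)
  g1 <- glance(one)
  expect_equal(g1$ba_median, g1$ba_ci_low)

  pd <- run_validation_experiment(ds, sp, cohort_meta(ds)$name, spec,
                                  n_runs = 30, seed = 23)
  expect_equal(nrow(pd$samples), 30)
  expect_true(all(pd$samples$balanced_accuracy >= 0 & pd$samples$balanced_accuracy <= 1))

  pd2 <- run_validation_experiment(ds, sp, cohort_meta(ds)$name, spec,
                                   n_runs = 30, seed = 23)
  expect_equal(pd$samples, pd2$samples)

  strong <- run_validation_experiment(ds, sp, "pressure_blunt", spec,
                                      n_runs = 30, seed = 24)
  expect_true(glance(strong)$trained_successfully)

  expect_error(run_validation_experiment(ds, sp, character(0), spec), "empty feature set")
  expect_error(run_validation_experiment(ds, sp, "nope", spec), "not in dataset")
})

test_that("permuted training hovers at guessing level", {
  ds <- simulate_cohort(cohort_config(), seed = 25) |>
    impute_censored() |> log10_transform()
  sp <- optimal_split(ds, n_candidates = 200, seed = 26)
  pc <- permutation_control(ds, sp, cohort_meta(ds)$name,
                            classifier_spec("lda"), n_runs = 50, seed = 27)
  g <- glance(pc)
  expect_lte(g$ba_ci_low, 0.5)
  expect_gte(g$ba_ci_high, 0.5)
  expect_lt(abs(g$ba_median - 0.5), 0.1)
  expect_false(g$trained_successfully)
  expect_equal(pc$feature_set, "permuted")
})

test_that("unselected control runs on the exact complement", {
  ds <- simulate_cohort(cohort_config(), seed = 28) |>
    impute_censored() |> log10_transform()
  sp <- optimal_split(ds, n_candidates = 200, seed = 29)
  sel <- c("pressure_blunt", "pressure_punctate",
           "pressure_punctate_capsaicin", "electrical_current")
  uc <- unselected_control(ds, sp, sel, classifier_spec("lda"),
                           n_runs = 20, seed = 30)
  expect_setequal(c(sel, uc$features), cohort_meta(ds)$name)
  expect_length(intersect(sel, uc$features), 0)

  # complement of the empty set reproduces the full-set experiment
  full <- run_validation_experiment(ds, sp, cohort_meta(ds)$name,
                                    classifier_spec("lda"), n_runs = 10, seed = 31)
  none <- unselected_control(ds, sp, character(0), classifier_spec("lda"),
                             n_runs = 10, seed = 31)
  expect_equal(full$samples, none$samples)

  expect_error(unselected_control(ds, sp, cohort_meta(ds)$name,
                                  classifier_spec("lda")), "complement")
})

test_that("evaluate_all produces one cell per classifier and condition", {
  ds <- simulate_cohort(cohort_config(), seed = 32) |>
    impute_censored() |> log10_transform()
  sp <- optimal_split(ds, n_candidates = 100, seed = 33)
  bank <- default_classifier_bank(seed = 1, include_nn = FALSE)[c(1, 3)]
  fsets <- list(full = cohort_meta(ds)$name,
                sparse_permuted = list(features = "pressure_blunt", permuted = TRUE))
  rep <- evaluate_all(ds, sp, fsets, classifiers = bank, n_runs = 8, seed = 34)
  expect_length(rep$cells, 4)
  g <- glance(rep)
  expect_setequal(g$feature_set, c("full", "sparse_permuted"))
  tb <- performance_table(rep)
  expect_equal(nrow(tb), 4)
  expect_match(tb$balanced_accuracy[1], "^[01]\\.\\d{2} \\([01]\\.\\d{2}-")
  td <- tidy(rep)
  expect_equal(nrow(td), 4 * 8)
})
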