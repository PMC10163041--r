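#' Balanced accuracy
#'
#' Mean of sensitivity and specificity; 0.5 equals guessing regardless of
#' class imbalance.
#'
#' @param y_true Binary truth labels (both classes present).
#' @param y_pred Binary predictions of the same length.
#' @return Scalar in `[0, 1]`.
#' @examples
#' balanced_accuracy(c(1, 1, 1, 1, 0, 0, 0, 0), c(1, 1, 1, 0, 0, 0, 1, 1))
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(unique(y_true)) < 2) abort("single-class truth")
  sens <- mean(y_pred[y_true == 1L] == 1L)
  spec <- mean(y_pred[y_true == 0L] == 0L)
  (sens + spec) / 2
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen class-1 case receives a higher
#' score than a randomly chosen class-0 case, ties counted half (the
#' Mann--Whitney identity, computed from midranks).
#'
#' @param y_true Binary truth labels (both classes present).
#' @param scores Continuous classifier scores oriented toward class 1.
#' @return Scalar in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) abort("length mismatch")
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
  if (n1 == 0 || n0 == 0) abort("single-class truth")
  r <- rank(scores) # midranks: ties count half
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Summarise a performance-sample distribution
#'
#' @param samples Numeric vector of per-run performance values.
#' @return One-row tibble: `median`, `ci_low`/`ci_high` (2.5th and 97.5th
#'   empirical percentiles) and `trained_successfully` (the CI excludes the
#'   0.5 guessing level from above).
#' @export
summarize_performance <- function(samples) {
  if (length(samples) == 0) abort("no samples")
  ci <- unname(quantile(samples, c(0.025, 0.975)))
  tibble::tibble(median = median(samples), ci_low = ci[1], ci_high = ci[2],
                 trained_successfully = ci[1] > 0.5)
}

#' The repeated train/validate experiment
#'
#' For each of `n_runs` runs, trains the classifier on a class-proportional
#' random 67% subsample of the training partition, restricted to the given
#' feature set, and evaluates balanced accuracy and ROC-AUC on a
#' class-proportional random 80% subsample of the held-out validation
#' partition. With `permute_training = TRUE` every training-partition
#' column is independently permuted afresh each run (the overfitting
#' control: performance should then hover at the 0.5 guessing level).
#'
#' @param data A log-scale `pain_cohort`.
#' @param split A `split_result` partitioning `data`.
#' @param features Character vector of variable names to train on.
#' @param spec A `classifier_spec`.
#' @param n_runs Number of runs (default 100).
#' @param train_frac,val_frac Subsample fractions (defaults 0.67 and 0.80).
#' @param seed Integer seed; same seed reproduces the distribution exactly.
#' @param permute_training Permute training columns (negative control)?
#' @param feature_set_label Label stored in the result.
#' @return A `performance_distribution`: per-run samples plus summaries.
#' @export
run_validation_experiment <- function(data, split, features, spec,
                                      n_runs = 100, train_frac = 0.67,
                                      val_frac = 0.80, seed = NULL,
                                      permute_training = FALSE,
                                      feature_set_label = "custom") {
  stopifnot(inherits(data, "pain_cohort"), inherits(spec, "classifier_spec"))
  if (length(features) == 0) abort("empty feature set")
  vals <- cohort_matrix(data)
  missing <- setdiff(features, colnames(vals))
  if (length(missing)) abort(paste0("features not in dataset: ",
                                    paste(missing, collapse = ", ")))
  y <- cohort_sex(data)
  tr <- match(split$train_ids, data$subject_id)
  va <- match(split$validation_ids, data$subject_id)
  if (anyNA(tr) || anyNA(va)) abort("split does not partition this dataset")
  Xtr_all <- vals[tr, features, drop = FALSE]
  ytr <- y[tr]
  Xva_all <- vals[va, features, drop = FALSE]
  yva <- y[va]

  samples <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_runs), function(r) {
      Xtr <- Xtr_all
      if (permute_training) {
        Xtr <- apply(Xtr, 2, sample)
        colnames(Xtr) <- features
      }
      i_tr <- stratified_indices(ytr, train_frac)
      i_va <- stratified_indices(yva, val_frac)
      m <- fit_classifier(spec, Xtr[i_tr, , drop = FALSE], ytr[i_tr])
      pr <- predict(m, Xva_all[i_va, , drop = FALSE])
      tibble::tibble(run = r,
                     balanced_accuracy = balanced_accuracy(yva[i_va], pr$label),
                     roc_auc = roc_auc(yva[i_va], pr$score))
    })
  })

  structure(list(samples = samples,
                 classifier = spec$algorithm,
                 feature_set = feature_set_label,
                 features = features,
                 n_runs = n_runs, seed = seed,
                 permuted = permute_training),
            class = "performance_distribution")
}

#' Negative control: training on permuted data
#'
#' Identical to [run_validation_experiment()] except each training-partition
#' column is independently permuted (a fresh permutation every run) before
#' subsampling; validation data are untouched. Each column's marginal
#' multiset is unchanged, only its link to the labels is destroyed.
#'
#' @inheritParams run_validation_experiment
#' @return A `performance_distribution`.
#' @export
permutation_control <- function(data, split, features, spec, n_runs = 100,
                                seed = NULL, ...) {
  run_validation_experiment(data, split, features, spec, n_runs = n_runs,
                            seed = seed, permute_training = TRUE,
                            feature_set_label = "permuted", ...)
}

#' Negative control: training on the unselected features
#'
#' Runs the validation experiment on the complement of the selected feature
#' set (the variables feature selection did not find informative).
#'
#' @inheritParams run_validation_experiment
#' @param selected Character vector of selected variable names; the
#'   experiment uses all other variables.
#' @return A `performance_distribution`.
#' @export
unselected_control <- function(data, split, selected, spec, n_runs = 100,
                               seed = NULL, ...) {
  all_vars <- cohort_meta(data)$name
  complement <- setdiff(all_vars, selected)
  if (length(complement) == 0) abort("complement of the selected set is empty")
  run_validation_experiment(data, split, complement, spec, n_runs = n_runs,
                            seed = seed, feature_set_label = "unselected", ...)
}

#' @export
print.performance_distribution <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<performance_distribution> %s on '%s' (%d runs)\n  balanced accuracy %.2f (%.2f-%.2f)%s | roc-auc %.2f (%.2f-%.2f)\n",
    x$classifier, x$feature_set, x$n_runs,
    g$ba_median, g$ba_ci_low, g$ba_ci_high,
    if (g$trained_successfully) " *" else "",
    g$auc_median, g$auc_ci_low, g$auc_ci_high))
  invisible(x)
}

#' @export
tidy.performance_distribution <- function(x, ...) {
  dplyr::mutate(x$samples, classifier = x$classifier,
                feature_set = x$feature_set, .before = 1)
}

#' @export
glance.performance_distribution <- function(x, ...) {
  ba <- summarize_performance(x$samples$balanced_accuracy)
  auc <- summarize_performance(x$samples$roc_auc)
  tibble::tibble(classifier = x$classifier, feature_set = x$feature_set,
                 n_runs = x$n_runs,
                 ba_median = ba$median, ba_ci_low = ba$ci_low,
                 ba_ci_high = ba$ci_high,
                 auc_median = auc$median, auc_ci_low = auc$ci_low,
                 auc_ci_high = auc$ci_high,
                 trained_successfully = ba$trained_successfully)
}

#' Evaluate a classifier bank across feature-set conditions
#'
#' Runs [run_validation_experiment()] for every classifier and every named
#' feature-set condition. A condition named `"permuted"` or given as
#' `list(features = ..., permuted = TRUE)` runs the permutation control on
#' those features.
#'
#' @param data A log-scale `pain_cohort`.
#' @param split A `split_result`.
#' @param feature_sets Named list; each element is a character vector of
#'   features or a list with `features` and optional `permuted` flag.
#' @param classifiers Named list of `classifier_spec`s.
#' @param n_runs Runs per cell.
#' @param seed Base seed; each cell receives a derived sub-seed.
#' @return An `evaluation_report`: list of `performance_distribution`s with
#'   [tidy()]/[glance()] methods and a Table-1-shaped [performance_table()].
#' @export
evaluate_all <- function(data, split, feature_sets,
                         classifiers = default_classifier_bank(seed),
                         n_runs = 100, seed = NULL) {
  cells <- list()
  k <- 0L
  for (fs_name in names(feature_sets)) {
    fs <- feature_sets[[fs_name]]
    if (!is.list(fs)) fs <- list(features = fs, permuted = FALSE)
    for (clf_name in names(classifiers)) {
      k <- k + 1L
      cells[[paste(fs_name, clf_name, sep = ".")]] <-
        run_validation_experiment(
          data, split, fs$features, classifiers[[clf_name]],
          n_runs = n_runs, seed = spawn_seed(seed, k),
          permute_training = isTRUE(fs$permuted),
          feature_set_label = fs_name)
    }
  }
  structure(list(cells = cells, n_runs = n_runs, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d cells, %d runs each\n",
              length(x$cells), x$n_runs))
  print(performance_table(x), n = Inf)
  invisible(x)
}

#' @export
tidy.evaluation_report <- function(x, ...) {
  purrr::map_dfr(x$cells, tidy)
}

#' @export
glance.evaluation_report <- function(x, ...) {
  purrr::map_dfr(x$cells, glance)
}

#' Median (CI) performance table
#'
#' One row per feature-set condition and classifier, with balanced accuracy
#' and ROC-AUC formatted as "median (2.5th--97.5th percentile)".
#'
#' @param report An `evaluation_report`.
#' @return Tibble with formatted columns.
#' @export
performance_table <- function(report) {
  fmt <- function(m, lo, hi) sprintf("%.2f (%.2f-%.2f)", m, lo, hi)
  glance(report) |>
    dplyr::transmute(
      feature_set = .data$feature_set,
      classifier = .data$classifier,
      balanced_accuracy = fmt(.data$ba_median, .data$ba_ci_low, .data$ba_ci_high),
      roc_auc = fmt(.data$auc_median, .data$auc_ci_low, .data$auc_ci_high),
      trained_successfully = .data$trained_successfully)
}

#' @export
autoplot.evaluation_report <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(c("balanced_accuracy", "roc_auc"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$classifier, .data$value)) +
    ggplot2::geom_hline(yintercept = 0.5, colour = "red", linetype = "dashed") +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.5, outlier.size = 0.4) +
    ggplot2::facet_grid(metric ~ feature_set) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
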