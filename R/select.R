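#' Repeated stratified cross-validation scheme
#'
#' @param n_splits Folds per repeat (>= 2; default 5).
#' @param n_repeats Repeats (default 20, giving 100 folds).
#' @param stratified Preserve class proportions within folds?
#' @param seed Integer seed for fold assignment and any stochastic selector
#'   step.
#' @return A `cv_scheme`.
#' @export
cv_scheme <- function(n_splits = 5, n_repeats = 20, stratified = TRUE, seed = NULL) {
  if (n_splits < 2) abort("n_splits must be at least 2")
  if (n_repeats < 1) abort("n_repeats must be at least 1")
  structure(list(n_splits = as.integer(n_splits),
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified), seed = seed),
            class = "cv_scheme")
}

#' Fold indices for a scheme
#'
#' @param y Binary label vector.
#' @param scheme A [cv_scheme()].
#' @return List of `n_splits * n_repeats` folds, each with `train` and
#'   `test` index vectors.
#' @export
cv_folds <- function(y, scheme = cv_scheme()) {
  n <- length(y)
  with_seed(scheme$seed, {
    folds <- list()
    for (r in seq_len(scheme$n_repeats)) {
      fold_id <- integer(n)
      if (scheme$stratified) {
        for (ix in split(seq_len(n), y)) {
          fold_id[sample(ix)] <- rep_len(seq_len(scheme$n_splits), length(ix))
        }
      } else {
        fold_id[sample(n)] <- rep_len(seq_len(scheme$n_splits), n)
      }
      for (f in seq_len(scheme$n_splits)) {
        folds[[length(folds) + 1L]] <- list(train = which(fold_id != f),
                                            test = which(fold_id == f))
      }
    }
    folds
  })
}

# Vectorised one-way F statistic for a binary grouping (equivalent to the
# squared pooled-variance t statistic), with p-values from F(1, n - 2).
f_statistic <- function(X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  i0 <- y == 0L; i1 <- y == 1L
  n0 <- sum(i0); n1 <- sum(i1); n <- n0 + n1
  m0 <- colMeans(X[i0, , drop = FALSE]); m1 <- colMeans(X[i1, , drop = FALSE])
  v0 <- apply(X[i0, , drop = FALSE], 2, var)
  v1 <- apply(X[i1, , drop = FALSE], 2, var)
  sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n - 2)
  f <- (m1 - m0)^2 / (sp2 * (1 / n0 + 1 / n1))
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  tibble::tibble(variable = colnames(X) %||% paste0("V", seq_along(f)),
                 statistic = unname(f), p_value = unname(p))
}

#' Univariate filter selectors
#'
#' Select variables whose one-way F-test p-value against the class labels
#' falls below `alpha`: uncorrected ("false positive rate" filter) or
#' Bonferroni-corrected across variables ("family-wise error rate" filter).
#' Constant variables have an undefined p-value and are never selected.
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param alpha Significance threshold (default 0.05).
#' @return Named logical vector of selections.
#' @export
univariate_fpr_select <- function(X, y, alpha = 0.05) {
  assert_binary_labels(y)
  p <- f_statistic(X, y)$p_value
  out <- !is.na(p) & p < alpha
  setNames(out, colnames(as.matrix(X)))
}

#' @rdname univariate_fpr_select
#' @export
univariate_fwe_select <- function(X, y, alpha = 0.05) {
  univariate_fpr_select(X, y, alpha = alpha / ncol(as.matrix(X)))
}

fold_ba <- function(spec, Xtr, ytr, Xte, yte, features) {
  m <- fit_classifier(spec, Xtr[, features, drop = FALSE], ytr)
  pr <- predict(m, Xte[, features, drop = FALSE])
  balanced_accuracy(yte, pr$label)
}

# ---- per-fold cores of the multivariate selector families ----

sel_topk <- function(spec, Xtr, ytr, Xte, yte, k_grid) {
  f <- f_statistic(Xtr, ytr)$statistic
  f[is.na(f)] <- -Inf
  ord <- order(-f)
  ba <- vapply(k_grid, function(k) {
    fold_ba(spec, Xtr, ytr, Xte, yte, ord[seq_len(k)])
  }, numeric(1))
  k_best <- k_grid[which.max(ba)]
  sel <- rep(FALSE, ncol(Xtr))
  sel[ord[seq_len(k_best)]] <- TRUE
  sel
}

sel_sfm <- function(spec, Xtr, ytr) {
  m <- fit_classifier(spec, Xtr, ytr)
  imp <- feature_importance(m)
  imp > mean(imp)
}

sel_rfe <- function(spec, Xtr, ytr, Xte, yte) {
  d <- ncol(Xtr)
  active <- seq_len(d)
  sets <- vector("list", d)
  ba <- numeric(d)
  for (step in seq_len(d)) {
    sets[[step]] <- active
    ba[step] <- fold_ba(spec, Xtr, ytr, Xte, yte, active)
    if (length(active) == 1L) break
    m <- fit_classifier(spec, Xtr[, active, drop = FALSE], ytr)
    imp <- feature_importance(m)
    active <- active[-which.min(imp)]
  }
  # ties resolved toward the smaller (later-visited) set
  best <- length(ba) - which.max(rev(ba)) + 1L
  sel <- rep(FALSE, d)
  sel[sets[[best]]] <- TRUE
  sel
}

sel_sfs <- function(spec, Xtr, ytr, Xte, yte, direction) {
  d <- ncol(Xtr)
  if (direction == "forward") {
    current <- integer(0)
    sets <- vector("list", d)
    ba <- numeric(d)
    for (step in seq_len(d)) {
      cands <- setdiff(seq_len(d), current)
      scores <- vapply(cands, function(j) {
        fold_ba(spec, Xtr, ytr, Xte, yte, c(current, j))
      }, numeric(1))
      current <- c(current, cands[which.max(scores)])
      sets[[step]] <- current
      ba[step] <- max(scores)
    }
    best <- which.max(ba) # ties -> smaller set
  } else {
    current <- seq_len(d)
    sets <- vector("list", d)
    ba <- numeric(d)
    for (step in seq_len(d)) {
      sets[[step]] <- current
      ba[step] <- fold_ba(spec, Xtr, ytr, Xte, yte, current)
      if (length(current) == 1L) break
      scores <- vapply(seq_along(current), function(i) {
        fold_ba(spec, Xtr, ytr, Xte, yte, current[-i])
      }, numeric(1))
      current <- current[-which.max(scores)]
    }
    best <- length(ba) - which.max(rev(ba)) + 1L # ties -> smaller set
  }
  sel <- rep(FALSE, d)
  sel[sets[[best]]] <- TRUE
  sel
}

sel_permimp <- function(spec, Xtr, ytr, Xte, yte, n_repeats) {
  if (n_repeats < 1) abort("permutation importance requires n_repeats >= 1")
  m <- fit_classifier(spec, Xtr, ytr)
  base <- balanced_accuracy(yte, predict(m, Xte)$label)
  d <- ncol(Xte)
  nte <- nrow(Xte)
  # stack all (variable, repeat) permutations into one prediction call
  blocks <- vector("list", d * n_repeats)
  k <- 0L
  for (j in seq_len(d)) {
    for (r in seq_len(n_repeats)) {
      k <- k + 1L
      Xp <- Xte
      Xp[, j] <- sample(Xp[, j])
      blocks[[k]] <- Xp
    }
  }
  labels <- predict(m, do.call(rbind, blocks))$label
  drops <- vapply(seq_len(d * n_repeats), function(k) {
    base - balanced_accuracy(yte, labels[(k - 1L) * nte + seq_len(nte)])
  }, numeric(1))
  # blocks are variable-major: column k of this matrix holds variable k's repeats
  imp <- colMeans(matrix(drops, nrow = n_repeats))
  imp > 0
}

run_over_folds <- function(X, y, folds, core) {
  votes <- vapply(folds, function(f) {
    core(X[f$train, , drop = FALSE], y[f$train],
         X[f$test, , drop = FALSE], y[f$test])
  }, logical(ncol(X)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = ncol(X))
  rowMeans(votes) > 0.5
}

#' Multivariate selectors run across a cross-validation scheme
#'
#' Each selector is run once per fold of the scheme on the fold's training
#' part, with subset sizes scored by balanced accuracy on the fold's
#' held-out part, and aggregated to one decision per variable by majority
#' vote over folds. `top_k_f_select` takes the `k` best variables by F
#' statistic with `k` chosen over a grid; `model_importance_select` keeps
#' variables whose importance in the fitted classifier exceeds the mean
#' importance; `rfe_select` recursively eliminates the least important
#' variable; `sfs_select` greedily adds (forward) or drops (backward)
#' variables; `permutation_importance_select` keeps variables whose mean
#' held-out balanced-accuracy drop over `n_repeats` column permutations is
#' strictly positive.
#'
#' @param X Feature matrix (log-scale thresholds).
#' @param y Binary labels.
#' @param clf A `classifier_spec` (importance-based selectors need a
#'   classifier exposing importance weights).
#' @param scheme A [cv_scheme()].
#' @param k_grid Candidate set sizes for `top_k_f_select` (default
#'   `1:ncol(X)`).
#' @param direction `"forward"` or `"backward"` for `sfs_select`.
#' @param n_repeats Permutations per variable for
#'   `permutation_importance_select` (default 50).
#' @return Named logical vector of selections.
#' @export
top_k_f_select <- function(X, y, clf, scheme = cv_scheme(), k_grid = NULL) {
  X <- as.matrix(X)
  k_grid <- k_grid %||% seq_len(ncol(X))
  if (length(k_grid) == 0) abort("empty k grid")
  if (any(k_grid < 1 | k_grid > ncol(X))) abort("k grid outside 1..n_variables")
  folds <- cv_folds(y, scheme)
  sel <- with_seed(spawn_seed(scheme$seed, 101L), run_over_folds(X, y, folds, function(Xtr, ytr, Xte, yte) {
    sel_topk(clf, Xtr, ytr, Xte, yte, k_grid)
  }))
  setNames(sel, colnames(X))
}

#' @rdname top_k_f_select
#' @export
model_importance_select <- function(X, y, clf, scheme = cv_scheme()) {
  X <- as.matrix(X)
  folds <- cv_folds(y, scheme)
  sel <- with_seed(spawn_seed(scheme$seed, 102L), run_over_folds(X, y, folds, function(Xtr, ytr, Xte, yte) {
    sel_sfm(clf, Xtr, ytr)
  }))
  setNames(sel, colnames(X))
}

#' @rdname top_k_f_select
#' @export
rfe_select <- function(X, y, clf, scheme = cv_scheme()) {
  X <- as.matrix(X)
  folds <- cv_folds(y, scheme)
  sel <- with_seed(spawn_seed(scheme$seed, 103L), run_over_folds(X, y, folds, function(Xtr, ytr, Xte, yte) {
    sel_rfe(clf, Xtr, ytr, Xte, yte)
  }))
  setNames(sel, colnames(X))
}

#' @rdname top_k_f_select
#' @export
sfs_select <- function(X, y, clf, direction = c("forward", "backward"),
                       scheme = cv_scheme()) {
  direction <- match.arg(direction)
  X <- as.matrix(X)
  folds <- cv_folds(y, scheme)
  sel <- with_seed(spawn_seed(scheme$seed, 104L), run_over_folds(X, y, folds, function(Xtr, ytr, Xte, yte) {
    sel_sfs(clf, Xtr, ytr, Xte, yte, direction)
  }))
  setNames(sel, colnames(X))
}

#' @rdname top_k_f_select
#' @export
permutation_importance_select <- function(X, y, clf, n_repeats = 50,
                                          scheme = cv_scheme()) {
  X <- as.matrix(X)
  if (n_repeats < 1) abort("n_repeats must be at least 1")
  folds <- cv_folds(y, scheme)
  sel <- with_seed(spawn_seed(scheme$seed, 105L), run_over_folds(X, y, folds, function(Xtr, ytr, Xte, yte) {
    sel_permimp(clf, Xtr, ytr, Xte, yte, n_repeats)
  }))
  setNames(sel, colnames(X))
}

#' Build the variables x methods selection vote matrix
#'
#' Runs the full selector roster -- two univariate filters plus six
#' multivariate families (top-k by F value, select-from-model, recursive
#' feature elimination, forward and backward sequential selection,
#' permutation importance), each paired with every classifier in the bank
#' -- across the cross-validation scheme. With the default bank of four
#' classifiers this yields 2 + 6 x 4 = 26 method instances. Each cell is 1
#' when the variable was selected by that method in more than half of the
#' scheme's folds; row sums count votes per variable.
#'
#' @param data A log-scale `pain_cohort`, or a data frame with a `sex`
#'   column and feature columns.
#' @param scheme A [cv_scheme()].
#' @param classifiers Named list of `classifier_spec`s (default the four
#'   classical algorithms).
#' @param alpha Threshold for the univariate filters.
#' @param n_permutations Permutations per variable for the
#'   permutation-importance family.
#' @return A `selection_matrix` with components `votes` (binary matrix),
#'   `row_sums`, `methods` (roster tibble) and `scheme`.
#' @export
build_selection_matrix <- function(data, scheme = cv_scheme(),
                                   classifiers = default_classifier_bank(
                                     seed = scheme$seed, include_nn = FALSE),
                                   alpha = 0.05, n_permutations = 50) {
  xy <- extract_xy(data)
  X <- xy$X; y <- xy$y
  folds <- cv_folds(y, scheme)

  roster <- selection_roster(names(classifiers))
  votes <- matrix(0L, ncol(X), nrow(roster),
                  dimnames = list(colnames(X), roster$label))

  run_method <- function(label, core) {
    res <- tryCatch(
      with_seed(spawn_seed(scheme$seed, 100L + match(label, roster$label)),
                run_over_folds(X, y, folds, core)),
      error = function(e) abort(paste0("selection method '", label, "' failed: ",
                                       conditionMessage(e)))
    )
    as.integer(res)
  }

  votes[, "fpr"] <- run_method("fpr", function(Xtr, ytr, Xte, yte) {
    univariate_fpr_select(Xtr, ytr, alpha)
  })
  votes[, "fwe"] <- run_method("fwe", function(Xtr, ytr, Xte, yte) {
    univariate_fwe_select(Xtr, ytr, alpha)
  })

  for (i in seq_len(nrow(roster))) {
    fam <- roster$family[i]
    if (fam %in% c("fpr", "fwe")) next
    clf <- classifiers[[roster$classifier[i]]]
    core <- switch(fam,
      topk = function(Xtr, ytr, Xte, yte) sel_topk(clf, Xtr, ytr, Xte, yte, seq_len(ncol(X))),
      sfm = function(Xtr, ytr, Xte, yte) sel_sfm(clf, Xtr, ytr),
      rfe = function(Xtr, ytr, Xte, yte) sel_rfe(clf, Xtr, ytr, Xte, yte),
      sfs_forward = function(Xtr, ytr, Xte, yte) sel_sfs(clf, Xtr, ytr, Xte, yte, "forward"),
      sfs_backward = function(Xtr, ytr, Xte, yte) sel_sfs(clf, Xtr, ytr, Xte, yte, "backward"),
      permimp = function(Xtr, ytr, Xte, yte) sel_permimp(clf, Xtr, ytr, Xte, yte, n_permutations)
    )
    votes[, roster$label[i]] <- run_method(roster$label[i], core)
  }

  structure(list(votes = votes, row_sums = rowSums(votes),
                 methods = roster, scheme = scheme),
            class = "selection_matrix")
}

selection_roster <- function(classifier_names) {
  families <- c("topk", "sfm", "rfe", "sfs_forward", "sfs_backward", "permimp")
  multi <- tidyr::expand_grid(family = families, classifier = classifier_names)
  dplyr::bind_rows(
    tibble::tibble(family = c("fpr", "fwe"), classifier = NA_character_,
                   label = c("fpr", "fwe")),
    dplyr::mutate(multi, label = paste(.data$family, .data$classifier, sep = "_"))
  )
}

# Accept a pain_cohort or any data frame with a sex column + features.
extract_xy <- function(data) {
  if (inherits(data, "pain_cohort")) {
    list(X = cohort_matrix(data), y = cohort_sex(data))
  } else {
    data <- as.data.frame(data)
    if (!"sex" %in% names(data)) abort("data must contain a 'sex' column")
    y <- as.integer(data$sex)
    keep <- setdiff(names(data), c("sex", "subject_id"))
    X <- as.matrix(data[keep])
    if (!is.numeric(X)) abort("feature columns must be numeric")
    list(X = X, y = y)
  }
}

#' @export
print.selection_matrix <- function(x, ...) {
  cat(sprintf("<selection_matrix> %d variables x %d methods\n",
              nrow(x$votes), ncol(x$votes)))
  print(sort(x$row_sums, decreasing = TRUE))
  invisible(x)
}

#' @export
tidy.selection_matrix <- function(x, ...) {
  long <- tibble::as_tibble(x$votes, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "method", values_to = "selected")
  dplyr::left_join(long,
                   dplyr::rename(x$methods, method = "label"),
                   by = "method")
}

#' @export
glance.selection_matrix <- function(x, ...) {
  tibble::tibble(n_variables = nrow(x$votes), n_methods = ncol(x$votes),
                 n_folds = x$scheme$n_splits * x$scheme$n_repeats)
}

#' @export
autoplot.selection_matrix <- function(object, ...) {
  sums <- tibble::tibble(variable = names(object$row_sums),
                         votes = as.numeric(object$row_sums)) |>
    dplyr::arrange(dplyr::desc(.data$votes)) |>
    dplyr::mutate(variable = factor(.data$variable, levels = .data$variable))
  ggplot2::ggplot(sums, ggplot2::aes(.data$variable, .data$votes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "selections across methods") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
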