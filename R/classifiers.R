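#' Classifier specifications
#'
#' The five classifier types used throughout the pipeline: linear support
#' vector machine, random forest, ridge-penalised logistic regression,
#' linear discriminant analysis, and a small deep neural network. Defaults
#' reflect the tuned settings of the workflow: ridge (L2) penalties for the
#' linear SVM and logistic regression, and a forest of 500 trees with
#' maximum depth 1 (decision stumps).
#'
#' @param algorithm One of `"linear_svm"`, `"random_forest"`,
#'   `"logistic_regression"`, `"lda"`, `"deep_nn"`.
#' @param params Named list of hyperparameters overriding the defaults:
#'   `cost` (SVM), `num_trees`/`max_depth` (forest), `lambda` (logistic
#'   ridge), `epochs`/`dropout`/`learning_rate` (NN).
#' @param seed Integer seed for stochastic fits (forest, NN).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("linear_svm", "random_forest",
                                          "logistic_regression", "lda", "deep_nn"),
                            params = list(), seed = NULL) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    linear_svm = list(cost = 1),
    random_forest = list(num_trees = 500, max_depth = 1),
    logistic_regression = list(lambda = 0.1),
    lda = list(),
    deep_nn = list(epochs = 1000, dropout = 0.2, learning_rate = 0.01)
  )
  defaults[names(params)] <- params
  structure(list(algorithm = algorithm, params = defaults, seed = seed),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  } else "defaults"
  cat(sprintf("<classifier_spec> %s (%s)\n", x$algorithm, ps))
  invisible(x)
}

#' The default tuned classifier bank
#'
#' @param seed Base seed; each classifier receives a derived sub-seed.
#' @param include_nn Include the deep NN (excluded from feature selection,
#'   which uses the four classical algorithms).
#' @return Named list of `classifier_spec`s.
#' @export
default_classifier_bank <- function(seed = NULL, include_nn = TRUE) {
  algos <- c("linear_svm", "random_forest", "logistic_regression", "lda")
  if (include_nn) algos <- c(algos, "deep_nn")
  specs <- lapply(seq_along(algos), function(i) {
    classifier_spec(algos[i], seed = spawn_seed(seed, i))
  })
  setNames(specs, algos)
}

#' Hidden-layer sizes of the deep neural network
#'
#' Direct evaluation of the architecture rule: with `d` input features the
#' first hidden layer has `int((d + 1) / 0.5)` neurons and the second
#' `int((d + 1) / 1)`, i.e. `2 * (d + 1)` and `d + 1`.
#'
#' @param n_features Number of input features (>= 1).
#' @return Integer vector `c(h1, h2)`.
#' @examples
#' nn_layer_sizes(11) # 24 12
#' @export
nn_layer_sizes <- function(n_features) {
  if (!is.numeric(n_features) || n_features < 1) abort("n_features must be >= 1")
  c(h1 = as.integer((n_features + 1) / 0.5), h2 = as.integer((n_features + 1) / 1))
}

#' Train a classifier
#'
#' Fits the specified classifier to a feature matrix and binary labels
#' (0 = men, 1 = women). Features are standardised to zero mean and unit
#' variance using training statistics for the SVM, logistic regression, LDA
#' and NN (the units g, degC, mA and N/cm2 are not commensurable); the
#' forest is scale-invariant and trains on raw features.
#'
#' @param spec A `classifier_spec`.
#' @param X Numeric matrix or data frame, subjects x features.
#' @param y Binary integer labels with both classes present.
#' @return A fitted `painsex_model` exposing [predict()] and
#'   [feature_importance()].
#' @export
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  y <- as.integer(y)
  assert_binary_labels(y)
  if (nrow(X) != length(y)) abort("X and y sizes differ")

  standardize <- spec$algorithm != "random_forest"
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    Xs <- scale(X, center = ctr, scale = scl)
  } else {
    ctr <- scl <- NULL
    Xs <- X
  }

  fit <- switch(spec$algorithm,
    linear_svm = fit_svm(Xs, y, spec),
    random_forest = fit_rf(Xs, y, spec),
    logistic_regression = fit_ridge_logistic(Xs, y, spec),
    lda = fit_lda(Xs, y, spec),
    deep_nn = fit_nn(Xs, y, spec)
  )
  structure(list(spec = spec, fit = fit, center = ctr, scale = scl,
                 features = colnames(X)),
            class = "painsex_model")
}

fit_svm <- function(X, y, spec) {
  m <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                  cost = spec$params$cost, scale = FALSE)
  # weight vector of the separating hyperplane
  w <- drop(crossprod(m$coefs, m$SV))
  # decision values are oriented toward the first training level
  list(model = m, w = setNames(as.numeric(w), colnames(X)))
}

fit_rf <- function(X, y, spec) {
  ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                 num.trees = spec$params$num_trees,
                 max.depth = spec$params$max_depth,
                 probability = TRUE, importance = "impurity",
                 seed = spec$seed %f% 1L, num.threads = 1)
}

fit_ridge_logistic <- function(X, y, spec) {
  # glmnet requires at least two columns; pad single-feature designs with a
  # constant zero column whose coefficient is identically zero
  padded <- ncol(X) < 2
  if (padded) X <- cbind(X, `..pad` = 0)
  m <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                      lambda = spec$params$lambda, standardize = FALSE)
  list(model = m, padded = padded)
}

fit_lda <- function(X, y, spec) {
  suppressWarnings(MASS::lda(X, grouping = factor(y, levels = c(0, 1))))
}

#' Predict from a fitted classifier
#'
#' @param object A `painsex_model`.
#' @param newdata Feature matrix with the training feature set.
#' @param ... Unused.
#' @return Tibble with `label` (0/1) and `score` (continuous, monotone in
#'   the propensity of class 1, women).
#' @export
predict.painsex_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (nrow(X) == 0) return(tibble::tibble(label = integer(), score = numeric()))
  if (!is.null(object$features)) {
    if (!all(object$features %in% colnames(X))) abort("feature mismatch with training data")
    X <- X[, object$features, drop = FALSE]
  }
  if (ncol(X) != length(object$features)) abort("feature count mismatch")
  if (!is.null(object$center)) X <- scale(X, center = object$center, scale = object$scale)

  score <- switch(object$spec$algorithm,
    linear_svm = {
      dv <- attr(predict(object$fit$model, X, decision.values = TRUE),
                 "decision.values")
      # orient toward class 1: column name "a/b" means positive favours a
      if (startsWith(colnames(dv)[1], "1")) drop(dv) else -drop(dv)
    },
    random_forest = {
      pr <- predict(object$fit, data = X, num.threads = 1)$predictions
      pr[, "1"]
    },
    logistic_regression = {
      Xp <- if (object$fit$padded) cbind(X, `..pad` = 0) else X
      drop(predict(object$fit$model, Xp, type = "response"))
    },
    lda = predict(object$fit, X)$posterior[, "1"],
    deep_nn = predict_nn(object$fit, X)
  )
  label <- if (object$spec$algorithm == "linear_svm") {
    as.integer(score > 0)
  } else {
    as.integer(score > 0.5)
  }
  tibble::tibble(label = label, score = as.numeric(score))
}

#' Importance weights of a fitted classifier
#'
#' Absolute coefficients for the linear models (SVM hyperplane weights,
#' logistic ridge coefficients, LDA discriminant loadings) and impurity
#' importances for the forest. The NN exposes no importances.
#'
#' @param model A `painsex_model`.
#' @return Named nonnegative numeric vector, one entry per feature.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "painsex_model"))
  imp <- switch(model$spec$algorithm,
    linear_svm = abs(model$fit$w),
    random_forest = ranger::importance(model$fit),
    logistic_regression = {
      b <- as.numeric(stats::coef(model$fit$model))[-1]
      names(b) <- rownames(stats::coef(model$fit$model))[-1]
      abs(b[names(b) != "..pad"])
    },
    lda = abs(setNames(model$fit$scaling[, 1], rownames(model$fit$scaling))),
    abort("classifier does not expose importance weights")
  )
  imp[model$features]
}

#' @export
glance.painsex_model <- function(x, ...) {
  tibble::tibble(algorithm = x$spec$algorithm,
                 n_features = length(x$features),
                 seed = x$spec$seed %f% NA_integer_)
}

# ---- deep neural network (2 linear hidden layers, dropout, sigmoid output) ----

fit_nn <- function(X, y, spec) {
  d <- ncol(X)
  h <- nn_layer_sizes(d)
  epochs <- spec$params$epochs
  drop_rate <- spec$params$dropout
  lr <- spec$params$learning_rate
  n <- nrow(X)

  with_seed(spec$seed %f% 1L, {
    init <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(1 / nin)), nin, nout)
    par <- list(W1 = init(d, h[1]), b1 = rep(0, h[1]),
                W2 = init(h[1], h[2]), b2 = rep(0, h[2]),
                W3 = init(h[2], 1), b3 = 0)
    mom <- lapply(par, function(p) p * 0)
    vel <- lapply(par, function(p) p * 0)
    b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
    keep <- 1 - drop_rate

    for (t in seq_len(epochs)) {
      M1 <- matrix(stats::rbinom(n * h[1], 1, keep) / keep, n, h[1])
      M2 <- matrix(stats::rbinom(n * h[2], 1, keep) / keep, n, h[2])
      A1 <- (X %*% par$W1 + rep(par$b1, each = n)) * M1
      A2 <- (A1 %*% par$W2 + rep(par$b2, each = n)) * M2
      z <- drop(A2 %*% par$W3) + par$b3
      p <- 1 / (1 + exp(-z))
      dz <- matrix((p - y) / n, n, 1)
      grad <- list(
        W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL,
        W3 = crossprod(A2, dz), b3 = sum(dz)
      )
      dA2 <- (dz %*% t(par$W3)) * M2
      grad$W2 <- crossprod(A1, dA2)
      grad$b2 <- colSums(dA2)
      dA1 <- (dA2 %*% t(par$W2)) * M1
      grad$W1 <- crossprod(X, dA1)
      grad$b1 <- colSums(dA1)

      for (nm in names(par)) {
        mom[[nm]] <- b1a * mom[[nm]] + (1 - b1a) * grad[[nm]]
        vel[[nm]] <- b2a * vel[[nm]] + (1 - b2a) * grad[[nm]]^2
        mhat <- mom[[nm]] / (1 - b1a^t)
        vhat <- vel[[nm]] / (1 - b2a^t)
        par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    list(par = par, h = h)
  })
}

predict_nn <- function(fit, X) {
  par <- fit$par
  n <- nrow(X)
  A1 <- X %*% par$W1 + rep(par$b1, each = n)
  A2 <- A1 %*% par$W2 + rep(par$b2, each = n)
  z <- drop(A2 %*% par$W3) + par$b3
  1 / (1 + exp(-z))
}

#' Grid-search hyperparameter tuning
#'
#' Scores each grid point by mean cross-validated balanced accuracy under
#' the scheme and returns the spec rebuilt with the best point (ties go to
#' the earliest grid point).
#'
#' @param spec A `classifier_spec`.
#' @param X,y Training features and binary labels.
#' @param grid Data frame or list of named parameter combinations; default
#'   [default_grid()] for the spec's algorithm.
#' @param scheme A [cv_scheme()] (smaller schemes are fine for tuning).
#' @return The tuned `classifier_spec` with attributes `cv_score` and
#'   `cv_scores` (per grid point).
#' @export
tune_classifier <- function(spec, X, y, grid = default_grid(spec$algorithm),
                            scheme = cv_scheme(5, 2, seed = spec$seed)) {
  if (is.data.frame(grid)) grid <- purrr::transpose(as.list(grid))
  if (length(grid) == 0) abort("empty tuning grid")
  X <- as.matrix(X)
  y <- as.integer(y)
  folds <- cv_folds(y, scheme)
  scores <- vapply(grid, function(pt) {
    cand <- classifier_spec(spec$algorithm, params = pt, seed = spec$seed)
    mean(vapply(folds, function(f) {
      m <- fit_classifier(cand, X[f$train, , drop = FALSE], y[f$train])
      pr <- predict(m, X[f$test, , drop = FALSE])
      balanced_accuracy(y[f$test], pr$label)
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(scores)
  out <- classifier_spec(spec$algorithm, params = grid[[best]], seed = spec$seed)
  attr(out, "cv_score") <- scores[best]
  attr(out, "cv_scores") <- scores
  out
}

#' @rdname tune_classifier
#' @param algorithm Classifier algorithm name.
#' @export
default_grid <- function(algorithm) {
  switch(algorithm,
    linear_svm = data.frame(cost = 10^seq(-2, 2)),
    logistic_regression = data.frame(lambda = 10^seq(-3, 1)),
    random_forest = expand.grid(num_trees = c(100, 500), max_depth = c(1, 3)),
    lda = list(list()),
    deep_nn = data.frame(epochs = 1000),
    abort(paste0("unknown algorithm: ", algorithm))
  )
}
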