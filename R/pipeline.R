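#' Pipeline configuration
#'
#' Bundles every stage's settings: the synthetic generator (or an input CSV
#' path), the 80/20 distribution-optimal split, the 5 x 20 cross-validation
#' scheme used by feature selection, the evaluation run counts and
#' subsample fractions, and a single global seed from which every stage
#' derives its own substream.
#'
#' @param generator A [cohort_config()]; ignored when `input_csv` is given.
#' @param input_csv Optional path to a cohort CSV to analyse instead of a
#'   simulated one.
#' @param split_fraction Validation fraction (default 0.2).
#' @param n_candidates Candidate splits searched (1e6 is the full-fidelity
#'   setting; 1e3--1e4 is nearly indistinguishable and much faster).
#' @param scheme [cv_scheme()] for feature selection.
#' @param impute_policy Censoring imputation policy.
#' @param n_runs Evaluation runs per classifier x feature-set cell.
#' @param train_frac,val_frac Evaluation subsample fractions.
#' @param seed Global seed (mandatory for reproducible runs).
#' @param out_dir Output directory for artifacts, or `NULL` to skip writing.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(generator = cohort_config(),
                            input_csv = NULL,
                            split_fraction = 0.2,
                            n_candidates = 1e6,
                            scheme = NULL,
                            impute_policy = "at_bound",
                            n_runs = 100,
                            train_frac = 0.67,
                            val_frac = 0.80,
                            seed = 42,
                            out_dir = NULL) {
  if (is.null(seed)) abort("a global seed is mandatory")
  stopifnot(split_fraction > 0, split_fraction < 1,
            train_frac > 0, train_frac < 1, val_frac > 0, val_frac < 1)
  structure(list(generator = generator, input_csv = input_csv,
                 split_fraction = split_fraction,
                 n_candidates = n_candidates,
                 scheme = scheme,
                 impute_policy = impute_policy,
                 n_runs = n_runs, train_frac = train_frac,
                 val_frac = val_frac, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, preprocessing (imputation and log10 transform),
#' the distribution-optimal 80/20 split, the 26-method selection matrix on
#' the training partition, cABC and recursive cABC of the vote sums, and
#' the validation experiment for the five feature-set conditions (full,
#' reduced = cABC category A, sparse = recursive cABC A, sparse with
#' permuted training data, and the unselected complement of the reduced
#' set) with all five classifiers. When `config$out_dir` is set, every
#' artifact is written as CSV/JSON together with a run manifest carrying
#' the seed and a configuration hash.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages?
#' @return A `pipeline_result` list: `cohort` (log scale), `split`,
#'   `selection`, `abc`, `recursive_abc`, `feature_sets`, `report`, and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  scheme <- config$scheme %||% cv_scheme(5, 20, seed = spawn_seed(seed, 3))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  raw <- stage("data", {
    if (!is.null(config$input_csv)) {
      load_cohort(config$input_csv, meta = config$generator$meta)
    } else {
      simulate_cohort(config$generator, seed = spawn_seed(seed, 1))
    }
  })
  say("data: %d subjects x %d variables (seed %d)", nrow(raw),
      nrow(cohort_meta(raw)), seed)

  cohort <- stage("preprocess", {
    raw |>
      impute_censored(policy = config$impute_policy,
                      seed = spawn_seed(seed, 2)) |>
      log10_transform()
  })
  say("preprocess: policy '%s', log10 scale", config$impute_policy)

  split <- stage("split", {
    optimal_split(cohort, fraction = config$split_fraction,
                  n_candidates = config$n_candidates,
                  seed = spawn_seed(seed, 4))
  })
  say("split: %d train / %d validation, score %.4f",
      length(split$train_ids), length(split$validation_ids),
      split$similarity_score)

  train_cohort <- cohort_slice(cohort, match(split$train_ids, cohort$subject_id))
  selection <- stage("select", build_selection_matrix(train_cohort, scheme = scheme))
  say("select: %d x %d vote matrix", nrow(selection$votes), ncol(selection$votes))

  abc <- stage("cabc", abc_categorize(selection$row_sums))
  rec <- stage("cabc", recursive_abc(selection$row_sums))
  reduced <- abc_set_a(abc)
  sparse <- rec$sparse_set
  say("cabc: reduced = {%s}; sparse = {%s}",
      paste(reduced, collapse = ", "), paste(sparse, collapse = ", "))

  all_vars <- cohort_meta(cohort)$name
  feature_sets <- list(
    full = all_vars,
    reduced = reduced,
    sparse = sparse,
    sparse_permuted = list(features = sparse, permuted = TRUE),
    unselected = setdiff(all_vars, reduced)
  )

  report <- stage("evaluate", {
    evaluate_all(cohort, split, feature_sets,
                 classifiers = default_classifier_bank(spawn_seed(seed, 5)),
                 n_runs = config$n_runs, seed = spawn_seed(seed, 6))
  })
  say("evaluate: %d cells x %d runs", length(report$cells), config$n_runs)

  manifest <- list(seed = seed,
                   config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
                   n_subjects = nrow(cohort),
                   n_variables = length(all_vars),
                   feature_sets = lapply(feature_sets, function(f) {
                     if (is.list(f)) f$features else f
                   }),
                   timestamp = format(Sys.time(), tz = "UTC"))

  result <- structure(list(cohort = cohort, raw_cohort = raw, split = split,
                           selection = selection, abc = abc,
                           recursive_abc = rec, feature_sets = feature_sets,
                           report = report, manifest = manifest),
                      class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    stage("report", write_pipeline_artifacts(result, config$out_dir))
    say("report: artifacts in %s", config$out_dir)
  }
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_cohort(result$raw_cohort, p("cohort.csv"))
  jsonlite::write_json(list(train_ids = result$split$train_ids,
                            validation_ids = result$split$validation_ids,
                            similarity_score = result$split$similarity_score),
                       p("split.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(cbind(variable = rownames(result$selection$votes),
                         as.data.frame(result$selection$votes),
                         row_sum = result$selection$row_sums),
                   p("selection_matrix.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(categories = split(result$abc$items$item, result$abc$items$category),
         ab_limit = result$abc$ab_limit, bc_limit = result$abc$bc_limit,
         sparse_set = result$recursive_abc$sparse_set),
    p("cabc.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(performance_table(result$report), p("report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(glance(result$report), p("report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  reduced set:", paste(abc_set_a(x$abc), collapse = ", "), "\n")
  cat("  sparse set: ", paste(x$recursive_abc$sparse_set, collapse = ", "), "\n")
  print(performance_table(x$report), n = Inf)
  invisible(x)
}
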