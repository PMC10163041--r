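#' Pain-threshold cohort objects
#'
#' A `pain_cohort` is a tibble with one row per subject, columns
#' `subject_id`, `sex` (integer, 0 = men, 1 = women) and one numeric column
#' per threshold variable, plus attributes carrying the variable metadata
#' (see [qst_variables()]), a subjects-by-variables logical matrix of
#' censoring flags, and a scale flag (`"raw"` or `"log10"`).
#'
#' @param data Data frame with `subject_id`, `sex` and the variable columns
#'   named in `meta`. `sex` may be coded `"m"`/`"f"` or 0/1.
#' @param meta Variable metadata tibble; defaults to [qst_variables()].
#' @param censored Optional logical matrix of censoring flags (subjects x
#'   variables). If omitted, flags are set where a raw value sits exactly on
#'   its variable's censor bound.
#' @param scale `"raw"` or `"log10"`.
#' @return A `pain_cohort` tibble.
#' @export
pain_cohort <- function(data, meta = qst_variables(), censored = NULL,
                        scale = c("raw", "log10")) {
  scale <- match.arg(scale)
  meta <- validate_variable_meta(meta)
  data <- tibble::as_tibble(data)
  if (!"subject_id" %in% names(data)) abort("missing column: subject_id")
  if (!"sex" %in% names(data)) abort("missing column: sex")
  missing_vars <- setdiff(meta$name, names(data))
  if (length(missing_vars)) {
    abort(paste0("missing variable columns: ", paste(missing_vars, collapse = ", ")))
  }
  if (nrow(data) == 0) abort("no subjects")
  if (anyDuplicated(data$subject_id)) abort("duplicate subject id")

  sex <- data$sex
  if (is.character(sex) || is.factor(sex)) {
    sex <- as.character(sex)
    unknown <- setdiff(unique(sex), c("m", "f"))
    if (length(unknown)) abort(paste0("unknown sex label: ", paste(unknown, collapse = ", ")))
    sex <- ifelse(sex == "f", 1L, 0L)
  } else {
    sex <- as.integer(sex)
    if (!all(sex %in% c(0L, 1L))) abort("sex must be coded m/f or 0/1")
  }
  if (length(unique(sex)) < 2) abort("single-class dataset: both sexes required")

  vals <- as.matrix(data[meta$name])
  if (!is.numeric(vals)) abort("non-numeric threshold values")
  if (anyNA(vals)) abort("missing threshold values are not supported")
  rownames(vals) <- data$subject_id

  if (is.null(censored)) {
    censored <- infer_censoring_flags(vals, meta)
  } else {
    censored <- as.matrix(censored)
    stopifnot(identical(dim(censored), dim(vals)))
    dimnames(censored) <- dimnames(vals)
  }

  out <- tibble::tibble(subject_id = as.character(data$subject_id), sex = sex)
  out <- dplyr::bind_cols(out, tibble::as_tibble(vals))
  structure(out,
            meta = meta, censored = censored, scale = scale,
            class = c("pain_cohort", class(out)))
}

infer_censoring_flags <- function(vals, meta) {
  flags <- matrix(FALSE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  for (j in seq_len(nrow(meta))) {
    lo <- meta$censor_low[j]; hi <- meta$censor_high[j]
    v <- vals[, meta$name[j]]
    if (!is.na(lo)) flags[v <= lo, meta$name[j]] <- TRUE
    if (!is.na(hi)) flags[v >= hi, meta$name[j]] <- TRUE
  }
  # derived effect variables inherit censoring from either source threshold
  for (j in which(meta$sensitization == "effect")) {
    src <- c(meta$effect_baseline[j], meta$effect_sensitized[j])
    if (all(src %in% colnames(flags))) {
      flags[, meta$name[j]] <- flags[, src[1]] | flags[, src[2]]
    }
  }
  flags
}

validate_pain_cohort <- function(ds) {
  meta <- cohort_meta(ds)
  vals <- cohort_matrix(ds)
  cen <- cohort_censored(ds)
  stopifnot(identical(dim(cen), dim(vals)))
  assert_binary_labels(ds$sex)
  if (cohort_scale(ds) == "raw") {
    for (j in seq_len(nrow(meta))) {
      if (meta$magnitude[j] == "log_ratio") next
      v <- vals[, meta$name[j]]
      lo <- meta$censor_low[j]; hi <- meta$censor_high[j]
      if (!is.na(lo) && any(v < lo - 1e-9)) abort(paste0(meta$name[j], ": value below censor bound"))
      if (!is.na(hi) && any(v > hi + 1e-9)) abort(paste0(meta$name[j], ": value above censor bound"))
    }
  } else if (!all(is.finite(vals))) {
    abort("log-scale values must be finite")
  }
  invisible(ds)
}

#' Cohort accessors
#'
#' @param ds A `pain_cohort`.
#' @return `cohort_matrix()`: the subjects x variables numeric matrix;
#'   `cohort_sex()`: the integer label vector; `cohort_meta()`: the metadata
#'   tibble; `cohort_censored()`: the logical censoring matrix;
#'   `cohort_scale()`: `"raw"` or `"log10"`.
#' @export
cohort_matrix <- function(ds) {
  meta <- cohort_meta(ds)
  m <- as.matrix(as.data.frame(ds)[meta$name])
  rownames(m) <- ds$subject_id
  m
}

#' @rdname cohort_matrix
#' @export
cohort_sex <- function(ds) ds$sex

#' @rdname cohort_matrix
#' @export
cohort_meta <- function(ds) attr(ds, "meta")

#' @rdname cohort_matrix
#' @export
cohort_censored <- function(ds) attr(ds, "censored")

#' @rdname cohort_matrix
#' @export
cohort_scale <- function(ds) attr(ds, "scale")

# Rebuild a cohort with replaced values, keeping ids/labels/meta.
replace_values <- function(ds, vals, censored = cohort_censored(ds),
                           scale = cohort_scale(ds)) {
  out <- ds
  for (nm in colnames(vals)) out[[nm]] <- vals[, nm]
  attr(out, "censored") <- censored
  attr(out, "scale") <- scale
  out
}

# Subset a cohort by row indices, keeping attributes aligned.
cohort_slice <- function(ds, idx) {
  out <- tibble::as_tibble(as.data.frame(ds))[idx, , drop = FALSE]
  structure(out,
            meta = cohort_meta(ds),
            censored = cohort_censored(ds)[idx, , drop = FALSE],
            scale = cohort_scale(ds),
            class = c("pain_cohort", class(tibble::tibble())))
}

#' @export
print.pain_cohort <- function(x, ...) {
  cat(sprintf("<pain_cohort> %d subjects (%d men, %d women) x %d variables [%s scale]\n",
              nrow(x), sum(x$sex == 0), sum(x$sex == 1),
              nrow(cohort_meta(x)), cohort_scale(x)))
  NextMethod()
}

#' Read and write cohort CSV files
#'
#' The CSV dialect is UTF-8, comma-separated, `"."` decimal, with a mandatory
#' header of `subject_id`, `sex` (coded `"m"`/`"f"`) and one column per
#' variable in `meta`. Censoring flags are re-derived on load from the
#' metadata's censor bounds, so write/load round-trips are exact.
#'
#' @param path CSV file path.
#' @param meta Variable metadata (default [qst_variables()]).
#' @param ds A `pain_cohort` on raw scale.
#' @return `load_cohort()` returns a raw-scale `pain_cohort`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
load_cohort <- function(path, meta = qst_variables()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = NA,
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0) abort("no subjects")
  ds <- pain_cohort(raw, meta = meta, scale = "raw")
  validate_pain_cohort(ds)
}

#' @rdname load_cohort
#' @export
write_cohort <- function(ds, path) {
  stopifnot(inherits(ds, "pain_cohort"))
  out <- as.data.frame(ds)
  out$sex <- ifelse(out$sex == 1L, "f", "m")
  # format() with 17 significant digits guarantees bit-exact double round-trip
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sub("^\\s+", "", format(v, digits = 17)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
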