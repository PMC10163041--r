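#' Impute censored threshold values
#'
#' Device censoring truncates thresholds at hardware limits (thermode 0--50
#' degC, stimulator 20 mA, von Frey ladder 300 g). Two policies are offered:
#' `"at_bound"` (default) deterministically substitutes the censor bound
#' itself; `"tail_draw"` draws a seeded replacement from the tail of a
#' log-normal fitted to the variable's uncensored stimulus magnitudes,
#' conditional on lying strictly beyond the bound (an estimate of the latent
#' uncensored threshold, which may exceed the physical device range).
#'
#' @param ds Raw-scale `pain_cohort`.
#' @param policy `"at_bound"` or `"tail_draw"`.
#' @param seed Integer seed used by `"tail_draw"`.
#' @return A raw-scale `pain_cohort` with censored cells replaced and
#'   censoring flags preserved.
#' @export
impute_censored <- function(ds, policy = c("at_bound", "tail_draw"), seed = NULL) {
  stopifnot(inherits(ds, "pain_cohort"))
  if (cohort_scale(ds) != "raw") abort("impute_censored() expects a raw-scale cohort")
  if (is.character(policy) && length(policy) == 1 &&
      !policy %in% c("at_bound", "tail_draw")) {
    abort(paste0("unknown imputation policy: ", policy))
  }
  policy <- match.arg(policy)
  meta <- cohort_meta(ds)
  vals <- cohort_matrix(ds)
  cen <- cohort_censored(ds)
  if (!any(cen)) return(ds)

  with_seed(seed, {
    for (j in seq_len(nrow(meta))) {
      nm <- meta$name[j]
      if (meta$magnitude[j] == "log_ratio") next
      flag <- cen[, nm]
      if (!any(flag)) next
      lo <- meta$censor_low[j]; hi <- meta$censor_high[j]
      v <- vals[, nm]
      at_low <- flag & !is.na(lo) & v <= lo + 1e-12
      at_high <- flag & !is.na(hi) & v >= hi - 1e-12
      if (policy == "at_bound") {
        v[at_low] <- lo
        v[at_high] <- hi
      } else {
        # Fit on log10 magnitudes of uncensored cells, draw from the
        # truncated tail beyond the bound on the magnitude scale.
        mag <- to_magnitude(v, meta$magnitude[j])
        ok <- !flag & mag > 0
        if (sum(ok) < 3) abort(paste0(nm, ": too few uncensored values to fit a tail"))
        m <- mean(log10(mag[ok])); s <- sd(log10(mag[ok]))
        if (!is.finite(s) || s <= 0) abort(paste0(nm, ": degenerate spread, cannot draw tail"))
        draw_tail <- function(bound_mag, upper) {
          pz <- stats::pnorm((log10(bound_mag) - m) / s)
          u <- if (upper) runif(1, pz, 1) else runif(1, 0, pz)
          10^(m + s * stats::qnorm(u))
        }
        # cold stimuli: magnitude grows as temperature falls, so the low
        # temperature bound is the *upper* magnitude tail
        inverted <- meta$magnitude[j] == "below_32C"
        for (i in which(at_low)) {
          mag[i] <- draw_tail(to_magnitude(lo, meta$magnitude[j]), upper = inverted)
        }
        for (i in which(at_high)) {
          mag[i] <- draw_tail(to_magnitude(hi, meta$magnitude[j]), upper = !inverted)
        }
        v <- from_magnitude(mag, meta$magnitude[j])
      }
      vals[, nm] <- v
    }
  })
  replace_values(ds, vals)
}

# Map a recorded value to positive stimulus magnitude and back. Cold stimuli
# start at the 32 degC thermode baseline and grow by cooling, so their
# strength is 32 - T.
to_magnitude <- function(v, rule) {
  switch(rule, identity = v, below_32C = 32 - v, log_ratio = v)
}
from_magnitude <- function(mag, rule) {
  switch(rule, identity = mag, below_32C = 32 - mag, log_ratio = mag)
}

#' Log10-transform a cohort
#'
#' Replaces each measured threshold by the log10 of its positive stimulus
#' magnitude (for cold stimuli the magnitude is the temperature drop below
#' the 32 degC baseline). Derived sensitization-effect variables are already
#' log-scale differences and pass through unchanged. The inverse transform
#' restores raw values.
#'
#' @param ds Raw-scale (`log10_transform`) or log-scale
#'   (`inverse_log10_transform`) `pain_cohort`, imputation already applied.
#' @return A `pain_cohort` on the other scale.
#' @export
log10_transform <- function(ds) {
  stopifnot(inherits(ds, "pain_cohort"))
  if (cohort_scale(ds) != "raw") abort("cohort is already log10-transformed")
  meta <- cohort_meta(ds)
  vals <- cohort_matrix(ds)
  for (j in seq_len(nrow(meta))) {
    rule <- meta$magnitude[j]
    if (rule == "log_ratio") next
    mag <- to_magnitude(vals[, meta$name[j]], rule)
    if (any(mag <= 0)) abort(paste0(meta$name[j], ": non-positive stimulus magnitude"))
    vals[, meta$name[j]] <- log10(mag)
  }
  replace_values(ds, vals, scale = "log10")
}

#' @rdname log10_transform
#' @export
inverse_log10_transform <- function(ds) {
  stopifnot(inherits(ds, "pain_cohort"))
  if (cohort_scale(ds) != "log10") abort("cohort is not on the log10 scale")
  meta <- cohort_meta(ds)
  vals <- cohort_matrix(ds)
  for (j in seq_len(nrow(meta))) {
    rule <- meta$magnitude[j]
    if (rule == "log_ratio") next
    vals[, meta$name[j]] <- from_magnitude(10^vals[, meta$name[j]], rule)
  }
  replace_values(ds, vals, scale = "raw")
}

#' Standardised sex difference per variable (Cohen's d)
#'
#' Cohen's d computed as (mean of women - mean of men) / pooled standard
#' deviation, on the cohort's current scale. A negative d on a variable
#' tagged `higher_is_less_sensitive` means women have lower (more sensitive)
#' thresholds.
#'
#' @param ds A `pain_cohort`.
#' @param variables Variable names; default all.
#' @return Tibble with columns `variable`, `d`, `direction`.
#' @export
cohens_d <- function(ds, variables = NULL) {
  stopifnot(inherits(ds, "pain_cohort"))
  meta <- cohort_meta(ds)
  variables <- variables %||% meta$name
  vals <- cohort_matrix(ds)
  sex <- cohort_sex(ds)
  assert_binary_labels(sex)
  purrr::map_dfr(variables, function(nm) {
    if (!nm %in% colnames(vals)) abort(paste0("unknown variable: ", nm))
    x0 <- vals[sex == 0L, nm]; x1 <- vals[sex == 1L, nm]
    n0 <- length(x0); n1 <- length(x1)
    sp2 <- ((n0 - 1) * var(x0) + (n1 - 1) * var(x1)) / (n0 + n1 - 2)
    if (!is.finite(sp2) || sp2 <= 0) abort(paste0(nm, ": zero pooled variance"))
    tibble::tibble(variable = nm,
                   d = (mean(x1) - mean(x0)) / sqrt(sp2),
                   direction = meta$direction[match(nm, meta$name)])
  })
}

#' Per-variable two-sample sex comparison
#'
#' Two-sided Welch two-sample t-test of women versus men on the cohort's
#' (log-scale) values, one p-value per variable.
#'
#' @param ds A log-scale `pain_cohort`.
#' @param variables Variable names; default all.
#' @return Tibble with `variable`, `statistic`, `p_value`.
#' @export
group_compare <- function(ds, variables = NULL) {
  stopifnot(inherits(ds, "pain_cohort"))
  meta <- cohort_meta(ds)
  variables <- variables %||% meta$name
  vals <- cohort_matrix(ds)
  sex <- cohort_sex(ds)
  assert_binary_labels(sex)
  purrr::map_dfr(variables, function(nm) {
    tt <- t.test(vals[sex == 1L, nm], vals[sex == 0L, nm])
    tibble::tibble(variable = nm,
                   statistic = unname(tt$statistic),
                   p_value = tt$p.value)
  })
}

#' Inter-variable correlation matrix with p-values
#'
#' Pearson correlations between all variable pairs on the cohort's log-scale
#' values, with the two-sided p-value of each off-diagonal pair.
#'
#' @param ds A log-scale `pain_cohort`.
#' @return A `qst_correlation` object with components `r` (symmetric
#'   unit-diagonal matrix) and `p` (p-value matrix, `NA` diagonal). Use
#'   [tidy()] for a long tibble or [autoplot()] for a heat map.
#' @export
correlation_matrix <- function(ds) {
  stopifnot(inherits(ds, "pain_cohort"))
  vals <- cohort_matrix(ds)
  sds <- apply(vals, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant variable: ",
                 paste(colnames(vals)[sds == 0], collapse = ", ")))
  }
  r <- cor(vals)
  p <- matrix(NA_real_, ncol(vals), ncol(vals), dimnames = dimnames(r))
  for (i in seq_len(ncol(vals) - 1)) {
    for (j in (i + 1):ncol(vals)) {
      ct <- cor.test(vals[, i], vals[, j])
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p), class = "qst_correlation")
}

#' @export
print.qst_correlation <- function(x, ...) {
  cat("<qst_correlation>", ncol(x$r), "variables\n")
  print(round(x$r, 2))
  invisible(x)
}

#' @export
tidy.qst_correlation <- function(x, ...) {
  nm <- colnames(x$r)
  grid <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(variable1 = nm[grid[, 1]], variable2 = nm[grid[, 2]],
                 estimate = x$r[grid], p_value = x$p[grid])
}

#' @export
autoplot.qst_correlation <- function(object, ...) {
  nm <- colnames(object$r)
  long <- tidyr::expand_grid(variable1 = nm, variable2 = nm) |>
    dplyr::mutate(estimate = as.vector(t(object$r)))
  ggplot2::ggplot(long, ggplot2::aes(.data$variable2, .data$variable1,
                                     fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Violin/box overview of thresholds by sex
#'
#' @param object A `pain_cohort`.
#' @param ... Unused.
#' @return A ggplot: per-variable distributions split by sex.
#' @export
autoplot.pain_cohort <- function(object, ...) {
  meta <- cohort_meta(object)
  long <- tibble::as_tibble(as.data.frame(object)) |>
    dplyr::mutate(sex = factor(ifelse(.data$sex == 1, "women", "men"))) |>
    tidyr::pivot_longer(dplyr::all_of(meta$name),
                        names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$sex, .data$value, fill = .data$sex)) +
    ggplot2::geom_violin(alpha = 0.4, colour = NA) +
    ggplot2::geom_boxplot(width = 0.25, outlier.size = 0.5) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = paste0("threshold (", cohort_scale(object), " scale)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
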