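#' Synthetic-cohort generator configuration
#'
#' Defines the study conditions the generator emulates: 69 men and 56 women;
#' eleven threshold variables (eight measured, three derived sensitization
#' effects); log-normal thresholds with configurable log10-scale means and
#' SDs; an inter-variable correlation of 0.3 within and 0.1 across stimulus
#' modalities; device censoring at the hardware bounds; punctate thresholds
#' quantised to the von Frey force ladder; and signed target Cohen's d
#' (women minus men, in pooled-SD units on the log scale) on blunt pressure,
#' punctate pressure with and without capsaicin, and electrical current,
#' with no sex effect on thermal or sensitization-effect variables.
#'
#' @param n_male,n_female Group sizes (default 69 and 56).
#' @param meta Variable metadata, see [qst_variables()].
#' @param log_mean,log_sd Named log10-scale means/SDs of the measured
#'   (non-effect) variables' stimulus magnitudes.
#' @param effect_d Named signed target Cohen's d per measured variable.
#' @param rho_within,rho_between Correlation between measured variables of
#'   the same / of different modality. Ignored when `correlation` is given.
#' @param correlation Optional full correlation matrix over the measured
#'   variables (symmetric, unit diagonal, positive semi-definite).
#' @param quantize_punctate Snap punctate (gram-unit) thresholds to the von
#'   Frey ladder?
#' @param ladder von Frey force ladder, strictly increasing.
#' @param seed Default seed used by [simulate_cohort()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_male = 69, n_female = 56,
                          meta = qst_variables(),
                          log_mean = NULL, log_sd = NULL, effect_d = NULL,
                          rho_within = 0.3, rho_between = 0.1,
                          correlation = NULL,
                          quantize_punctate = TRUE,
                          ladder = von_frey_ladder(),
                          seed = NULL) {
  meta <- validate_variable_meta(meta)
  measured <- meta$name[meta$sensitization != "effect"]

  defaults_mean <- c(pressure_blunt = 1.55, pressure_punctate = 1.5,
                     heat_pain = 1.662, cold_pain = 1.30,
                     electrical_current = 0.35,
                     pressure_punctate_capsaicin = 1.2,
                     heat_pain_capsaicin = 1.635, cold_pain_menthol = 1.15)
  defaults_sd <- c(pressure_blunt = 0.18, pressure_punctate = 0.5,
                   heat_pain = 0.02, cold_pain = 0.25,
                   electrical_current = 0.3,
                   pressure_punctate_capsaicin = 0.5,
                   heat_pain_capsaicin = 0.022, cold_pain_menthol = 0.28)
  defaults_d <- setNames(numeric(length(measured)), measured)
  defaults_d[c("pressure_blunt", "pressure_punctate",
               "pressure_punctate_capsaicin", "electrical_current")] <-
    c(-1.2, -1.0, -1.0, -0.8)

  log_mean <- fill_named(log_mean, defaults_mean, measured, "log_mean")
  log_sd <- fill_named(log_sd, defaults_sd, measured, "log_sd")
  effect_d <- fill_named(effect_d, defaults_d, measured, "effect_d")
  if (any(!is.finite(effect_d))) abort("effect_d must be finite")
  if (any(log_sd <= 0)) abort("log_sd must be positive")
  if (n_male < 2 || n_female < 2) abort("group sizes must be at least 2")

  if (is.null(correlation)) {
    modality <- meta$modality[match(measured, meta$name)]
    correlation <- ifelse(outer(modality, modality, "=="), rho_within, rho_between)
    diag(correlation) <- 1
    dimnames(correlation) <- list(measured, measured)
  } else {
    correlation <- as.matrix(correlation)
    if (!isTRUE(all.equal(correlation, t(correlation))) ||
        !isTRUE(all.equal(unname(diag(correlation)), rep(1, nrow(correlation))))) {
      abort("correlation must be symmetric with unit diagonal")
    }
    if (is.null(dimnames(correlation))) dimnames(correlation) <- list(measured, measured)
    correlation <- correlation[measured, measured]
  }
  if (min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("correlation matrix is not positive semi-definite")
  }
  if (quantize_punctate) {
    if (is.null(ladder) || length(ladder) == 0) abort("quantize_punctate requires a ladder")
    if (any(diff(ladder) <= 0)) abort("ladder must be strictly increasing")
  }

  structure(list(n_male = n_male, n_female = n_female, meta = meta,
                 measured = measured, log_mean = log_mean, log_sd = log_sd,
                 effect_d = effect_d, correlation = correlation,
                 quantize_punctate = quantize_punctate, ladder = ladder,
                 seed = seed),
            class = "cohort_config")
}

fill_named <- function(x, defaults, names_all, what) {
  out <- defaults[names_all]
  if (!is.null(x)) {
    unknown <- setdiff(names(x), names_all)
    if (length(unknown)) abort(paste0(what, ": unknown variables ",
                                      paste(unknown, collapse = ", ")))
    out[names(x)] <- x
  }
  out
}

#' Simulate a seeded pain-threshold cohort
#'
#' Draws per-class multivariate normal log10 stimulus magnitudes with the
#' configured correlation, shifts class means symmetrically by +-d/2 pooled
#' SDs to hit the target Cohen's d, exponentiates to the raw measurement
#' scale, censors at the device bounds, snaps punctate thresholds to the von
#' Frey ladder, and derives the sensitization-effect variables as the
#' difference of the realised log10 magnitudes (sensitized minus baseline).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; same seed gives a bit-identical cohort.
#' @return A raw-scale `pain_cohort` of `n_male + n_female` subjects.
#' @examples
#' ds <- simulate_cohort(cohort_config(), seed = 1)
#' dim(cohort_matrix(ds))
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  meta <- config$meta
  measured <- config$measured
  p <- length(measured)
  n0 <- config$n_male; n1 <- config$n_female

  Dmat <- diag(config$log_sd[measured], p)
  Sigma <- Dmat %*% config$correlation %*% Dmat
  cholS <- chol(Sigma + diag(1e-12, p))

  z <- with_seed(seed, {
    zz <- matrix(rnorm((n0 + n1) * p), n0 + n1, p) %*% cholS
    zz <- sweep(zz, 2, config$log_mean[measured], "+")
    shift <- config$effect_d[measured] * config$log_sd[measured] / 2
    zz[seq_len(n0), ] <- sweep(zz[seq_len(n0), , drop = FALSE], 2, shift, "-")
    zz[n0 + seq_len(n1), ] <- sweep(zz[n0 + seq_len(n1), , drop = FALSE], 2, shift, "+")
    zz
  })
  colnames(z) <- measured

  n <- n0 + n1
  vals <- matrix(NA_real_, n, nrow(meta), dimnames = list(NULL, meta$name))
  flags <- matrix(FALSE, n, nrow(meta), dimnames = list(NULL, meta$name))

  for (nm in measured) {
    j <- match(nm, meta$name)
    mag <- 10^z[, nm]
    snap_flag <- rep(FALSE, n)
    if (config$quantize_punctate && meta$unit[j] == "g") {
      sn <- snap_to_von_frey(mag, config$ladder)
      mag <- sn$values
      snap_flag <- sn$censored
    }
    raw <- from_magnitude(mag, meta$magnitude[j])
    cc <- apply_censoring(raw, meta$censor_low[j], meta$censor_high[j])
    vals[, nm] <- cc$values
    flags[, nm] <- cc$censored | snap_flag
  }
  # align with the loader's rule: any value sitting on a censor bound (e.g.
  # snapped onto the top von Frey rung) is flagged censored
  flags[, measured] <- flags[, measured] |
    infer_censoring_flags(vals[, measured, drop = FALSE],
                          meta[match(measured, meta$name), ])

  for (j in which(meta$sensitization == "effect")) {
    base <- meta$effect_baseline[j]; sens <- meta$effect_sensitized[j]
    jb <- match(base, meta$name); js <- match(sens, meta$name)
    mb <- to_magnitude(vals[, base], meta$magnitude[jb])
    ms <- to_magnitude(vals[, sens], meta$magnitude[js])
    vals[, meta$name[j]] <- log10(ms) - log10(mb)
    flags[, meta$name[j]] <- flags[, base] | flags[, sens]
  }

  data <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    sex = c(rep(0L, n0), rep(1L, n1))
  )
  data <- dplyr::bind_cols(data, tibble::as_tibble(vals))
  ds <- pain_cohort(data, meta = meta, censored = flags, scale = "raw")
  validate_pain_cohort(ds)
}

#' Snap punctate thresholds to the von Frey ladder
#'
#' Replaces each value by the nearest ladder force (ties resolved toward the
#' lower filament). Values above the strongest filament map to the ladder
#' maximum and are flagged censored.
#'
#' @param values Positive punctate thresholds (grams).
#' @param ladder Strictly increasing force ladder.
#' @return List with `values` (quantised) and `censored` (logical flags).
#' @examples
#' snap_to_von_frey(c(0.05, 500))
#' @export
snap_to_von_frey <- function(values, ladder = von_frey_ladder()) {
  if (length(ladder) == 0) abort("empty ladder")
  if (any(diff(ladder) <= 0)) abort("ladder must be strictly increasing")
  if (any(values <= 0)) abort("punctate thresholds must be positive")
  mids <- (head(ladder, -1) + tail(ladder, -1)) / 2
  idx <- findInterval(values, mids, left.open = TRUE) + 1L
  list(values = ladder[idx],
       censored = values > ladder[length(ladder)])
}

#' Clip values into device censoring bounds
#'
#' @param values Numeric vector.
#' @param lower,upper Censor bounds; `NA` means unbounded on that side.
#' @return List with `values` clipped into `[lower, upper]` and `censored`
#'   flags marking clipped cells.
#' @examples
#' apply_censoring(c(25, 10), lower = 0, upper = 20)
#' @export
apply_censoring <- function(values, lower = NA, upper = NA) {
  lo <- if (is.na(lower)) -Inf else lower
  hi <- if (is.na(upper)) Inf else upper
  if (lo >= hi) abort("lower bound must be below upper bound")
  flags <- values < lo | values > hi
  list(values = pmin(pmax(values, lo), hi), censored = flags)
}
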