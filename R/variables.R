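#' Default QST variable metadata
#'
#' Metadata for the eleven pain-threshold variables analysed by the package:
#' five baseline thresholds (blunt pressure, punctate pressure, heat, cold,
#' electrical current), three thresholds measured after topical sensitization
#' (punctate and heat after capsaicin, cold after menthol), and three derived
#' sensitization-effect variables, defined as the difference of log10
#' stimulus magnitudes (sensitized minus baseline).
#'
#' Each variable carries its stimulus modality, sensitization tag, physical
#' unit, device censoring bounds where the measurement hardware imposes them
#' (thermode range 0--50 degC from a 32 degC baseline, constant-current
#' stimulator 0--20 mA, von Frey ladder up to 300 g), a direction tag stating
#' whether larger values mean lower pain sensitivity, and the rule mapping
#' the recorded value to a positive stimulus magnitude (`"below_32C"` for
#' cold stimuli, whose strength is the temperature drop below the 32 degC
#' thermode baseline; `"identity"` otherwise; `"log_ratio"` for derived
#' effect variables already on the log scale).
#'
#' @return A tibble with one row per variable and columns `name`, `modality`,
#'   `sensitization`, `unit`, `censor_low`, `censor_high`, `direction`,
#'   `magnitude`, `effect_baseline`, `effect_sensitized`.
#' @examples
#' qst_variables()
#' @export
qst_variables <- function() {
  meta <- tibble::tribble(
    ~name,                          ~modality,    ~sensitization, ~unit,      ~censor_low, ~censor_high, ~direction,                   ~magnitude,  ~effect_baseline,     ~effect_sensitized,
    "pressure_blunt",               "mechanical", "none",         "N/cm2",    NA_real_,    NA_real_,     "higher_is_less_sensitive",   "identity",  NA_character_,        NA_character_,
    "pressure_punctate",            "mechanical", "none",         "g",        0.008,       300,          "higher_is_less_sensitive",   "identity",  NA_character_,        NA_character_,
    "heat_pain",                    "thermal",    "none",         "degC",     NA_real_,    50,           "higher_is_less_sensitive",   "identity",  NA_character_,        NA_character_,
    "cold_pain",                    "thermal",    "none",         "degC",     0,           NA_real_,     "higher_is_more_sensitive",   "below_32C", NA_character_,        NA_character_,
    "electrical_current",           "electrical", "none",         "mA",       0,           20,           "higher_is_less_sensitive",   "identity",  NA_character_,        NA_character_,
    "pressure_punctate_capsaicin",  "mechanical", "capsaicin",    "g",        0.008,       300,          "higher_is_less_sensitive",   "identity",  NA_character_,        NA_character_,
    "heat_pain_capsaicin",          "thermal",    "capsaicin",    "degC",     NA_real_,    50,           "higher_is_less_sensitive",   "identity",  NA_character_,        NA_character_,
    "cold_pain_menthol",            "thermal",    "menthol",      "degC",     0,           NA_real_,     "higher_is_more_sensitive",   "below_32C", NA_character_,        NA_character_,
    "punctate_capsaicin_effect",    "mechanical", "effect",       "log10 g",  NA_real_,    NA_real_,     "higher_is_less_sensitive",   "log_ratio", "pressure_punctate",  "pressure_punctate_capsaicin",
    "heat_capsaicin_effect",        "thermal",    "effect",       "log10 degC", NA_real_,  NA_real_,     "higher_is_less_sensitive",   "log_ratio", "heat_pain",          "heat_pain_capsaicin",
    "cold_menthol_effect",          "thermal",    "effect",       "log10 degC", NA_real_,  NA_real_,     "higher_is_more_sensitive",   "log_ratio", "cold_pain",          "cold_pain_menthol"
  )
  validate_variable_meta(meta)
}

validate_variable_meta <- function(meta) {
  meta <- tibble::as_tibble(meta)
  required <- c("name", "modality", "sensitization", "unit", "censor_low",
                "censor_high", "direction", "magnitude")
  missing <- setdiff(required, names(meta))
  if (length(missing)) abort(paste0("variable metadata lacks columns: ",
                                    paste(missing, collapse = ", ")))
  if (anyDuplicated(meta$name)) abort("duplicate variable names in metadata")
  if (!all(meta$modality %in% c("mechanical", "thermal", "electrical"))) {
    abort("modality must be one of mechanical, thermal, electrical")
  }
  if (!all(meta$sensitization %in% c("none", "capsaicin", "menthol", "effect"))) {
    abort("sensitization must be one of none, capsaicin, menthol, effect")
  }
  if (!all(meta$direction %in% c("higher_is_less_sensitive", "higher_is_more_sensitive"))) {
    abort("unknown direction tag")
  }
  if (!all(meta$magnitude %in% c("identity", "below_32C", "log_ratio"))) {
    abort("unknown magnitude mapping")
  }
  both <- !is.na(meta$censor_low) & !is.na(meta$censor_high)
  if (any(both & meta$censor_low >= meta$censor_high)) {
    abort("censor_low must be strictly below censor_high")
  }
  if (!"effect_baseline" %in% names(meta)) meta$effect_baseline <- NA_character_
  if (!"effect_sensitized" %in% names(meta)) meta$effect_sensitized <- NA_character_
  eff <- meta$sensitization == "effect"
  if (any(eff & (is.na(meta$effect_baseline) | is.na(meta$effect_sensitized)))) {
    abort("effect variables must name their baseline and sensitized source variables")
  }
  meta
}

#' The von Frey filament force ladder
#'
#' The 20 calibrated forces (in grams) of the von Frey hair set used for
#' punctate pressure thresholds. Punctate thresholds can only take values on
#' this ladder; values beyond its maximum are censored at 300 g.
#'
#' @return Numeric vector of 20 strictly increasing forces in grams.
#' @examples
#' von_frey_ladder()
#' @export
von_frey_ladder <- function() {
  c(0.008, 0.02, 0.04, 0.07, 0.16, 0.4, 0.6, 1, 1.4, 2,
    4, 6, 8, 10, 15, 26, 60, 100, 180, 300)
}

#' Read or write variable metadata as YAML
#'
#' Serialises the variable-metadata table (see [qst_variables()]) to a YAML
#' config file, one mapping per variable, and reads it back.
#'
#' @param meta Variable metadata tibble.
#' @param path File path.
#' @return `read_variable_meta()` returns the metadata tibble;
#'   `write_variable_meta()` returns `path` invisibly.
#' @export
write_variable_meta <- function(meta, path) {
  meta <- validate_variable_meta(meta)
  recs <- lapply(seq_len(nrow(meta)), function(i) {
    r <- as.list(meta[i, ])
    lapply(r, function(v) if (is.na(v)) NULL else v)
  })
  yaml::write_yaml(list(variables = recs), path)
  invisible(path)
}

#' @rdname write_variable_meta
#' @export
read_variable_meta <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$variables)) abort("metadata file lacks a 'variables' list")
  rows <- lapply(raw$variables, function(r) {
    tibble::tibble(
      name = r$name, modality = r$modality, sensitization = r$sensitization,
      unit = r$unit,
      censor_low = r$censor_low %f% NA_real_,
      censor_high = r$censor_high %f% NA_real_,
      direction = r$direction, magnitude = r$magnitude,
      effect_baseline = r$effect_baseline %f% NA_character_,
      effect_sensitized = r$effect_sensitized %f% NA_character_
    )
  })
  validate_variable_meta(dplyr::bind_rows(rows))
}
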