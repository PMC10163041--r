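test_that("cohort CSV write/load round-trips exactly", {
  ds <- simulate_cohort(cohort_config(), seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ds, path)
  back <- load_cohort(path)
  expect_equal(cohort_matrix(back), cohort_matrix(ds))
  expect_identical(back$sex, ds$sex)
  expect_identical(back$subject_id, ds$subject_id)
  expect_equal(cohort_censored(back), cohort_censored(ds))
})

test_that("cohort loading rejects malformed inputs", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("subject_id,sex", path)
  expect_error(load_cohort(path), "no subjects|header|empty")

  ds <- simulate_cohort(cohort_config(n_male = 5, n_female = 5), seed = 1)
  df <- as.data.frame(ds)
  expect_error(pain_cohort(dplyr::mutate(df, sex = 0L)), "single-class")
  expect_error(pain_cohort(dplyr::select(df, -sex)), "sex")
  expect_error(pain_cohort(dplyr::mutate(df, sex = ifelse(sex == 1, "x", "m"))),
               "unknown sex label")
  expect_error(pain_cohort(df[c(1, 1, 2:10), ]), "duplicate subject id")
})

test_that("at_bound imputation keeps bounds and flags; clean data unchanged", {
  ds <- simulate_cohort(cohort_config(), seed = 2)
  cen <- cohort_censored(ds)
  expect_gt(sum(cen), 0)
  imp <- impute_censored(ds, policy = "at_bound")
  expect_identical(cohort_censored(imp), cen)
  heat_cens <- which(cen[, "heat_pain"])
  if (length(heat_cens)) {
    expect_true(all(cohort_matrix(imp)[heat_cens, "heat_pain"] == 50))
  }
  expect_equal(cohort_matrix(imp)[!cen], cohort_matrix(ds)[!cen])

  clean <- toy_cohort(matrix(1:6, 3), matrix(7:12, 3))
  expect_identical(cohort_matrix(impute_censored(clean)), cohort_matrix(clean))
  expect_error(impute_censored(ds, policy = "nonsense"), "unknown imputation policy")
})

test_that("tail_draw imputation is seeded and lands strictly beyond the bound", {
  ds <- simulate_cohort(cohort_config(), seed = 3)
  cen <- cohort_censored(ds)
  a <- impute_censored(ds, policy = "tail_draw", seed = 7)
  b <- impute_censored(ds, policy = "tail_draw", seed = 7)
  expect_equal(cohort_matrix(a), cohort_matrix(b))
  cold <- cohort_matrix(a)[, "cold_pain"]
  cold_cens <- cen[, "cold_pain"]
  if (any(cold_cens)) expect_true(all(cold[cold_cens] < 0)) # beyond the 0 degC cutoff
  heat <- cohort_matrix(a)[, "heat_pain"]
  heat_cens <- cen[, "heat_pain"]
  if (any(heat_cens)) expect_true(all(heat[heat_cens] > 50))
})

test_that("log10 transform maps magnitudes, handles cold baseline, and inverts", {
  vals0 <- cbind(c(1, 100, 10), c(1, 1, 1))
  ds <- toy_cohort(vals0[, , drop = FALSE], vals0 + 1)
  lg <- log10_transform(ds)
  expect_equal(cohort_matrix(lg)[1:3, "v1"], c(0, 2, 1), ignore_attr = TRUE)
  expect_equal(cohort_scale(lg), "log10")
  back <- inverse_log10_transform(lg)
  expect_equal(cohort_matrix(back), cohort_matrix(ds), tolerance = 1e-12)
  expect_error(log10_transform(lg), "already")

  # cold threshold of 22 degC is a 10-degree drop below the 32 degC baseline
  ds2 <- simulate_cohort(cohort_config(), seed = 5)
  vals <- cohort_matrix(ds2)
  vals[1, "cold_pain"] <- 22
  ds2 <- painsex:::replace_values(ds2, vals)
  expect_equal(cohort_matrix(log10_transform(ds2))[1, "cold_pain"], 1)

  bad <- toy_cohort(matrix(c(-1, 2), 2), matrix(c(1, 2), 2))
  expect_error(log10_transform(bad), "non-positive")
})

test_that("cohens_d matches the hand-computed case and is antisymmetric", {
  ds <- toy_cohort(matrix(c(1, 2, 3)), matrix(c(2, 3, 4)))
  expect_equal(cohens_d(ds, "v1")$d, 1.0)

  swapped <- toy_cohort(matrix(c(2, 3, 4)), matrix(c(1, 2, 3)))
  expect_equal(cohens_d(swapped, "v1")$d, -1.0)

  same <- toy_cohort(matrix(c(1, 2, 3)), matrix(c(1, 2, 3)))
  expect_equal(cohens_d(same, "v1")$d, 0)

  const <- toy_cohort(matrix(c(1, 1, 1)), matrix(c(1, 1, 1)))
  expect_error(cohens_d(const, "v1"), "zero pooled variance")
})

test_that("group_compare is maximal for identical groups and powered at d = 1", {
  same <- toy_cohort(matrix(c(1, 2, 3, 4)), matrix(c(1, 2, 3, 4)))
  expect_equal(group_compare(same, "v1")$p_value, 1)

  hits <- 0
  nulls <- numeric(20)
  for (s in 1:20) {
    ds <- gaussian_cohort(69, 56, shifts = c(1, 0), seed = 100 + s)
    res <- group_compare(ds)
    hits <- hits + (res$p_value[res$variable == "v1"] < 0.05)
    nulls[s] <- res$p_value[res$variable == "v2"]
  }
  expect_gte(hits, 18) # d = 1 at n = 125 has ~100% Welch power
  expect_lte(sum(nulls < 0.05), 4) # type-I control on the null variable
})

test_that("correlation matrix is symmetric PSD with unit diagonal and pair p-values", {
  ds <- simulate_cohort(cohort_config(), seed = 8) |>
    impute_censored() |> log10_transform()
  cm <- correlation_matrix(ds)
  expect_equal(diag(cm$r), rep(1, 11), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  expect_gte(min(eigen(cm$r, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_true(all(!is.na(cm$p[upper.tri(cm$p)])))

  dup <- gaussian_cohort(30, 30, shifts = c(0, 0), seed = 1)
  vals <- cohort_matrix(dup)
  vals[, "v2"] <- vals[, "v1"]
  dup <- painsex:::replace_values(dup, vals)
  cm2 <- correlation_matrix(dup)
  expect_equal(cm2$r["v1", "v2"], 1)
  expect_lt(cm2$p["v1", "v2"], 1e-12)

  const <- toy_cohort(matrix(c(1, 1, 1)), matrix(c(1, 1, 1)))
  expect_error(correlation_matrix(const), "constant variable")

  td <- tidy(cm)
  expect_equal(nrow(td), 11 * 10 / 2)
})

test_that("variable metadata round-trips through YAML config", {
  meta <- qst_variables()
  path <- withr::local_tempfile(fileext = ".yml")
  write_variable_meta(meta, path)
  expect_equal(read_variable_meta(path), meta)
})
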