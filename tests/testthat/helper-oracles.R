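# Shared fixture builders and independent oracles used across the suite.

# Minimal metadata: k uncensored mechanical variables on the identity
# magnitude scale (keeps unit/censoring machinery out of unit tests).
toy_meta <- function(k = 2, names = paste0("v", seq_len(k))) {
  tibble::tibble(
    name = names, modality = "mechanical", sensitization = "none",
    unit = "g", censor_low = NA_real_, censor_high = NA_real_,
    direction = "higher_is_less_sensitive", magnitude = "identity",
    effect_baseline = NA_character_, effect_sensitized = NA_character_
  )
}

# Build a pain_cohort directly from per-class value matrices (men, women).
toy_cohort <- function(X0, X1, scale = "raw") {
  X0 <- as.matrix(X0); X1 <- as.matrix(X1)
  k <- ncol(X0)
  meta <- toy_meta(k)
  vals <- rbind(X0, X1)
  colnames(vals) <- meta$name
  df <- data.frame(subject_id = sprintf("T%03d", seq_len(nrow(vals))),
                   sex = rep(c(0L, 1L), c(nrow(X0), nrow(X1))))
  ds <- pain_cohort(cbind(df, as.data.frame(vals)), meta = meta, scale = scale)
  ds
}

# Two-class Gaussian toy data: variable j gets standardised mean shift
# shifts[j] between classes (women higher).
gaussian_cohort <- function(n0, n1, shifts, seed, sd = 1) {
  withr::with_seed(seed, {
    k <- length(shifts)
    X0 <- matrix(rnorm(n0 * k, sd = sd), n0, k)
    X1 <- matrix(rnorm(n1 * k, sd = sd), n1, k)
    X1 <- sweep(X1, 2, shifts * sd, "+")
    toy_cohort(X0, X1, scale = "log10")
  })
}

# --- independent oracles -----------------------------------------------------

# Brute-force two-sample KS distance: maximum ECDF gap over pooled values.
ks_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# Exhaustive pair-comparison ROC-AUC (ties count half).
auc_oracle <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Dense sampling of the piecewise-linear ABC curve.
sample_abc_curve <- function(curve, n_grid = 4000) {
  xs <- seq(0, 1, length.out = n_grid)
  ys <- approx(curve$effort, curve$yield, xout = xs)$y
  list(x = xs, y = ys)
}

# Grid-minimisation oracle for the Pareto point (distance to (0, 1)).
pareto_oracle <- function(curve, n_grid = 4000) {
  g <- sample_abc_curve(curve, n_grid)
  d <- sqrt(g$x^2 + (1 - g$y)^2)
  i <- which.min(d)
  c(effort = g$x[i], yield = g$y[i], dist = d[i])
}

# Slope-scan oracle for the break-even point: earliest sampled point whose
# local slope drops to 1 (diagonal curves map to (1, 1)).
break_even_oracle <- function(curve, n_grid = 4000) {
  g <- sample_abc_curve(curve, n_grid)
  sl <- diff(g$y) / diff(g$x)
  if (all(abs(sl - 1) < 1e-9)) return(c(effort = 1, yield = 1))
  i <- which(sl < 1 + 1e-9)[1]
  c(effort = g$x[i], yield = g$y[i])
}
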