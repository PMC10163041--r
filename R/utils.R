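# Internal helpers shared across modules.

# Evaluate `code` under a local, restorable RNG state. `seed` may be NULL,
# in which case the current RNG stream is used (and advanced).
with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Derive a reproducible sub-seed from a parent seed and a stream index,
# kept within the 32-bit integer range.
spawn_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + index * 8191) %% 2147483647L)
}

# Stratified sample of row indices: draws `round(frac * n_c)` rows from each
# class of `y` (0/1). Guarantees at least one row per class when frac > 0.
stratified_indices <- function(y, frac) {
  stopifnot(frac > 0, frac < 1)
  idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
    k <- max(1L, round(frac * length(ix)))
    if (k >= length(ix)) k <- length(ix) - 1L
    if (k < 1L) abort("class too small to subsample")
    sample(ix, k)
  }), use.names = FALSE)
  sort(idx)
}

assert_binary_labels <- function(y) {
  u <- sort(unique(as.integer(y)))
  if (!identical(u, c(0L, 1L))) {
    abort("sex labels must be binary (0 = men, 1 = women) with both classes present")
  }
  invisible(TRUE)
}

`%f%` <- function(x, default) if (is.null(x) || length(x) == 0) default else x
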