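#' ABC curve of a set of positive item scores
#'
#' Sorts the scores in decreasing order (stable: ties keep input order) and
#' returns the cumulative-contribution curve: point i is (i/n, cumulative
#' share of the total score), starting at (0, 0) and ending at (1, 1),
#' interpolated piecewise-linearly between points. The curve is
#' non-decreasing and concave.
#'
#' @param scores Nonnegative numeric vector with at least one positive
#'   entry; names are kept as item labels.
#' @return Tibble with columns `effort`, `yield` (n + 1 vertices).
#' @export
abc_curve <- function(scores) {
  check_scores(scores)
  s <- sort(scores, decreasing = TRUE, method = "radix") # stable
  n <- length(s)
  tibble::tibble(effort = seq(0, n) / n,
                 yield = c(0, cumsum(s) / sum(s)))
}

check_scores <- function(scores) {
  if (length(scores) == 0) abort("no scores")
  if (any(!is.finite(scores))) abort("scores must be finite")
  if (any(scores < 0)) abort("scores must be nonnegative")
  if (all(scores == 0)) abort("all scores are zero")
  invisible(scores)
}

#' Break-even point of an ABC curve
#'
#' The earliest point on the piecewise-linear curve where the slope falls to
#' 1 (the marginal yield per unit effort equals the average). For the
#' diagonal curve of all-equal scores the convention is (1, 1).
#'
#' @param curve Tibble from [abc_curve()].
#' @return One-row tibble with `effort`, `yield`.
#' @export
break_even_point <- function(curve) {
  slopes <- diff(curve$yield) / diff(curve$effort)
  if (all(abs(slopes - 1) < 1e-12)) {
    return(tibble::tibble(effort = 1, yield = 1))
  }
  unit <- which(abs(slopes - 1) < 1e-12)
  if (length(unit)) {
    i <- unit[1] # left endpoint of the first unit-slope segment
    return(curve[i, c("effort", "yield")])
  }
  i <- max(which(slopes > 1)) # joint where slope crosses 1
  curve[i + 1L, c("effort", "yield")]
}

#' Pareto point of an ABC curve
#'
#' The point of the piecewise-linear curve closest (Euclidean) to the ideal
#' of full yield at zero effort, (0, 1); the earliest such point on ties.
#'
#' @param curve Tibble from [abc_curve()].
#' @return One-row tibble with `effort`, `yield`.
#' @export
pareto_point <- function(curve) {
  best <- c(effort = curve$effort[1], yield = curve$yield[1])
  best_d <- dist_to_ideal(best[1], best[2])
  for (i in seq_len(nrow(curve) - 1)) {
    p <- closest_on_segment(curve$effort[i], curve$yield[i],
                            curve$effort[i + 1], curve$yield[i + 1])
    d <- dist_to_ideal(p[1], p[2])
    if (d < best_d - 1e-12) {
      best <- p
      best_d <- d
    }
  }
  tibble::tibble(effort = unname(best[1]), yield = unname(best[2]))
}

dist_to_ideal <- function(x, y) sqrt(x^2 + (1 - y)^2)

# Orthogonal projection of (0, 1) onto a segment, clamped to its ends;
# returns the earlier endpoint on degenerate segments.
closest_on_segment <- function(x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- if (len2 == 0) 0 else ((0 - x1) * dx + (1 - y1) * dy) / len2
  t <- min(1, max(0, t))
  c(effort = x1 + t * dx, yield = y1 + t * dy)
}

#' Computed ABC categorisation of item scores
#'
#' Divides positive item scores into the "important few" (A), an
#' intermediate set (B) and the "trivial many" (C) using the geometry of
#' the ABC curve: the A/B boundary is the smaller of the Pareto-point and
#' break-even-point efforts, and the B/C boundary is the effort of the
#' curve point closest to the ideal point shifted to the A/B boundary,
#' (ab_limit, 1). Item counts at the boundaries round up, so category A is
#' never empty for positive input; zero-score items are always category C.
#'
#' @param scores Named nonnegative scores (e.g. selection vote sums).
#' @return An `abc_result` with the sorted item table (`items`), the curve,
#'   `pareto_point`, `break_even_point`, `ab_limit`, `bc_limit`. Use
#'   [tidy()] for the item/category tibble.
#' @examples
#' abc_categorize(c(a = 10, b = 1, c = 1, d = 1, e = 1))
#' @export
abc_categorize <- function(scores) {
  check_scores(scores)
  n <- length(scores)
  nms <- names(scores) %||% paste0("item", seq_len(n))
  ord <- order(-scores) # stable for ties (input order)
  sorted <- scores[ord]

  curve <- abc_curve(scores)
  pp <- pareto_point(curve)
  bep <- break_even_point(curve)
  ab_limit <- min(pp$effort, bep$effort)

  bc_candidates <- vapply(seq_len(nrow(curve)), function(i) {
    sqrt((curve$effort[i] - ab_limit)^2 + (curve$yield[i] - 1)^2)
  }, numeric(1))
  bc_limit <- curve$effort[which.min(bc_candidates)]
  bc_limit <- max(bc_limit, ab_limit)

  n_a <- max(1L, ceiling(n * ab_limit - 1e-9))
  n_ab <- max(n_a, ceiling(n * bc_limit - 1e-9))
  cat_sorted <- rep("C", n)
  cat_sorted[seq_len(n_ab)] <- "B"
  cat_sorted[seq_len(n_a)] <- "A"
  cat_sorted[sorted == 0] <- "C"
  if (all(cat_sorted != "A")) cat_sorted[which(sorted > 0)[1]] <- "A"

  items <- tibble::tibble(item = nms[ord], score = unname(sorted),
                          rank = seq_len(n), effort = seq_len(n) / n,
                          category = cat_sorted)
  structure(list(items = items, curve = curve,
                 pareto_point = pp, break_even_point = bep,
                 ab_limit = ab_limit, bc_limit = bc_limit),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  ab <- split(x$items$item, x$items$category)
  cat(sprintf("<abc_result> %d items | ab_limit %.3f, bc_limit %.3f\n",
              nrow(x$items), x$ab_limit, x$bc_limit))
  for (k in c("A", "B", "C")) {
    cat(sprintf("  %s: %s\n", k, paste(ab[[k]] %f% "-", collapse = ", ")))
  }
  invisible(x)
}

#' @export
tidy.abc_result <- function(x, ...) x$items

#' @export
glance.abc_result <- function(x, ...) {
  tibble::tibble(n_items = nrow(x$items),
                 n_a = sum(x$items$category == "A"),
                 n_b = sum(x$items$category == "B"),
                 n_c = sum(x$items$category == "C"),
                 ab_limit = x$ab_limit, bc_limit = x$bc_limit)
}

#' @export
autoplot.abc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$effort, .data$yield)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = object$pareto_point, colour = "red") +
    ggplot2::geom_vline(xintercept = c(object$ab_limit, object$bc_limit),
                        colour = "red", linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "effort (fraction of items)",
                  y = "yield (fraction of total score)") +
    ggplot2::theme_minimal()
}

#' Items in category A
#'
#' @param x An `abc_result`.
#' @return Character vector of A-set item names, in decreasing score order.
#' @export
abc_set_a <- function(x) {
  stopifnot(inherits(x, "abc_result"))
  x$items$item[x$items$category == "A"]
}

#' Recursive computed ABC analysis
#'
#' Re-applies [abc_categorize()] to the A set of the previous level until
#' the A set has a single member, stops shrinking, or `max_depth` levels
#' have run. The final A set is the sparse item set.
#'
#' @param scores Named nonnegative scores.
#' @param max_depth Maximum recursion depth (>= 1).
#' @return A `recursive_abc_result`: list of per-level `abc_result`s
#'   (`levels`) and the final `sparse_set`.
#' @export
recursive_abc <- function(scores, max_depth = 10) {
  if (max_depth < 1) abort("max_depth must be at least 1")
  levels <- list()
  current <- scores
  if (is.null(names(current))) names(current) <- paste0("item", seq_along(current))
  for (depth in seq_len(max_depth)) {
    res <- abc_categorize(current)
    levels[[depth]] <- res
    a <- abc_set_a(res)
    if (length(a) == length(current) || length(a) <= 1) {
      current <- current[a]
      break
    }
    current <- current[a]
  }
  structure(list(levels = levels, sparse_set = names(current)),
            class = "recursive_abc_result")
}

#' @export
print.recursive_abc_result <- function(x, ...) {
  cat(sprintf("<recursive_abc_result> %d level%s; sparse set: %s\n",
              length(x$levels), if (length(x$levels) == 1) "" else "s",
              paste(x$sparse_set, collapse = ", ")))
  invisible(x)
}
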