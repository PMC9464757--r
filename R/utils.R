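#' Deterministic largest-remainder allocation
#'
#' Split `n` items over categories proportionally to `weights`, rounding by
#' the largest-remainder rule so the parts always sum to `n` exactly. Ties in
#' the remainders are broken by category position.
#'
#' @param n Non-negative integer total.
#' @param weights Non-negative numeric weights (not all zero).
#' @return Integer vector of the same length (and names) as `weights`,
#'   summing to `n`.
#' @export
#' @examples
#' allocate_counts(1000, c(Luminal = 0.85, Basal = 0.10, HER2 = 0.05))
allocate_counts <- function(n, weights) {
  stopifnot(length(n) == 1L, is.finite(n), n >= 0, n == round(n))
  if (any(!is.finite(weights)) || any(weights < 0) || sum(weights) <= 0) {
    stop("`weights` must be non-negative, finite and not all zero")
  }
  quota <- n * weights / sum(weights)
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    take <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1L
  }
  stats::setNames(as.integer(counts), names(weights))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rank class scores: descending score, ties broken by model class order.
rank_classes <- function(scores, classes) {
  idx <- match(names(scores), classes)
  order(-scores, idx)
}

# Clip a numeric vector into [lo, hi].
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_if_missing_genes <- function(needed, available, what = "expression matrix") {
  missing <- setdiff(needed, available)
  if (length(missing)) {
    stop("gene(s) absent from ", what, ": ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) sprintf(" (and %d more)", length(missing) - 10L) else "")
  }
  invisible(TRUE)
}
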