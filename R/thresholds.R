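# Cohort-level thresholds on the top score difference, per winning class.

# Mclust() resolves `mclustBIC` in the calling environment, so it must be
# imported explicitly.
#' @importFrom mclust Mclust mclustBIC
NULL

# Fit 1- vs 2-component Gaussian mixture to a difference vector and derive a
# threshold. Returns list(threshold, decision, diagnostics).
.threshold_one <- function(d, fallback_q, grid_step) {
  quant <- function() {
    t <- unname(stats::quantile(d, fallback_q))
    list(threshold = max(t, 0), decision = "quantile-fallback",
         diagnostics = list(quantile = fallback_q, n = length(d)))
  }
  if (length(unique(d)) < 3L) return(quant())
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(d, G = 1:2, verbose = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$G != 2L) return(quant())
  p <- fit$parameters
  sds <- sqrt(p$variance$sigmasq)
  if (length(sds) == 1L) sds <- rep(sds, 2L)   # equal-variance model
  mu <- p$mean
  if (abs(mu[2L] - mu[1L]) <= sum(sds)) return(quant())
  grid <- seq(min(mu), max(mu), by = grid_step)
  dens <- p$pro[1L] * stats::dnorm(grid, mu[1L], sds[1L]) +
          p$pro[2L] * stats::dnorm(grid, mu[2L], sds[2L])
  list(threshold = max(grid[which.min(dens)], 0), decision = "bimodal-valley",
       diagnostics = list(means = unname(mu), sds = unname(sds),
                          proportions = unname(p$pro), n = length(d)))
}

#' Fit per-subtype thresholds on the top score difference
#'
#' For every winning class, the distribution of `d` (top minus second score)
#' over the samples won by that class is tested for bimodality: 1- and
#' 2-component Gaussian mixtures are fitted and compared by BIC. When the
#' 2-component model is preferred and its component means are separated by
#' more than the sum of their standard deviations, the threshold is the
#' density minimum between the two means (grid search); otherwise the
#' threshold falls back to a low quantile of `d`. Classes with fewer than
#' `min_class_n` winners are fitted on the pooled distribution over all
#' samples instead.
#'
#' @param scores_table Output of [classify_cohort()].
#' @param min_class_n Minimum winners per class before the class-specific
#'   distribution is used (default 50).
#' @param fallback_q Quantile for the fallback rule (default 0.05).
#' @param grid_step Grid resolution of the valley search (default 1e-4).
#' @return Object of class `threshold_set`: data.frame with one row per
#'   class (`class`, `n`, `pooled`, `threshold`, `decision`) and the fit
#'   diagnostics as an attribute. Classes that won no samples get an `NA`
#'   threshold with decision `"undefined"`.
#' @export
fit_difference_thresholds <- function(scores_table, min_class_n = 50,
                                      fallback_q = 0.05, grid_step = 1e-4) {
  classes <- attr(scores_table, "classes") %||%
    sub("^score_", "", grep("^score_", names(scores_table), value = TRUE))
  d_all <- scores_table$d_top
  if (is.null(d_all)) stop("`scores_table` must carry a `d_top` column")
  rows <- list()
  diagnostics <- list()
  for (cl in classes) {
    d_cl <- d_all[scores_table$winning_class == cl]
    if (length(d_cl) == 0L) {
      rows[[cl]] <- data.frame(class = cl, n = 0L, pooled = FALSE,
                               threshold = NA_real_, decision = "undefined",
                               stringsAsFactors = FALSE)
      next
    }
    pooled <- length(d_cl) < min_class_n
    fit <- .threshold_one(if (pooled) d_all else d_cl, fallback_q, grid_step)
    rows[[cl]] <- data.frame(class = cl, n = length(d_cl), pooled = pooled,
                             threshold = fit$threshold, decision = fit$decision,
                             stringsAsFactors = FALSE)
    diagnostics[[cl]] <- fit$diagnostics
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "diagnostics") <- diagnostics
  attr(out, "fallback_q") <- fallback_q
  class(out) <- c("threshold_set", "data.frame")
  out
}

#' Look up the threshold for a winning class
#'
#' @param thresholds A [fit_difference_thresholds()] result.
#' @param class Class name.
#' @return The numeric threshold; errors if it is undefined.
#' @export
threshold_for <- function(thresholds, class) {
  stopifnot(inherits(thresholds, "threshold_set"))
  i <- match(class, thresholds$class)
  if (is.na(i) || !is.finite(thresholds$threshold[i])) {
    stop("no threshold defined for winning class '", class, "'")
  }
  thresholds$threshold[i]
}

#' Serialize a threshold set to JSON
#'
#' @param thresholds A [fit_difference_thresholds()] result.
#' @param path Output path.
#' @export
write_threshold_set <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "threshold_set"))
  jsonlite::write_json(
    list(thresholds = as.data.frame(unclass(thresholds))[
           , c("class", "n", "pooled", "threshold", "decision")],
         diagnostics = attr(thresholds, "diagnostics")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}
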