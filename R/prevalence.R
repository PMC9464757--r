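# Dual-subtype prevalence under a clinical subtype mixture.

#' Clinical subtype mixture specification
#'
#' Default weights follow population-registry distributions of the four
#' HR/HER2 clinical subtypes: 70% HR+HER2-, 13% HR+HER2+, 5% HR-HER2+ and
#' 12% HR-HER2-.
#'
#' @param weights Named fractions over the clinical subtypes, summing to 1.
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(weights = c("HR+HER2-" = 0.70, "HR+HER2+" = 0.13,
                                     "HR-HER2+" = 0.05, "HR-HER2-" = 0.12)) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("`weights` must be named by clinical subtype")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("mixture weights must be non-negative and sum to 1")
  }
  structure(list(weights = weights), class = "mixture_spec")
}

#' Estimate dual-subtype prevalence under a clinical subtype mixture
#'
#' The cohort is repeatedly resampled to the target clinical composition:
#' each iteration draws, with replacement, `round(weight_k * subset_size)`
#' samples from stratum `k` and records the fraction of dual calls in the
#' resampled subset. Because the per-sample dual indicator is binary,
#' with-replacement stratum draws are realized as binomial draws on the
#' stratum's observed dual rate. The estimate is the mean over iterations
#' and the confidence interval the 2.5/97.5 percentile of the iteration
#' fractions.
#'
#' @param calls Character vector of call kinds (`"Single"`, `"Dual"`,
#'   `"Triple"`) or a data.frame with a `kind` column.
#' @param clinical_subtype Character vector of clinical strata, same length.
#' @param mix A [mixture_spec()].
#' @param n_iter Number of resampling iterations (at least 2).
#' @param subset_size Target size of each resampled subset.
#' @param seed Integer RNG seed.
#' @param include_triple Count Triple calls in the numerator (default
#'   `FALSE`; triples are accounted separately).
#' @return Object of class `prevalence_estimate`: list with `estimate_pct`,
#'   `ci_pct` (length 2), `n_iter`, `subset_size`, `weights`, `seed` and the
#'   per-stratum observed rates.
#' @export
estimate_mixture_prevalence <- function(calls, clinical_subtype, mix = mixture_spec(),
                                        n_iter = 1000, subset_size = 10000,
                                        seed = 1, include_triple = FALSE) {
  if (is.data.frame(calls)) calls <- calls$kind
  stopifnot(inherits(mix, "mixture_spec"))
  if (length(calls) != length(clinical_subtype)) {
    stop("`calls` and `clinical_subtype` must have the same length")
  }
  if (n_iter < 2) stop("`n_iter` must be at least 2")
  hit <- calls == "Dual" | (include_triple & calls == "Triple")
  w <- mix$weights[mix$weights > 0]
  quota <- round(w * subset_size)
  strata_rate <- numeric(length(w))
  names(strata_rate) <- names(w)
  for (k in names(w)) {
    members <- clinical_subtype == k
    if (!any(members)) {
      stop("stratification error: no samples in required stratum '", k, "'")
    }
    strata_rate[k] <- mean(hit[members])
  }
  set.seed(seed)
  draws <- vapply(names(w),
                  function(k) as.numeric(stats::rbinom(n_iter, quota[k], strata_rate[k])),
                  numeric(n_iter))
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = n_iter)
  frac <- 100 * rowSums(draws) / sum(quota)
  ci <- unname(stats::quantile(frac, c(0.025, 0.975)))
  structure(list(
    estimate_pct = mean(frac),
    ci_pct = ci,
    n_iter = as.integer(n_iter),
    subset_size = as.integer(subset_size),
    weights = mix$weights,
    stratum_rates = strata_rate,
    include_triple = include_triple,
    seed = as.integer(seed)
  ), class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("Mixture-weighted dual-subtype prevalence: %.2f%% (95%% CI %.2f-%.2f)\n",
              x$estimate_pct, x$ci_pct[1], x$ci_pct[2]))
  cat(sprintf("  %d iterations of stratified subsets of size %d\n",
              x$n_iter, x$subset_size))
  invisible(x)
}

#' Serialize a prevalence estimate to JSON
#'
#' @param x A [estimate_mixture_prevalence()] result.
#' @param path Output path.
#' @export
write_prevalence_estimate <- function(x, path) {
  stopifnot(inherits(x, "prevalence_estimate"))
  jsonlite::write_json(
    list(estimate_pct = x$estimate_pct, ci_pct = x$ci_pct,
         n_iter = x$n_iter, subset_size = x$subset_size,
         weights = as.list(x$weights), stratum_rates = as.list(x$stratum_rates),
         include_triple = x$include_triple, seed = x$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
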