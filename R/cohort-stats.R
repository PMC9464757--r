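# Clinical subtype derivation rules and the cohort statistics toolkit.

#' Derive hormone-receptor status from ER / PR positivity
#'
#' A tumor is HR-positive when ER or PR staining reaches at least 1%;
#' otherwise HR-negative. With one marker missing the rule is applied to the
#' available one unless it is below 1% (then the status cannot be excluded
#' and is missing). Both missing yields `NA`.
#'
#' @param er_pct,pr_pct Percent positivity in `[0, 100]`, `NA` allowed.
#' @return Character vector in `{"HR+", "HR-"}` with `NA` for missing status.
#' @export
derive_hr_status <- function(er_pct, pr_pct) {
  n <- max(length(er_pct), length(pr_pct))
  er_pct <- rep_len(er_pct, n)
  pr_pct <- rep_len(pr_pct, n)
  rng <- function(x) any(is.finite(x) & (x < 0 | x > 100))
  if (rng(er_pct) || rng(pr_pct)) stop("ER/PR percentages must lie in [0, 100]")
  pos <- (is.finite(er_pct) & er_pct >= 1) | (is.finite(pr_pct) & pr_pct >= 1)
  neg <- is.finite(er_pct) & er_pct < 1 & is.finite(pr_pct) & pr_pct < 1
  ifelse(pos, "HR+", ifelse(neg, "HR-", NA_character_))
}

#' Derive HER2 status from IHC score and FISH
#'
#' IHC 0, 1+ and 2+/FISH-non-amplified are HER2-negative; IHC 2+/FISH-
#' amplified and 3+ are HER2-positive. IHC 2+ with missing FISH is a missing
#' status (`NA`).
#'
#' @param her2_ihc Character vector in `{"0", "1+", "2+", "3+"}`.
#' @param her2_fish Character vector in `{"amplified", "non-amplified"}` or
#'   `NA`; only consulted for IHC 2+.
#' @return Character vector in `{"HER2+", "HER2-"}` with `NA` for missing.
#' @export
derive_her2_status <- function(her2_ihc, her2_fish = NA_character_) {
  n <- max(length(her2_ihc), length(her2_fish))
  ihc <- rep_len(as.character(her2_ihc), n)
  fish <- rep_len(as.character(her2_fish), n)
  bad <- !is.na(ihc) & !ihc %in% c("0", "1+", "2+", "3+")
  if (any(bad)) stop("invalid HER2 IHC score(s): ", paste(unique(ihc[bad]), collapse = ", "))
  bad_f <- !is.na(fish) & !fish %in% c("amplified", "non-amplified")
  if (any(bad_f)) stop("invalid HER2 FISH value(s): ", paste(unique(fish[bad_f]), collapse = ", "))
  out <- rep(NA_character_, n)
  out[ihc %in% c("0", "1+")] <- "HER2-"
  out[ihc == "3+"] <- "HER2+"
  out[ihc == "2+" & fish == "amplified"] <- "HER2+"
  out[ihc == "2+" & fish == "non-amplified"] <- "HER2-"
  out
}

#' Combine HR and HER2 status into the four clinical subtypes
#'
#' @param hr Character in `{"HR+", "HR-"}`.
#' @param her2 Character in `{"HER2+", "HER2-"}`.
#' @return Character such as `"HR+HER2-"`; `NA` when either input is missing.
#' @export
derive_clinical_subtype <- function(hr, her2) {
  ifelse(is.na(hr) | is.na(her2), NA_character_, paste0(hr, her2))
}

#' Tag samples in the low-proliferation (TNLP) Ki-67 range
#'
#' @param ki67_pct Percent Ki-67 positivity.
#' @param threshold Cut point, default 30 (Ki-67 below it is "TNLP-range").
#' @return Logical vector.
#' @export
ki67_tnlp <- function(ki67_pct, threshold = 30) {
  is.finite(ki67_pct) & ki67_pct < threshold
}

#' Tag ER-low-positive samples (1-10% IHC, inclusive)
#'
#' @param er_pct Percent ER positivity.
#' @return Logical vector.
#' @export
er_low_positive <- function(er_pct) {
  is.finite(er_pct) & er_pct >= 1 & er_pct <= 10
}

#' Pearson chi-square test of independence
#'
#' Classic Pearson statistic without continuity correction;
#' `df = (r - 1)(c - 1)`, p from the upper chi-square tail.
#'
#' @param tab Matrix or table of non-negative counts.
#' @return List with `statistic`, `df`, `p_value` and the `expected` counts.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab))) stop("counts must be non-negative and finite")
  n <- sum(tab)
  if (n == 0) stop("degenerate table: no observations")
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected == 0)) {
    stop("degenerate table: zero expected count (empty row or column margin)")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = expected)
}

#' Two-sample t-test (Welch by default)
#'
#' @param x,y Numeric vectors, each with at least 2 finite values.
#' @param var_equal If `TRUE`, use the pooled-variance test instead of
#'   Welch/Satterthwaite.
#' @return List with `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
welch_t_test <- function(x, y, var_equal = FALSE) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("insufficient data: each group needs at least 2 finite values")
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Proportion with Wilson score confidence interval
#'
#' @param k Number of successes.
#' @param n Number of trials (at least 1).
#' @param conf_level Confidence level, default 0.95.
#' @return List with `point`, `lower`, `upper` (fractions), `k`, `n`.
#' @export
#' @examples
#' proportion_with_ci(34, 47)
proportion_with_ci <- function(k, n, conf_level = 0.95) {
  if (n < 1) stop("undefined proportion: n must be at least 1")
  if (k < 0 || k > n) stop("`k` must lie in [0, n]")
  ci <- suppressWarnings(
    stats::prop.test(k, n, conf.level = conf_level, correct = FALSE)$conf.int
  )
  list(point = k / n, lower = ci[1L], upper = ci[2L], k = k, n = n)
}

#' Multivariate logistic regression with Wald tests
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' `stats::glm`), reporting per-covariate coefficient, standard error and
#' Wald p-value. Quasi-complete separation is detected from diverging
#' coefficients and flagged: the partial results are returned with attribute
#' `separation = TRUE` and a warning.
#'
#' @param design data.frame or numeric matrix of named covariates (no
#'   intercept column; one is added).
#' @param outcome Binary 0/1 vector.
#' @param max_iter,tol IRLS iteration cap and coefficient-change tolerance.
#' @return data.frame with columns `term`, `estimate`, `se`, `z`, `p_value`.
#' @export
logistic_fit <- function(design, outcome, max_iter = 100, tol = 1e-8) {
  design <- as.data.frame(design)
  if (is.null(names(design)) || any(!nzchar(names(design)))) {
    stop("design columns must be named")
  }
  if (nrow(design) != length(outcome)) stop("design and outcome sizes differ")
  if (!all(outcome %in% c(0, 1))) stop("`outcome` must be binary 0/1")
  if (length(unique(outcome)) < 2L) {
    stop("degenerate outcome: all responses identical")
  }
  mm <- stats::model.matrix(~ ., data = design)
  for (j in seq_len(ncol(mm))[-1L]) {
    if (stats::sd(mm[, j]) == 0) stop("constant covariate: ", colnames(mm)[j])
  }
  if (qr(mm)$rank < ncol(mm)) stop("exactly collinear covariates in design")
  fit <- suppressWarnings(stats::glm.fit(
    mm, outcome, family = stats::binomial(),
    control = stats::glm.control(epsilon = tol, maxit = max_iter)
  ))
  coefs <- fit$coefficients
  cov_un <- chol2inv(chol(crossprod(mm * sqrt(fit$weights), mm)))
  se <- sqrt(diag(cov_un))
  separation <- !fit$converged || any(abs(coefs) > 12) ||
    any(fit$fitted.values < 1e-10) || any(fit$fitted.values > 1 - 1e-10)
  if (separation) {
    warning("possible separation: coefficients may be diverging; ",
            "estimates flagged unusable")
  }
  z <- coefs / se
  out <- data.frame(
    term = colnames(mm), estimate = unname(coefs), se = unname(se),
    z = unname(z), p_value = 2 * stats::pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "separation") <- separation
  attr(out, "converged") <- fit$converged
  out
}
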