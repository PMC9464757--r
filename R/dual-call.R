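# Single / Dual / Triple subtype calling.

#' Call a sample as Single, Dual or Triple subtype
#'
#' The top pair (highest vs second-highest score) is *indiscernible* when the
#' observed difference falls strictly below the winning class's cohort
#' threshold,
#' or when the bootstrap flip fraction between the two classes exceeds
#' `alpha`. If the top pair is indiscernible, the (second, third) pair is
#' tested by the same rule — reusing the winning class's threshold on the
#' second-vs-third difference — and the sample is called Triple when both
#' pairs are indiscernible, Dual when only the top pair is, and Single
#' otherwise.
#'
#' @param scores Named numeric vector of class scores for one sample.
#' @param boot The sample's [bootstrap_scores()]; may be `NULL` when
#'   `use_bootstrap = FALSE`.
#' @param thresholds A [fit_difference_thresholds()] result.
#' @param alpha Flip-fraction cutoff in (0, 1), default 0.05.
#' @param use_threshold,use_bootstrap Enable/disable the two indiscernibility
#'   criteria (both on by default; they combine by OR).
#' @param sample_id Optional identifier carried into the call.
#' @return Object of class `dual_call`: list with `sample_id`, `kind`
#'   (`"Single"`, `"Dual"` or `"Triple"`), `components` (classes in
#'   descending score order), `label` (e.g. `"Luminal-Basal-type"`), and the
#'   evidence (`d_top`, `d_23`, `flip_top`, `flip_23`, `threshold`).
#' @export
classify_single_dual <- function(scores, boot, thresholds, alpha = 0.05,
                                 use_threshold = TRUE, use_bootstrap = TRUE,
                                 sample_id = NA_character_) {
  if (is.null(names(scores)) || length(scores) < 2L) {
    stop("`scores` must be a named vector of at least 2 class scores")
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (use_bootstrap && is.null(boot)) {
    stop("bootstrap criterion enabled but no bootstrap distribution supplied")
  }
  classes <- names(scores)
  ord <- rank_classes(scores, classes)
  top <- classes[ord[1L]]
  second <- classes[ord[2L]]
  third <- if (length(classes) >= 3L) classes[ord[3L]] else NA_character_
  t_win <- threshold_for(thresholds, top)

  d_top <- unname(scores[ord[1L]] - scores[ord[2L]])
  flip_top <- if (use_bootstrap) flip_fraction(boot, top, second) else NA_real_
  indis_12 <- (use_threshold && d_top < t_win) ||
              (use_bootstrap && flip_top > alpha)

  d_23 <- NA_real_
  flip_23 <- NA_real_
  indis_23 <- FALSE
  if (indis_12 && !is.na(third)) {
    d_23 <- unname(scores[ord[2L]] - scores[ord[3L]])
    flip_23 <- if (use_bootstrap) flip_fraction(boot, second, third) else NA_real_
    indis_23 <- (use_threshold && d_23 < t_win) ||
                (use_bootstrap && flip_23 > alpha)
  }

  kind <- if (indis_12 && indis_23) "Triple" else if (indis_12) "Dual" else "Single"
  components <- switch(kind,
    Single = top,
    Dual = c(top, second),
    Triple = c(top, second, third)
  )
  structure(list(
    sample_id = sample_id,
    kind = kind,
    components = components,
    label = components_to_label(components),
    d_top = d_top, d_23 = d_23,
    flip_top = flip_top, flip_23 = flip_23,
    threshold = t_win
  ), class = "dual_call")
}

#' @export
print.dual_call <- function(x, ...) {
  cat(x$label, " (", x$kind, "): d_top = ", signif(x$d_top, 4),
      ", threshold = ", signif(x$threshold, 4),
      if (is.finite(x$flip_top)) paste0(", flip = ", signif(x$flip_top, 4)),
      "\n", sep = "")
  invisible(x)
}

#' Dual-subtype classification of a whole cohort
#'
#' Two-pass orchestration: pass 1 scores every sample ([classify_cohort()])
#' and fits the per-subtype thresholds ([fit_difference_thresholds()]);
#' pass 2 bootstraps each sample ([bootstrap_scores()]) and applies
#' [classify_single_dual()]. Per-sample bootstrap seeds are derived from
#' `seed`, so a fixed seed reproduces the call table exactly.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param model A [signature_model()].
#' @param B Bootstrap replicates per sample.
#' @param alpha Flip-fraction cutoff.
#' @param seed Integer seed.
#' @param thresholds Optional precomputed [fit_difference_thresholds()]
#'   result; fitted on this cohort when `NULL`.
#' @param sample_subset Optional character vector of sample ids to bootstrap
#'   and call (thresholds are always fitted on the full cohort); defaults to
#'   all samples.
#' @inheritParams classify_single_dual
#' @return List with `calls` (data.frame: `sample_id`, `kind`, `label`,
#'   score columns, `d_top`, `flip_top`, `threshold_applied`), `thresholds`
#'   and `scores` (the pass-1 score table).
#' @export
classify_cohort_dual <- function(expr, model, B = 1000, alpha = 0.05, seed = 1,
                                 thresholds = NULL, sample_subset = NULL,
                                 use_threshold = TRUE, use_bootstrap = TRUE) {
  scores_table <- classify_cohort(expr, model)
  if (is.null(thresholds)) thresholds <- fit_difference_thresholds(scores_table)
  ids <- sample_subset %||% scores_table$sample_id
  missing <- setdiff(ids, scores_table$sample_id)
  if (length(missing)) {
    stop("sample(s) not in cohort: ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  S <- score_matrix(scores_table)
  calls <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    i <- match(id, scores_table$sample_id)
    boot <- if (use_bootstrap) {
      bootstrap_scores(expr[, id], model, B = B,
                       seed = (seed + i) %% .Machine$integer.max,
                       sample_id = id)
    } else NULL
    call <- tryCatch(
      classify_single_dual(S[i, ], boot, thresholds, alpha = alpha,
                           use_threshold = use_threshold,
                           use_bootstrap = use_bootstrap, sample_id = id),
      error = function(e) stop("sample '", id, "': ", conditionMessage(e))
    )
    calls[[k]] <- data.frame(
      sample_id = id, kind = call$kind, label = call$label,
      d_top = call$d_top, flip_top = call$flip_top,
      threshold_applied = call$threshold, stringsAsFactors = FALSE
    )
  }
  calls <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  if (is.null(calls)) {
    calls <- data.frame(sample_id = character(0), kind = character(0),
                        label = character(0), d_top = numeric(0),
                        flip_top = numeric(0), threshold_applied = numeric(0),
                        stringsAsFactors = FALSE)
  }
  sc <- scores_table[match(calls$sample_id, scores_table$sample_id),
                     grep("^score_", names(scores_table)), drop = FALSE]
  calls <- cbind(calls, sc, row.names = NULL)
  list(calls = calls, thresholds = thresholds, scores = scores_table)
}

#' Write a dual-call table as CSV
#'
#' @param calls The `calls` data.frame from [classify_cohort_dual()].
#' @param path Output path.
#' @export
write_dual_calls <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE)
  invisible(path)
}
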