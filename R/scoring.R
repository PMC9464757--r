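# Correlation-to-centroid scoring of sample profiles.

# Score one numeric profile segment against a centroid.
.class_score <- function(x, centroid, method) {
  if (length(x) < 2L) stop("signature must contain at least 2 genes for scoring")
  switch(method,
    pearson = {
      if (stats::sd(x) == 0 || stats::sd(centroid) == 0) {
        stop("undefined score: zero variance in profile or centroid restriction")
      }
      stats::cor(x, centroid)
    },
    spearman = {
      if (stats::sd(x) == 0 || stats::sd(centroid) == 0) {
        stop("undefined score: zero variance in profile or centroid restriction")
      }
      stats::cor(x, centroid, method = "spearman")
    },
    cosine = {
      den <- sqrt(sum(x^2) * sum(centroid^2))
      if (den == 0) stop("undefined score: zero-norm profile or centroid")
      sum(x * centroid) / den
    },
    stop("unknown scoring method '", method, "'")
  )
}

#' Score a single sample against every class centroid
#'
#' The score of a class is the Pearson correlation (by default) between the
#' sample profile restricted to that class's gene set and the class centroid.
#' The winning class attains the maximum score; exact ties are broken by the
#' model's class order.
#'
#' @param profile Named numeric vector of per-gene values covering every gene
#'   of every class signature.
#' @param model A [signature_model()].
#' @param method Scoring rule: `"pearson"` (default), `"spearman"` or
#'   `"cosine"`.
#' @param standardize If `TRUE`, profile and centroid restrictions are
#'   z-scored before scoring (off by default).
#' @return List with `scores` (named numeric in `[-1, 1]`), `winning_class`,
#'   `runner_up_class`, `d_top` (top minus second score, non-negative) and
#'   `d_range` (top minus lowest score, a diagnostic).
#' @export
score_sample <- function(profile, model, method = c("pearson", "spearman", "cosine"),
                         standardize = FALSE) {
  stopifnot(inherits(model, "signature_model"))
  method <- match.arg(method)
  if (is.null(names(profile))) stop("`profile` must be a named numeric vector")
  scores <- vapply(model$classes, function(cl) {
    sig <- model$signatures[[cl]]
    stop_if_missing_genes(sig$genes, names(profile), what = "profile")
    x <- as.numeric(profile[sig$genes])
    cent <- sig$centroid
    if (standardize) {
      x <- as.numeric(scale(x))
      cent <- as.numeric(scale(cent))
    }
    .class_score(x, cent, method)
  }, numeric(1))
  ord <- rank_classes(scores, model$classes)
  list(
    scores = scores,
    winning_class = model$classes[ord[1L]],
    runner_up_class = if (length(scores) >= 2L) model$classes[ord[2L]] else NA_character_,
    d_top = if (length(scores) >= 2L) unname(scores[ord[1L]] - scores[ord[2L]]) else NA_real_,
    d_range = unname(scores[ord[1L]] - scores[ord[length(ord)]])
  )
}

#' Standard (argmax) subtype call from a set of class scores
#'
#' @param scores Named numeric vector of class scores.
#' @param classes Class order used to break exact ties; defaults to the
#'   order of `scores`.
#' @return The winning class name.
#' @export
standard_classify <- function(scores, classes = names(scores)) {
  if (is.null(names(scores))) stop("`scores` must be named")
  if (!setequal(names(scores), classes)) stop("`scores` must cover all classes")
  classes[rank_classes(scores[classes], classes)[1L]]
}

#' Score and classify a whole cohort
#'
#' Vectorized application of [score_sample()] over the columns of an
#' expression matrix.
#'
#' @param expr Numeric genes-by-samples matrix with gene and sample names.
#' @param model A [signature_model()].
#' @inheritParams score_sample
#' @return data.frame with one row per sample: `sample_id`, one score column
#'   per class (`score_<class>`), `winning_class`, `runner_up_class`,
#'   `d_top`, `d_range`.
#' @export
classify_cohort <- function(expr, model, method = c("pearson", "spearman", "cosine"),
                            standardize = FALSE) {
  stopifnot(is.matrix(expr), inherits(model, "signature_model"))
  method <- match.arg(method)
  classes <- model$classes
  n <- ncol(expr)
  score_cols <- paste0("score_", classes)
  if (n == 0L) {
    out <- data.frame(sample_id = character(0), stringsAsFactors = FALSE)
    for (sc in score_cols) out[[sc]] <- numeric(0)
    out$winning_class <- character(0)
    out$runner_up_class <- character(0)
    out$d_top <- numeric(0)
    out$d_range <- numeric(0)
    return(out)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("`expr` needs gene row names and sample column names")
  }
  S <- matrix(NA_real_, nrow = n, ncol = length(classes),
              dimnames = list(colnames(expr), classes))
  for (cl in classes) {
    sig <- model$signatures[[cl]]
    stop_if_missing_genes(sig$genes, rownames(expr))
    sub <- expr[sig$genes, , drop = FALSE]
    cent <- sig$centroid
    if (standardize) {
      sub <- apply(sub, 2L, function(x) as.numeric(scale(x)))
      cent <- as.numeric(scale(cent))
    }
    if (method == "pearson") {
      sds <- apply(sub, 2L, stats::sd)
      if (any(sds == 0)) {
        stop("undefined score for sample(s) ",
             paste(utils::head(colnames(expr)[sds == 0], 5L), collapse = ", "),
             ": zero variance on the ", cl, " gene set")
      }
      S[, cl] <- as.vector(stats::cor(sub, cent))
    } else {
      S[, cl] <- apply(sub, 2L, .class_score, centroid = cent, method = method)
    }
  }
  idx <- seq_along(classes)
  ord <- t(apply(S, 1L, function(s) order(-s, idx)))
  top <- ord[, 1L]
  second <- if (length(classes) >= 2L) ord[, 2L] else NA_integer_
  out <- data.frame(sample_id = colnames(expr), stringsAsFactors = FALSE)
  for (k in idx) out[[score_cols[k]]] <- unname(S[, k])
  out$winning_class <- classes[top]
  out$runner_up_class <- if (length(classes) >= 2L) classes[second] else NA_character_
  out$d_top <- if (length(classes) >= 2L) {
    S[cbind(seq_len(n), top)] - S[cbind(seq_len(n), second)]
  } else NA_real_
  out$d_range <- S[cbind(seq_len(n), top)] - S[cbind(seq_len(n), ord[, length(classes)])]
  attr(out, "classes") <- classes
  out
}

# Extract the per-sample score matrix from a classify_cohort() data.frame.
score_matrix <- function(scores_table) {
  classes <- attr(scores_table, "classes") %||%
    sub("^score_", "", grep("^score_", names(scores_table), value = TRUE))
  S <- as.matrix(scores_table[, paste0("score_", classes), drop = FALSE])
  colnames(S) <- classes
  rownames(S) <- scores_table$sample_id
  S
}
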