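# Four-class TNBC re-classification (BLIA / BLIS / LAR / MES) over a shared
# 80-gene panel, reusing the centroid-correlation scoring core.

BURSTEIN_CLASSES <- c("BLIA", "BLIS", "LAR", "MES")

#' Construct a four-class TNBC centroid model
#'
#' All four classes (BLIA, BLIS, LAR, MES) share one gene panel; each class
#' has its own centroid over that panel. Published centroid values are not
#' shipped with the package — supply them via this constructor or
#' [read_signature_model()]; [synthetic_burstein_model()] provides a clearly
#' synthetic stand-in for testing.
#'
#' @param genes Character vector: the shared gene panel (classically 80
#'   genes).
#' @param centroids Named list or matrix (genes by class) of centroid
#'   vectors for exactly the classes BLIA, BLIS, LAR, MES.
#' @return A [signature_model()] with subclass `burstein_model`.
#' @export
burstein_model <- function(genes, centroids) {
  if (is.matrix(centroids)) {
    centroids <- stats::setNames(
      lapply(seq_len(ncol(centroids)), function(j) centroids[, j]),
      colnames(centroids)
    )
  }
  if (!setequal(names(centroids), BURSTEIN_CLASSES)) {
    stop("centroids must be named exactly ", paste(BURSTEIN_CLASSES, collapse = ", "))
  }
  sigs <- lapply(BURSTEIN_CLASSES, function(cl) {
    list(genes = genes, centroid = as.numeric(centroids[[cl]]))
  })
  model <- signature_model(stats::setNames(sigs, BURSTEIN_CLASSES))
  class(model) <- c("burstein_model", class(model))
  model
}

#' Synthetic four-class TNBC model for testing
#'
#' Draws four standard-normal centroids over a synthetic gene panel. This is
#' a stand-in for published centroids, usable only to exercise the classifier
#' mechanics.
#'
#' @param n_genes Panel size (default 80).
#' @param seed Integer seed.
#' @return A [burstein_model()].
#' @export
synthetic_burstein_model <- function(n_genes = 80, seed = 7) {
  set.seed(seed)
  genes <- sprintf("TNBC_g%03d", seq_len(n_genes))
  centroids <- stats::setNames(
    lapply(BURSTEIN_CLASSES, function(cl) stats::rnorm(n_genes)),
    BURSTEIN_CLASSES
  )
  burstein_model(genes, centroids)
}

#' Simulate a cohort clustered around the four TNBC centroids
#'
#' @param model A [burstein_model()].
#' @param n Number of samples; allocated over classes by largest-remainder
#'   rounding of `proportions`.
#' @param proportions Named class fractions (default equal).
#' @param noise_sd Gaussian noise SD around the class centroid.
#' @param seed Integer seed.
#' @return List with `expression` (genes-by-samples matrix) and `truth`
#'   (data.frame: `sample_id`, `class`).
#' @export
simulate_burstein_cohort <- function(model, n, proportions = NULL,
                                     noise_sd = 0.3, seed = 1) {
  stopifnot(inherits(model, "burstein_model"))
  proportions <- proportions %||%
    stats::setNames(rep(1 / 4, 4), BURSTEIN_CLASSES)
  counts <- allocate_counts(n, proportions[BURSTEIN_CLASSES])
  labels <- rep(BURSTEIN_CLASSES, counts)
  genes <- model$signatures[[1L]]$genes
  set.seed(seed)
  expr <- vapply(labels, function(cl) {
    model$signatures[[cl]]$centroid + stats::rnorm(length(genes), sd = noise_sd)
  }, numeric(length(genes)))
  expr <- matrix(expr, nrow = length(genes),
                 dimnames = list(genes, sprintf("T%05d", seq_len(n))))
  list(expression = expr,
       truth = data.frame(sample_id = colnames(expr), class = labels,
                          stringsAsFactors = FALSE))
}

#' Classify samples into the four TNBC subtypes
#'
#' Argmax centroid correlation over the shared panel; exact ties are broken
#' in the order BLIA, BLIS, LAR, MES. Identical to the generic scoring core
#' applied to a shared-panel four-class model.
#'
#' @param expr Genes-by-samples matrix containing the full panel.
#' @param model A [burstein_model()].
#' @return data.frame: `sample_id`, `class`, plus the four score columns.
#' @export
classify_burstein <- function(expr, model) {
  stopifnot(inherits(model, "burstein_model"))
  st <- classify_cohort(expr, model)
  out <- data.frame(sample_id = st$sample_id, class = st$winning_class,
                    stringsAsFactors = FALSE)
  cbind(out, st[, grep("^score_", names(st)), drop = FALSE], row.names = NULL)
}

#' Cross-tabulate TNBC subtype against single/dual classification
#'
#' @param burstein_calls data.frame from [classify_burstein()] (or a
#'   character vector of its `class` column).
#' @param dual_calls data.frame from [classify_cohort_dual()]`$calls` (or a
#'   character vector of labels/kinds), aligned by `sample_id` when both are
#'   data.frames.
#' @param dual_by Which dual annotation forms the rows: `"label"` (default)
#'   or `"kind"`.
#' @return A contingency table (rows: dual groups, columns: BLIA, BLIS, LAR,
#'   MES) suitable for [chi_square_test()].
#' @export
crosstab_burstein_vs_dual <- function(burstein_calls, dual_calls,
                                      dual_by = c("label", "kind")) {
  dual_by <- match.arg(dual_by)
  if (is.data.frame(burstein_calls)) {
    b <- burstein_calls$class
    b_id <- burstein_calls$sample_id
  } else {
    b <- burstein_calls
    b_id <- NULL
  }
  if (is.data.frame(dual_calls)) {
    d <- dual_calls[[dual_by]]
    if (!is.null(b_id) && !is.null(dual_calls$sample_id)) {
      d <- d[match(b_id, dual_calls$sample_id)]
    }
  } else {
    d <- dual_calls
  }
  if (length(b) != length(d) || anyNA(d)) {
    stop("TNBC calls and dual calls do not align sample-for-sample")
  }
  if (!all(b %in% BURSTEIN_CLASSES)) {
    stop("unexpected TNBC class labels: ",
         paste(setdiff(unique(b), BURSTEIN_CLASSES), collapse = ", "))
  }
  table(dual = d, burstein = factor(b, levels = BURSTEIN_CLASSES))
}
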