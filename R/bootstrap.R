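# Per-sample gene bootstrap of subtype scores.

#' Bootstrap the class scores of one sample by resampling signature genes
#'
#' Each replicate resamples, independently for every class, that class's
#' genes with replacement (keeping the signature size) and recomputes the
#' correlation score on the resampled gene multiset. Replicates in which a
#' class's resampled profile or centroid restriction has zero variance are
#' marked invalid for that class; a replicate is usable for a class pair when
#' both classes are valid.
#'
#' @param profile Named numeric per-gene vector (one sample).
#' @param model A [signature_model()].
#' @param B Number of bootstrap replicates (at least 1).
#' @param seed Integer RNG seed; classes are resampled in model order from a
#'   single stream, so a fixed seed reproduces the replicates exactly.
#' @param max_invalid Error if the fraction of replicates invalid for any
#'   class exceeds this bound (default 0.5). Tiny signatures (2 genes)
#'   degenerate in half of their resamples; raise the bound to study them.
#' @param sample_id Optional identifier carried into the result.
#' @return Object of class `bootstrap_scores`: list with `sample_id`, `B`,
#'   `scores` (B-by-class matrix, `NA` where invalid), `observed` (the
#'   non-resampled scores) and `invalid_fraction` per class.
#' @export
bootstrap_scores <- function(profile, model, B = 1000, seed = 1,
                             max_invalid = 0.5, sample_id = NA_character_) {
  stopifnot(inherits(model, "signature_model"))
  if (B < 1) stop("`B` must be at least 1")
  obs <- score_sample(profile, model)
  set.seed(seed)
  S <- matrix(NA_real_, nrow = B, ncol = length(model$classes),
              dimnames = list(NULL, model$classes))
  for (cl in model$classes) {
    sig <- model$signatures[[cl]]
    m <- length(sig$genes)
    idx <- matrix(sample.int(m, B * m, replace = TRUE), nrow = B, ncol = m)
    P <- matrix(profile[sig$genes][idx], nrow = B, ncol = m)
    C <- matrix(sig$centroid[idx], nrow = B, ncol = m)
    Pc <- P - rowMeans(P)
    Cc <- C - rowMeans(C)
    den <- sqrt(rowSums(Pc^2) * rowSums(Cc^2))
    r <- rowSums(Pc * Cc) / den
    r[den == 0] <- NA_real_
    S[, cl] <- r
  }
  invalid <- colMeans(is.na(S))
  if (any(invalid > max_invalid)) {
    bad <- names(invalid)[invalid > max_invalid]
    stop("bootstrap failure: more than ", round(100 * max_invalid),
         "% invalid replicates for class(es) ", paste(bad, collapse = ", "))
  }
  structure(list(sample_id = sample_id, B = as.integer(B), scores = S,
                 observed = obs$scores, invalid_fraction = invalid),
            class = "bootstrap_scores")
}

#' Flip fraction between two classes
#'
#' Fraction of (pairwise valid) bootstrap replicates in which `class_j`'s
#' score meets or exceeds `class_i`'s. Ties count toward a flip, so
#' `flip_fraction(b, i, j) + flip_fraction(b, j, i) >= 1`.
#'
#' @param boot A [bootstrap_scores()] object.
#' @param class_i,class_j Class names (typically the observed top and
#'   runner-up).
#' @return A fraction in `[0, 1]`.
#' @export
flip_fraction <- function(boot, class_i, class_j) {
  stopifnot(inherits(boot, "bootstrap_scores"))
  si <- boot$scores[, class_i]
  sj <- boot$scores[, class_j]
  ok <- is.finite(si) & is.finite(sj)
  if (!any(ok)) stop("no jointly valid replicates for classes ",
                     class_i, " and ", class_j)
  mean(sj[ok] >= si[ok])
}

#' @export
print.bootstrap_scores <- function(x, ...) {
  cat("Gene-bootstrap scores", if (!is.na(x$sample_id)) paste0("for ", x$sample_id),
      ": B =", x$B, "\n")
  print(round(rbind(observed = x$observed,
                    boot_mean = colMeans(x$scores, na.rm = TRUE),
                    boot_sd = apply(x$scores, 2L, stats::sd, na.rm = TRUE),
                    invalid = x$invalid_fraction), 4))
  invisible(x)
}
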