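#' Construct a signature model
#'
#' A signature model holds, for an ordered set of molecular classes, the gene
#' list of each class's signature and the class centroid over those genes
#' (log2 scale). Samples are scored by correlating their profile, restricted
#' to a class's genes, against that class's centroid.
#'
#' @param signatures Named list, one entry per class in the desired
#'   (tie-break) order. Each entry is a list with elements `genes`
#'   (character) and `centroid` (numeric, same length).
#' @return An object of class `signature_model`.
#' @export
#' @examples
#' m <- signature_model(list(
#'   A = list(genes = c("g1", "g2", "g3"), centroid = c(1, 0, -1)),
#'   B = list(genes = c("g4", "g5", "g6"), centroid = c(0, 2, 1))
#' ))
signature_model <- function(signatures) {
  if (!is.list(signatures) || is.null(names(signatures)) ||
      any(!nzchar(names(signatures)))) {
    stop("`signatures` must be a named list of classes")
  }
  for (cl in names(signatures)) {
    sig <- signatures[[cl]]
    if (!is.character(sig$genes) || !is.numeric(sig$centroid)) {
      stop("class '", cl, "': needs character `genes` and numeric `centroid`")
    }
    if (anyDuplicated(sig$genes)) {
      stop("class '", cl, "': duplicated gene identifiers")
    }
    if (length(sig$genes) != length(sig$centroid)) {
      stop("class '", cl, "': centroid length does not match gene list")
    }
    if (length(sig$genes) > 1L && stats::sd(sig$centroid) == 0) {
      stop("class '", cl, "': centroid has zero variance")
    }
    signatures[[cl]] <- list(genes = as.character(sig$genes),
                             centroid = as.numeric(sig$centroid))
  }
  structure(list(classes = names(signatures), signatures = signatures),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  sizes <- vapply(x$signatures, function(s) length(s$genes), integer(1))
  cat("Signature model:", length(x$classes), "classes\n")
  for (cl in x$classes) cat("  ", cl, ": ", sizes[[cl]], " genes\n", sep = "")
  invisible(x)
}

#' Train per-class centroids from labeled expression data
#'
#' The centroid of a class is the per-gene mean over the samples labeled with
#' that class, restricted to the class's own gene set.
#'
#' @param expr Numeric genes-by-samples matrix with gene row names.
#' @param labels Character vector of class labels, one per column of `expr`.
#' @param gene_sets Named list mapping each class to its gene identifiers;
#'   the class order of the resulting model follows this list.
#' @return A [signature_model()].
#' @export
train_centroids <- function(expr, labels, gene_sets) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (length(labels) != ncol(expr)) {
    stop("`labels` must have one entry per sample column")
  }
  signatures <- list()
  for (cl in names(gene_sets)) {
    genes <- gene_sets[[cl]]
    stop_if_missing_genes(genes, rownames(expr))
    members <- which(labels == cl)
    if (length(members) < 2L) {
      stop("class '", cl, "' has fewer than 2 labeled samples (", length(members), ")")
    }
    signatures[[cl]] <- list(
      genes = genes,
      centroid = rowMeans(expr[genes, members, drop = FALSE])
    )
  }
  signature_model(signatures)
}

#' Read / write a signature model as JSON
#'
#' Schema: `{"classes": [...], "signatures": {class: {"genes": [...],
#' "centroid": [...]}}}`.
#'
#' @param path File path.
#' @return `read_signature_model()` returns a [signature_model()];
#'   `write_signature_model()` returns `path` invisibly.
#' @export
read_signature_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$classes) || is.null(obj$signatures)) {
    stop("'", path, "' is not a signature model JSON (classes/signatures)")
  }
  sigs <- lapply(obj$signatures, function(s) {
    list(genes = as.character(s$genes), centroid = as.numeric(s$centroid))
  })
  signature_model(sigs[as.character(obj$classes)])
}

#' @rdname read_signature_model
#' @param model A [signature_model()].
#' @export
write_signature_model <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  jsonlite::write_json(
    list(classes = model$classes, signatures = model$signatures),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
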