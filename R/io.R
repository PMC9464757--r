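# Plain-text readers/writers: expression TSV, clinical CSV, truth CSV.

#' Write / read a genes-by-samples expression matrix as TSV
#'
#' The file has a `gene_id` first column and one column per sample. Writing
#' then reading reproduces identifiers exactly and values to better than
#' 1e-12.
#'
#' @param expr Numeric matrix with gene row names and sample column names.
#' @param path File path.
#' @return `read_expression_matrix()` returns the matrix;
#'   `write_expression_matrix()` returns `path` invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(gene_id = rownames(expr),
                   format(expr, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          fill = FALSE)
  if (names(df)[1L] != "gene_id") {
    stop("'", path, "': first column must be 'gene_id'")
  }
  genes <- as.character(df$gene_id)
  if (anyDuplicated(genes)) {
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  samples <- names(df)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
      stop("non-numeric expression value in column '", samples[j],
           "' (data line ", bad, ")")
    }
  }
  m <- as.matrix(vals)
  dimnames(m) <- list(genes, samples)
  m
}

CLINICAL_COLUMNS <- c("sample_id", "er_pct", "pr_pct", "ki67_pct", "her2_ihc",
                      "her2_fish", "stage", "grade", "therapy", "pcr")

#' Write / read a clinical annotation table as CSV
#'
#' Schema: `sample_id, er_pct, pr_pct, ki67_pct, her2_ihc, her2_fish, stage,
#' grade, therapy, pcr`. Percentages are validated into `[0, 100]`, HER2
#' IHC/FISH against their factor levels and `pcr` as 0/1.
#'
#' @param clinical data.frame following the schema.
#' @param path File path.
#' @return `read_clinical_table()` returns the validated data.frame.
#' @export
write_clinical_table <- function(clinical, path) {
  missing <- setdiff(CLINICAL_COLUMNS, names(clinical))
  if (length(missing)) stop("clinical table lacks column(s): ",
                            paste(missing, collapse = ", "))
  utils::write.csv(clinical[, CLINICAL_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_clinical_table
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(missing)) stop("'", path, "' lacks column(s): ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  for (col in c("er_pct", "pr_pct", "ki67_pct")) {
    x <- df[[col]]
    bad <- which(is.finite(x) & (x < 0 | x > 100))
    if (length(bad)) {
      stop("'", col, "' out of [0, 100] for sample ", df$sample_id[bad[1L]],
           " (value ", x[bad[1L]], ")")
    }
  }
  df$her2_ihc <- as.character(df$her2_ihc)
  df$her2_fish <- as.character(df$her2_fish)
  derive_her2_status(df$her2_ihc, df$her2_fish)  # validates the levels
  if (!all(df$pcr %in% c(0L, 1L, NA))) stop("`pcr` must be binary 0/1 or missing")
  df
}

#' Write / read a truth table as CSV
#'
#' @param truth data.frame from [generate_expression_cohort()].
#' @param path File path.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
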