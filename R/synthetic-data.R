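#' Configuration for the synthetic cohort generator
#'
#' The generator emulates a log-ratio expression cohort with three dominant
#' subtype programs (Luminal/Basal/HER2 by default). Each sample activates
#' one, two or three programs; active signature genes are shifted up by
#' `activation_effect` (times `dual_attenuation` when two or more programs
#' are co-active), inactive signature genes are repressed by
#' `repression_effect`, and background genes are pure noise. Per-gene shifts
#' are heterogeneous (loadings spanning 0.25-1.75 of the effect, mean exactly
#' 1) so that class centroids carry usable gene-level contrast.
#'
#' @param n_samples Positive integer cohort size.
#' @param class_proportions Named fractions over the classes, summing to 1.
#' @param dual_fraction,triple_fraction Fractions of samples with two / three
#'   co-active programs; their sum must be at most 1.
#' @param signature_sizes Named integer gene counts per class signature.
#' @param n_background_genes Number of pure-noise genes.
#' @param activation_effect Mean log2 shift of an active signature.
#' @param dual_attenuation Scaling in (0, 1] applied to each active program's
#'   shift when at least two programs are co-active.
#' @param repression_effect Mean downward log2 shift of inactive signatures;
#'   defaults to `activation_effect` (mirrored on/off states, as on
#'   reference-based log-ratio platforms).
#' @param noise_sd Gaussian noise standard deviation (log2 scale); may be 0
#'   for the noise-free limit.
#' @param seed Integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples,
                       class_proportions = c(Luminal = 0.85, Basal = 0.10, HER2 = 0.05),
                       dual_fraction = 0.05,
                       triple_fraction = 0.003,
                       signature_sizes = c(Luminal = 58, Basal = 28, HER2 = 4),
                       n_background_genes = 100,
                       activation_effect = 2,
                       dual_attenuation = 0.7,
                       repression_effect = NULL,
                       noise_sd = 0.3,
                       seed = 1) {
  if (length(n_samples) != 1L || !is.finite(n_samples) || n_samples != round(n_samples)) {
    stop("`n_samples` must be a single integer")
  }
  if (n_samples < 1L) stop("empty cohort: `n_samples` must be at least 1")
  if (is.null(names(class_proportions)) ||
      abs(sum(class_proportions) - 1) > 1e-9 || any(class_proportions < 0)) {
    stop("`class_proportions` must be named, non-negative and sum to 1")
  }
  if (dual_fraction < 0 || triple_fraction < 0 ||
      dual_fraction + triple_fraction > 1) {
    stop("`dual_fraction` + `triple_fraction` must lie in [0, 1]")
  }
  if (!setequal(names(signature_sizes), names(class_proportions))) {
    stop("`signature_sizes` must name the same classes as `class_proportions`")
  }
  if (any(signature_sizes < 1)) stop("signature sizes must be positive")
  if (n_background_genes < 0) stop("`n_background_genes` must be non-negative")
  if (activation_effect <= 0) stop("`activation_effect` must be positive")
  if (dual_attenuation <= 0 || dual_attenuation > 1) {
    stop("`dual_attenuation` must be in (0, 1]")
  }
  repression_effect <- repression_effect %||% activation_effect
  if (repression_effect < 0) stop("`repression_effect` must be non-negative")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(list(
    n_samples = as.integer(n_samples),
    class_proportions = class_proportions[names(class_proportions)],
    dual_fraction = dual_fraction,
    triple_fraction = triple_fraction,
    signature_sizes = signature_sizes[names(class_proportions)],
    n_background_genes = as.integer(n_background_genes),
    activation_effect = activation_effect,
    dual_attenuation = dual_attenuation,
    repression_effect = repression_effect,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Signature gene identifiers implied by a simulation configuration
#'
#' @param config A [sim_config()].
#' @return Named list mapping each class to its gene identifiers.
#' @export
signature_gene_sets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mapply(function(cl, m) sprintf("%s_g%03d", cl, seq_len(m)),
         names(config$signature_sizes), config$signature_sizes,
         SIMPLIFY = FALSE)
}

# Heterogeneous per-gene activation loadings; mean is exactly 1.
signature_loadings <- function(m) {
  if (m == 1L) return(1)
  seq(0.25, 1.75, length.out = m)
}

# Deterministic composition of the cohort: list of component vectors,
# canonical class order within each sample.
plan_components <- function(config) {
  cls <- names(config$class_proportions)
  n <- config$n_samples
  n_dual <- as.integer(round(n * config$dual_fraction))
  n_triple <- as.integer(round(n * config$triple_fraction))
  n_single <- n - n_dual - n_triple
  singles <- allocate_counts(n_single, config$class_proportions)
  comp <- list()
  for (cl in cls) comp <- c(comp, rep(list(cl), singles[[cl]]))
  if (length(cls) >= 2L) {
    pairs <- utils::combn(cls, 2L, simplify = FALSE)
    pw <- vapply(pairs, function(p) prod(config$class_proportions[p]), numeric(1))
    duals <- allocate_counts(n_dual, pw)
    for (k in seq_along(pairs)) comp <- c(comp, rep(list(pairs[[k]]), duals[[k]]))
  } else if (n_dual > 0L) {
    stop("dual samples require at least 2 classes")
  }
  if (n_triple > 0L) {
    if (length(cls) < 3L) stop("triple samples require at least 3 classes")
    comp <- c(comp, rep(list(cls[1:3]), n_triple))
  }
  comp
}

# Map planted components to the clinical HR/HER2 subtype stratum.
components_to_clinical <- function(components) {
  has <- function(cl) cl %in% components
  hr <- if (has("Luminal")) "HR+" else "HR-"
  her2 <- if (has("HER2")) "HER2+" else "HER2-"
  # Basal-only samples are triple negative by construction
  paste0(hr, her2)
}

components_to_label <- function(components) {
  if (length(components) == 1L) paste0(components, "-single-type")
  else paste0(paste(components, collapse = "-"), "-type")
}

#' Generate a synthetic expression cohort with planted single/dual structure
#'
#' Sample counts per label kind and per class composition are allocated
#' deterministically (largest-remainder rounding); randomness is confined to
#' the Gaussian expression noise. The same seed yields bit-identical output.
#'
#' @param config A [sim_config()].
#' @return List with elements `expression` (genes-by-samples numeric matrix),
#'   `truth` (data.frame: `sample_id`, `kind` in Single/Dual/Triple,
#'   `components`, `label`, `clinical_subtype`), `gene_sets`, and `config`.
#' @export
#' @examples
#' cohort <- generate_expression_cohort(sim_config(n_samples = 50, seed = 7))
#' table(cohort$truth$kind)
generate_expression_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  comp <- plan_components(config)
  n <- config$n_samples
  gene_sets <- signature_gene_sets(config)
  bg <- if (config$n_background_genes > 0L) {
    sprintf("BG_g%04d", seq_len(config$n_background_genes))
  } else character(0)
  genes <- c(unlist(gene_sets, use.names = FALSE), bg)
  samples <- sprintf("S%05d", seq_len(n))

  set.seed(config$seed)
  expr <- matrix(stats::rnorm(length(genes) * n, sd = config$noise_sd),
                 nrow = length(genes), ncol = n,
                 dimnames = list(genes, samples))
  loads <- lapply(config$signature_sizes, signature_loadings)
  for (i in seq_len(n)) {
    atten <- if (length(comp[[i]]) >= 2L) config$dual_attenuation else 1
    for (cl in names(gene_sets)) {
      shift <- if (cl %in% comp[[i]]) {
        loads[[cl]] * config$activation_effect * atten
      } else {
        -loads[[cl]] * config$repression_effect
      }
      expr[gene_sets[[cl]], i] <- expr[gene_sets[[cl]], i] + shift
    }
  }

  kind <- c("Single", "Dual", "Triple")[lengths(comp)]
  truth <- data.frame(
    sample_id = samples,
    kind = kind,
    components = vapply(comp, paste, character(1), collapse = "+"),
    label = vapply(comp, components_to_label, character(1)),
    clinical_subtype = vapply(comp, components_to_clinical, character(1)),
    stringsAsFactors = FALSE
  )
  list(expression = expr, truth = truth, gene_sets = gene_sets, config = config)
}

#' Generate clinical annotations coupled to the planted molecular classes
#'
#' ER positivity is highest in Luminal-single samples, intermediate in duals
#' with a Luminal component and below 1% in HR- samples; Ki-67 means are
#' ordered Luminal-single < dual < Basal/HER2-single; HER2 IHC/FISH agree
#' with the assigned clinical subtype. HER2+ samples are assigned to the
#' trastuzumab-containing therapy arm.
#'
#' @param truth Truth table from [generate_expression_cohort()].
#' @param config The matching [sim_config()]; its seed (offset by 1) drives
#'   the clinical draws.
#' @return data.frame with columns `sample_id`, `er_pct`, `pr_pct`,
#'   `ki67_pct`, `her2_ihc`, `her2_fish`, `stage`, `grade`, `therapy`, `pcr`
#'   (`NA`; see [generate_pcr_outcomes()]).
#' @export
generate_clinical_annotations <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(truth)
  empty <- data.frame(
    sample_id = character(0), er_pct = numeric(0), pr_pct = numeric(0),
    ki67_pct = numeric(0), her2_ihc = character(0), her2_fish = character(0),
    stage = integer(0), grade = integer(0), therapy = character(0),
    pcr = integer(0), stringsAsFactors = FALSE
  )
  if (n == 0L) return(empty)
  if (is.null(truth$components) || is.null(truth$clinical_subtype)) {
    stop("`truth` must carry `components` and `clinical_subtype` columns")
  }
  set.seed(config$seed + 1L)
  comp <- strsplit(truth$components, "+", fixed = TRUE)
  hr_pos <- grepl("^HR\\+", truth$clinical_subtype)
  her2_pos <- grepl("HER2\\+$", truth$clinical_subtype)
  has_lum <- vapply(comp, function(x) "Luminal" %in% x, logical(1))
  kind <- truth$kind

  er_mean <- ifelse(kind == "Single" & has_lum, 85, 60)
  er <- ifelse(hr_pos,
               clip(stats::rnorm(n, er_mean, ifelse(kind == "Single", 8, 15)), 1, 100),
               stats::runif(n, 0, 0.9))
  pr <- ifelse(hr_pos,
               clip(stats::rnorm(n, er * 0.7, 15), 0, 100),
               stats::runif(n, 0, 0.9))

  first <- vapply(comp, `[`, character(1), 1L)
  ki_mean <- rep(40, n)                      # duals / triples: intermediate
  ki_mean[kind == "Single" & first == "Luminal"] <- 15
  ki_mean[kind == "Single" & first == "Basal"] <- 70
  ki_mean[kind == "Single" & first == "HER2"] <- 65
  ki67 <- clip(stats::rnorm(n, ki_mean, 12), 0, 100)

  ihc <- character(n)
  fish <- rep(NA_character_, n)
  u <- stats::runif(n)
  ihc[her2_pos] <- ifelse(u[her2_pos] < 0.75, "3+", "2+")
  fish[her2_pos & ihc == "2+"] <- "amplified"
  ihc[!her2_pos] <- c("0", "1+", "2+")[findInterval(u[!her2_pos], c(0.45, 0.90)) + 1L]
  fish[!her2_pos & ihc == "2+"] <- "non-amplified"

  data.frame(
    sample_id = truth$sample_id,
    er_pct = er,
    pr_pct = pr,
    ki67_pct = ki67,
    her2_ihc = ihc,
    her2_fish = fish,
    stage = sample.int(3L, n, replace = TRUE, prob = c(0.35, 0.45, 0.20)),
    grade = sample.int(3L, n, replace = TRUE, prob = c(0.20, 0.50, 0.30)),
    therapy = ifelse(her2_pos, "CT+T", "CT"),
    pcr = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Simulate pathological complete response outcomes per subtype group
#'
#' Each sample's outcome is Bernoulli with the rate of its group (the truth
#' label, e.g. `"HER2-single-type"`).
#'
#' @param truth Truth table with `sample_id` and `label` columns.
#' @param rates Named probabilities in `[0, 1]`; every label present in
#'   `truth` must have a rate.
#' @param seed Integer RNG seed.
#' @return data.frame with columns `sample_id`, `label`, `pcr` (0/1).
#' @export
generate_pcr_outcomes <- function(truth, rates, seed = 1) {
  if (nrow(truth) == 0L) {
    return(data.frame(sample_id = character(0), label = character(0),
                      pcr = integer(0), stringsAsFactors = FALSE))
  }
  missing <- setdiff(unique(truth$label), names(rates))
  if (length(missing)) {
    stop("no pCR rate configured for group(s): ", paste(missing, collapse = ", "))
  }
  r <- rates[truth$label]
  if (any(r < 0 | r > 1)) stop("pCR rates must lie in [0, 1]")
  set.seed(seed)
  data.frame(
    sample_id = truth$sample_id,
    label = truth$label,
    pcr = stats::rbinom(nrow(truth), 1L, r),
    stringsAsFactors = FALSE
  )
}
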