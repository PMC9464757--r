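# Shared fixtures, all built in code.

# Small 3-class toy model with hand-picked centroids (distinct variances).
toy_model <- function() {
  signature_model(list(
    Luminal = list(genes = paste0("L", 1:5), centroid = c(2.0, 1.2, 0.4, 1.6, 0.8)),
    Basal = list(genes = paste0("B", 1:4), centroid = c(0.5, 1.5, 2.5, 1.0)),
    HER2 = list(genes = paste0("H", 1:3), centroid = c(0.3, 1.1, 2.2))
  ))
}

toy_genes <- function(model = toy_model()) {
  unlist(lapply(model$signatures, `[[`, "genes"), use.names = FALSE)
}

# A profile that matches one class's centroid on its genes and anti-matches
# the others (so the argmax is unambiguous).
toy_profile <- function(match_class = "Luminal", model = toy_model()) {
  vals <- unlist(lapply(names(model$signatures), function(cl) {
    cent <- model$signatures[[cl]]$centroid
    if (cl == match_class) cent else max(cent) - cent
  }), use.names = FALSE)
  stats::setNames(vals, toy_genes(model))
}

# Simulated cohort + trained model + score table, shared across tests.
make_scored_cohort <- function(n = 400, seed = 42, ...) {
  cfg <- sim_config(n_samples = n, seed = seed, ...)
  cohort <- generate_expression_cohort(cfg)
  model <- train_centroids(
    cohort$expression,
    ifelse(cohort$truth$kind == "Single", cohort$truth$components, NA_character_),
    cohort$gene_sets
  )
  scores <- classify_cohort(cohort$expression, model)
  list(config = cfg, cohort = cohort, model = model, scores = scores)
}

# Hand-built bootstrap distribution with constant per-class scores.
fake_boot <- function(scores, B = 100) {
  S <- matrix(rep(scores, each = B), nrow = B,
              dimnames = list(NULL, names(scores)))
  structure(list(sample_id = "fake", B = B, scores = S, observed = scores,
                 invalid_fraction = stats::setNames(rep(0, length(scores)),
                                                    names(scores))),
            class = "bootstrap_scores")
}

# Hand-built threshold set for a list of class -> threshold values.
fake_thresholds <- function(thresholds) {
  out <- data.frame(class = names(thresholds), n = 100L, pooled = FALSE,
                    threshold = unname(unlist(thresholds)),
                    decision = "quantile-fallback", stringsAsFactors = FALSE)
  class(out) <- c("threshold_set", "data.frame")
  out
}

# First component (standard argmax class) of a truth `components` string.
first_component <- function(components) {
  vapply(strsplit(components, "+", fixed = TRUE), `[`, character(1), 1L)
}

# Expected per-gene activation loadings of the generator (documented scheme).
expected_loadings <- function(m) if (m == 1) 1 else seq(0.25, 1.75, length.out = m)
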