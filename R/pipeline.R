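# Configuration-driven orchestration of the full analysis.

#' Default pipeline configuration
#'
#' @return Nested list with every documented setting: `simulate`, `seed`,
#'   `sim` (forwarded to [sim_config()]), `paths` (input files when
#'   `simulate` is `FALSE`), `dual` (`B`, `alpha`, `use_threshold`,
#'   `use_bootstrap`), `prevalence` (`enabled`, `n_iter`, `subset_size`,
#'   `weights`), `burstein` (`synthetic_demo`, `n`, `noise_sd`, `model`),
#'   `pcr_rates` and `save_expression`.
#' @export
default_pipeline_config <- function() {
  list(
    simulate = TRUE,
    seed = 1L,
    sim = list(n_samples = 2000L),
    paths = list(expression = NULL, clinical = NULL, model = NULL),
    dual = list(B = 1000L, alpha = 0.05, use_threshold = TRUE, use_bootstrap = TRUE),
    prevalence = list(enabled = TRUE, n_iter = 1000L, subset_size = 10000L,
                      weights = NULL),
    burstein = list(synthetic_demo = TRUE, n = 400L, noise_sd = 0.3, model = NULL),
    # pCR rates per planted group; the HER2-single vs Luminal-HER2 contrast
    # is the headline treatment-response difference the cohort emulates.
    pcr_rates = c("Luminal-single-type" = 0.15, "Basal-single-type" = 0.35,
                  "HER2-single-type" = 0.613, "Luminal-Basal-type" = 0.25,
                  "Luminal-HER2-type" = 0.238, "Basal-HER2-type" = 0.30,
                  "Luminal-Basal-HER2-type" = 0.30),
    save_expression = FALSE
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown top-level keys and missing input files are reported before any
#' computation starts.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param config Partial configuration list; defaults fill the rest.
#' @export
validate_pipeline_config <- function(config = list()) {
  base <- default_pipeline_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- merge_config(base, config)
  if (!isTRUE(cfg$simulate) && !isFALSE(cfg$simulate)) {
    stop("`simulate` must be TRUE or FALSE")
  }
  if (!cfg$simulate) {
    for (p in c("expression", "model")) {
      if (is.null(cfg$paths[[p]])) stop("`paths$", p, "` required when simulate = FALSE")
      if (!file.exists(cfg$paths[[p]])) stop("input file not found: ", cfg$paths[[p]])
    }
    if (!is.null(cfg$paths$clinical) && !file.exists(cfg$paths$clinical)) {
      stop("input file not found: ", cfg$paths$clinical)
    }
  }
  if (cfg$dual$B < 1) stop("`dual$B` must be at least 1")
  if (cfg$dual$alpha <= 0 || cfg$dual$alpha >= 1) stop("`dual$alpha` must be in (0, 1)")
  cfg
}

# Reorder the components of a call label into canonical class order, so that
# e.g. Basal-Luminal-type and Luminal-Basal-type form one analysis group.
canonical_group <- function(label, classes) {
  single <- grepl("-single-type$", label)
  out <- label
  comp <- strsplit(sub("-type$", "", label[!single]), "-", fixed = TRUE)
  out[!single] <- vapply(comp, function(x) {
    paste0(paste(classes[sort(match(x, classes))], collapse = "-"), "-type")
  }, character(1))
  out
}

stage_msg <- function(name, t0) {
  message(sprintf("[%s] done in %.2fs", name, as.numeric(Sys.time() - t0, units = "secs")))
}

#' Run the full dual-subtype analysis pipeline
#'
#' Stages: simulate (or ingest) -> train/read signature model -> score ->
#' threshold fitting and single/dual/triple calling -> mixture prevalence ->
#' TNBC re-classification -> cohort statistics -> summary. Deterministic
#' given the configuration (report files contain no timestamps); stage
#' timings go to the console log.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML/JSON file.
#' @param out_dir Optional directory for the report bundle (`truth.csv`,
#'   `clinical.csv`, `calls.csv`, `thresholds.json`, `prevalence.json`,
#'   `stats.json`, `summary.json`).
#' @return List with `calls`, `thresholds`, `scores`, `prevalence`,
#'   `burstein`, `stats`, `summary`, `truth`, `clinical`, `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else
    validate_pipeline_config(config)

  truth <- NULL
  clinical <- NULL
  t0 <- Sys.time()
  if (cfg$simulate) {
    sim_cfg <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
    cohort <- generate_expression_cohort(sim_cfg)
    expr <- cohort$expression
    truth <- cohort$truth
    clinical <- generate_clinical_annotations(truth, sim_cfg)
    pcr <- generate_pcr_outcomes(truth, cfg$pcr_rates, seed = cfg$seed + 2L)
    clinical$pcr <- pcr$pcr[match(clinical$sample_id, pcr$sample_id)]
    model <- train_centroids(
      expr,
      ifelse(truth$kind == "Single", truth$components, NA_character_),
      cohort$gene_sets
    )
    stage_msg("simulate", t0)
  } else {
    expr <- read_expression_matrix(cfg$paths$expression)
    model <- read_signature_model(cfg$paths$model)
    if (!is.null(cfg$paths$clinical)) clinical <- read_clinical_table(cfg$paths$clinical)
    stage_msg("ingest", t0)
  }

  t0 <- Sys.time()
  res <- classify_cohort_dual(expr, model, B = cfg$dual$B, alpha = cfg$dual$alpha,
                              seed = cfg$seed,
                              use_threshold = cfg$dual$use_threshold,
                              use_bootstrap = cfg$dual$use_bootstrap)
  calls <- res$calls
  calls$group <- canonical_group(calls$label, model$classes)
  stage_msg("classify", t0)

  prevalence <- NULL
  if (isTRUE(cfg$prevalence$enabled) && !is.null(clinical)) {
    t0 <- Sys.time()
    subtype <- if (!is.null(truth)) truth$clinical_subtype else {
      derive_clinical_subtype(
        derive_hr_status(clinical$er_pct, clinical$pr_pct),
        derive_her2_status(clinical$her2_ihc, clinical$her2_fish)
      )
    }
    mix <- if (is.null(cfg$prevalence$weights)) mixture_spec() else
      mixture_spec(unlist(cfg$prevalence$weights))
    # a cohort can lack a stratum the mixture requires (e.g. no HER2+ duals
    # or singles at all); the stage is then skipped, not fatal
    prevalence <- tryCatch(
      estimate_mixture_prevalence(
        calls$kind, subtype, mix, n_iter = cfg$prevalence$n_iter,
        subset_size = cfg$prevalence$subset_size, seed = cfg$seed + 3L
      ),
      error = function(e) {
        if (!grepl("stratification error", conditionMessage(e))) {
          stop("stage prevalence: ", conditionMessage(e))
        }
        message("[prevalence] skipped: ", conditionMessage(e))
        NULL
      }
    )
    stage_msg("prevalence", t0)
  }

  burstein <- NULL
  if (!is.null(cfg$burstein$model) || (cfg$simulate && isTRUE(cfg$burstein$synthetic_demo))) {
    t0 <- Sys.time()
    burstein <- run_burstein_stage(cfg, calls, expr)
    stage_msg("burstein", t0)
  }

  t0 <- Sys.time()
  stats <- if (!is.null(clinical)) {
    cohort_contrasts(calls, clinical, burstein = burstein)
  } else NULL
  summary <- pipeline_summary(calls, truth, model$classes)
  stage_msg("stats", t0)

  out <- list(calls = calls, thresholds = res$thresholds, scores = res$scores,
              prevalence = prevalence, burstein = burstein, stats = stats,
              summary = summary, truth = truth, clinical = clinical, config = cfg)
  if (!is.null(out_dir)) write_report_bundle(out, expr, out_dir)
  out
}

# TNBC re-classification stage. With a configured model, Basal-involved
# samples of the cohort are re-classified on the shared panel. In simulate
# mode, a self-contained synthetic demonstration regenerates TNBC-panel
# profiles for the Basal-involved samples: planted duals from LAR/MES
# centroids, planted singles from BLIA/BLIS, mirroring the qualitative
# contrast the re-classification is meant to surface.
run_burstein_stage <- function(cfg, calls, expr) {
  basal_involved <- grepl("Basal", calls$group)
  ids <- calls$sample_id[basal_involved]
  if (!is.null(cfg$burstein$model)) {
    model <- read_signature_model(cfg$burstein$model)
    class(model) <- c("burstein_model", class(model))
    bc <- classify_burstein(expr[, ids, drop = FALSE], model)
  } else {
    model <- synthetic_burstein_model(seed = cfg$seed + 4L)
    genes <- model$signatures[[1L]]$genes
    is_dual <- calls$kind[basal_involved] != "Single"
    set.seed(cfg$seed + 5L)
    src <- ifelse(is_dual,
                  sample(c("LAR", "MES"), length(ids), replace = TRUE),
                  sample(c("BLIA", "BLIS"), length(ids), replace = TRUE))
    panel <- vapply(src, function(cl) {
      model$signatures[[cl]]$centroid +
        stats::rnorm(length(genes), sd = cfg$burstein$noise_sd)
    }, numeric(length(genes)))
    panel <- matrix(panel, nrow = length(genes), dimnames = list(genes, ids))
    bc <- classify_burstein(panel, model)
  }
  xt <- crosstab_burstein_vs_dual(bc, calls[basal_involved, ], dual_by = "kind")
  test <- if (all(dim(xt) >= 2) && !any(rowSums(xt) == 0) && !any(colSums(xt) == 0)) {
    chi_square_test(xt[rowSums(xt) > 0, colSums(xt) > 0, drop = FALSE])
  } else NULL
  list(calls = bc, crosstab = xt, chi_square = test,
       synthetic_demo = is.null(cfg$burstein$model))
}

# The cohort contrasts: Ki-67 ordering, TNLP fractions, ER-low fractions,
# and the pCR response comparison with a covariate-adjusted logistic model.
cohort_contrasts <- function(calls, clinical, burstein = NULL) {
  df <- merge(calls, clinical, by = "sample_id")
  out <- list()
  grp <- function(g) df[df$group == g, , drop = FALSE]
  have <- function(g, k = 2L) sum(df$group == g) >= k

  if (have("Luminal-single-type") && have("Luminal-Basal-type")) {
    out$ki67_luminal_dual_vs_single <- welch_t_test(
      grp("Luminal-Basal-type")$ki67_pct, grp("Luminal-single-type")$ki67_pct)
  }
  if (have("Luminal-Basal-type") && have("Basal-single-type")) {
    out$ki67_luminal_basal_vs_basal <- welch_t_test(
      grp("Luminal-Basal-type")$ki67_pct, grp("Basal-single-type")$ki67_pct)
    tab <- rbind(
      "Luminal-Basal-type" = table(factor(ki67_tnlp(grp("Luminal-Basal-type")$ki67_pct),
                                          levels = c(TRUE, FALSE))),
      "Basal-single-type" = table(factor(ki67_tnlp(grp("Basal-single-type")$ki67_pct),
                                         levels = c(TRUE, FALSE)))
    )
    colnames(tab) <- c("TNLP-range", "Ki67>=30")
    out$tnlp_table <- tab
    if (!any(rowSums(tab) == 0) && !any(colSums(tab) == 0)) {
      out$tnlp_chi_square <- chi_square_test(tab)
    }
  }
  er_low <- er_low_positive(df$er_pct)
  if (any(er_low)) {
    counts <- table(df$group[er_low])
    out$er_low_by_group <- lapply(stats::setNames(names(counts), names(counts)),
      function(g) proportion_with_ci(counts[[g]], sum(er_low)))
  }

  her2_groups <- c("HER2-single-type", "Luminal-HER2-type")
  sub <- df[df$group %in% her2_groups & is.finite(df$pcr), , drop = FALSE]
  if (nrow(sub) && all(table(factor(sub$group, levels = her2_groups)) >= 2L) &&
      length(unique(sub$pcr)) == 2L) {
    out$pcr_rates <- lapply(stats::setNames(her2_groups, her2_groups), function(g) {
      proportion_with_ci(sum(sub$pcr[sub$group == g]), sum(sub$group == g))
    })
    tab <- table(factor(sub$group, levels = her2_groups), factor(sub$pcr, levels = c(0, 1)))
    out$pcr_chi_square <- chi_square_test(tab)
    design <- data.frame(
      luminal_her2 = as.integer(sub$group == "Luminal-HER2-type"),
      hr_positive = as.integer(derive_hr_status(sub$er_pct, sub$pr_pct) == "HR+"),
      stage = sub$stage,
      grade = sub$grade,
      therapy_t = as.integer(sub$therapy == "CT+T")
    )
    design <- design[, vapply(design, function(x) stats::sd(x) > 0, logical(1)),
                     drop = FALSE]
    out$pcr_logistic <- tryCatch(logistic_fit(design, sub$pcr),
                                 warning = function(w) {
                                   res <- suppressWarnings(logistic_fit(design, sub$pcr))
                                   attr(res, "warning") <- conditionMessage(w)
                                   res
                                 },
                                 error = function(e) conditionMessage(e))
  }
  out
}

# Table-1-style accounting plus truth-vs-call recovery when truth is known.
pipeline_summary <- function(calls, truth, classes) {
  acct <- list(
    n = nrow(calls),
    by_kind = as.list(table(factor(calls$kind, levels = c("Single", "Dual", "Triple")))),
    by_group = as.list(sort(table(calls$group), decreasing = TRUE)),
    # the standard (argmax) class is the first, highest-scoring component
    by_standard_class = as.list(table(factor(
      vapply(strsplit(sub("(-single)?-type$", "", calls$label), "-", fixed = TRUE),
             `[`, character(1), 1L), levels = classes)))
  )
  if (!is.null(truth)) {
    single <- truth$kind == "Single"
    called_first <- sub("(-single)?-type$", "", calls$label)
    called_first <- vapply(strsplit(called_first, "-", fixed = TRUE), `[`, character(1), 1L)
    m <- match(truth$sample_id, calls$sample_id)
    same_set <- function(a, b) {
      mapply(function(x, y) setequal(x, y),
             strsplit(a, "+", fixed = TRUE), strsplit(b, "-", fixed = TRUE))
    }
    dual <- truth$kind == "Dual"
    acct$truth_vs_call <- list(
      single_accuracy = mean(called_first[m][single] ==
                               vapply(strsplit(truth$components[single], "+", fixed = TRUE),
                                      `[`, character(1), 1L)),
      dual_recall = if (any(dual)) mean(calls$kind[m][dual] == "Dual") else NA_real_,
      dual_component_recall = if (any(dual)) {
        mean(calls$kind[m][dual] == "Dual" &
               same_set(truth$components[dual],
                        sub("-type$", "", calls$label[m][dual])))
      } else NA_real_,
      false_dual_rate = mean(calls$kind[m][single] != "Single")
    )
  }
  acct
}

write_report_bundle <- function(out, expr, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  if (!is.null(out$truth)) write_truth_table(out$truth, p("truth.csv"))
  if (!is.null(out$clinical)) write_clinical_table(out$clinical, p("clinical.csv"))
  write_dual_calls(out$calls, p("calls.csv"))
  write_threshold_set(out$thresholds, p("thresholds.json"))
  if (!is.null(out$prevalence)) write_prevalence_estimate(out$prevalence, p("prevalence.json"))
  if (!is.null(out$stats)) {
    jsonlite::write_json(out$stats, p("stats.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null", force = TRUE)
  }
  jsonlite::write_json(out$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null", force = TRUE)
  if (isTRUE(out$config$save_expression)) write_expression_matrix(expr, p("expression.tsv"))
  invisible(out_dir)
}
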