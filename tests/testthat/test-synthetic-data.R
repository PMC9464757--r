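test_that("configuration invariants are enforced", {
  expect_error(sim_config(0), "empty cohort")
  expect_error(sim_config(10, class_proportions = c(Luminal = 0.6, Basal = 0.3, HER2 = 0.2)),
               "sum to 1")
  expect_error(sim_config(10, dual_fraction = 0.7, triple_fraction = 0.5), "\\[0, 1\\]")
  expect_error(sim_config(10, noise_sd = -1), "noise_sd")
  expect_error(sim_config(10, dual_attenuation = 0), "dual_attenuation")
})

test_that("noise-free activation shift equals the configured effect exactly", {
  cfg <- sim_config(n_samples = 20, dual_fraction = 0, triple_fraction = 0,
                    noise_sd = 0, activation_effect = 2, seed = 5)
  cohort <- generate_expression_cohort(cfg)
  bg <- grep("^BG_", rownames(cohort$expression), value = TRUE)
  for (i in seq_len(20)) {
    own <- cohort$gene_sets[[cohort$truth$components[i]]]
    diff <- mean(cohort$expression[own, i]) - mean(cohort$expression[bg, i])
    expect_equal(diff, 2, tolerance = 1e-12)
  }
})

test_that("the same seed reproduces the cohort bit-identically", {
  a <- generate_expression_cohort(sim_config(n_samples = 40, seed = 7))
  b <- generate_expression_cohort(sim_config(n_samples = 40, seed = 7))
  c <- generate_expression_cohort(sim_config(n_samples = 40, seed = 8))
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$expression, c$expression))
})

test_that("label counts follow deterministic largest-remainder allocation", {
  cfg <- sim_config(n_samples = 1000, dual_fraction = 0.05, triple_fraction = 0.003)
  truth <- generate_expression_cohort(cfg)$truth
  kinds <- table(factor(truth$kind, levels = c("Single", "Dual", "Triple")))
  expect_identical(unname(as.integer(kinds)), c(947L, 50L, 3L))
  # label kind always equals the number of planted components
  expect_identical(unname(c("Single", "Dual", "Triple")[lengths(
    strsplit(truth$components, "+", fixed = TRUE))]), truth$kind)
  # class allocation of the singles follows the largest-remainder rule too
  singles <- table(truth$components[truth$kind == "Single"])
  expect_identical(
    as.integer(singles[c("Luminal", "Basal", "HER2")]),
    as.integer(allocate_counts(947, cfg$class_proportions))
  )
})

test_that("allocate_counts splits exactly and deterministically", {
  expect_identical(allocate_counts(7, c(a = 1, b = 1, c = 1)), c(a = 3L, b = 2L, c = 2L))
  expect_identical(sum(allocate_counts(193, c(0.61, 0.278, 0.112))), 193L)
  expect_error(allocate_counts(5, c(0, 0)), "not all zero")
})

test_that("clinical annotations couple ER and Ki-67 to the planted classes", {
  cfg <- sim_config(n_samples = 10000, seed = 21)
  groups <- c(rep("Luminal", 5000), rep("Luminal+Basal", 2000),
              rep("Basal", 2000), rep("HER2", 1000))
  truth <- data.frame(
    sample_id = sprintf("S%05d", seq_along(groups)),
    kind = c("Single", "Dual")[1L + grepl("+", groups, fixed = TRUE)],
    components = groups,
    label = c("Luminal-single-type", "Luminal-Basal-type", "Basal-single-type",
              "HER2-single-type")[match(groups, unique(groups))],
    clinical_subtype = c("HR+HER2-", "HR+HER2-", "HR-HER2-", "HR-HER2+")[
      match(groups, unique(groups))],
    stringsAsFactors = FALSE
  )
  clin <- generate_clinical_annotations(truth, cfg)
  mean_by <- function(col, g) mean(clin[[col]][truth$components == g])
  # ER ordering: Luminal-single > dual-with-Luminal > Basal-single
  expect_gt(mean_by("er_pct", "Luminal"), mean_by("er_pct", "Luminal+Basal"))
  expect_gt(mean_by("er_pct", "Luminal+Basal"), mean_by("er_pct", "Basal"))
  # Ki-67 ordering: Luminal-single < Luminal dual < Basal-single / HER2-single
  expect_lt(mean_by("ki67_pct", "Luminal"), mean_by("ki67_pct", "Luminal+Basal"))
  expect_lt(mean_by("ki67_pct", "Luminal+Basal"), mean_by("ki67_pct", "Basal"))
  expect_lt(mean_by("ki67_pct", "Luminal+Basal"), mean_by("ki67_pct", "HER2"))
  # triple negatives have ER and PR below the 1% positivity cut
  tn <- truth$clinical_subtype == "HR-HER2-"
  expect_true(all(clin$er_pct[tn] < 1 & clin$pr_pct[tn] < 1))
  # HER2 IHC/FISH agree with the assigned clinical subtype
  derived <- derive_her2_status(clin$her2_ihc, clin$her2_fish)
  expect_identical(derived == "HER2+", grepl("HER2\\+$", truth$clinical_subtype))
  # empty truth gives an empty, schema-complete table
  empty <- generate_clinical_annotations(truth[0, ], cfg)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("er_pct", "ki67_pct", "her2_ihc", "pcr") %in% names(empty)))
})

test_that("pCR outcomes follow the configured group rates", {
  truth <- data.frame(
    sample_id = sprintf("S%04d", 1:2200),
    label = c(rep("HER2-single-type", 2000), rep("Luminal-single-type", 200)),
    stringsAsFactors = FALSE
  )
  out <- generate_pcr_outcomes(
    truth, c("HER2-single-type" = 0.6, "Luminal-single-type" = 0), seed = 13)
  expect_true(all(out$pcr[out$label == "Luminal-single-type"] == 0))
  k <- sum(out$pcr[out$label == "HER2-single-type"])
  bounds <- qbinom(c(0.005, 0.995), 2000, 0.6)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
  # rate 1 forces the outcome; same seed reproduces draws
  all1 <- generate_pcr_outcomes(truth, c("HER2-single-type" = 1, "Luminal-single-type" = 1), 1)
  expect_true(all(all1$pcr == 1))
  expect_identical(out, generate_pcr_outcomes(
    truth, c("HER2-single-type" = 0.6, "Luminal-single-type" = 0), seed = 13))
  expect_error(generate_pcr_outcomes(truth, c("HER2-single-type" = 0.6), 1),
               "Luminal-single-type")
})
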