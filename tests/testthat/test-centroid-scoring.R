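test_that("trained centroids are per-gene class means", {
  expr <- matrix(c(1, 2, 3, 4, 1, 2, 5, 6), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2", "s3", "s4")))
  model <- train_centroids(expr, c("A", "A", "B", "B"),
                           list(A = c("g1", "g2"), B = c("g1", "g2")))
  expect_equal(unname(model$signatures$A$centroid), c(2, 3))
  # two identical samples reproduce the shared profile exactly
  expr2 <- matrix(c(5, 1, 5, 1), nrow = 2,
                  dimnames = list(c("g1", "g2"), c("s1", "s2")))
  m2 <- train_centroids(expr2, c("A", "A"), list(A = c("g1", "g2")))
  expect_equal(unname(m2$signatures$A$centroid), c(5, 1))
  expect_error(train_centroids(expr, c("A", "A", "B", "B"), list(A = c("g1", "gX"))), "gX")
  expect_error(train_centroids(expr, c("A", "A", "B", "C"), list(C = c("g1", "g2"))),
               "fewer than 2")
})

test_that("trained centroids recover the generating signature means", {
  fix <- make_scored_cohort(n = 300, seed = 2, noise_sd = 0.1,
                            dual_fraction = 0, triple_fraction = 0)
  truth <- fix$cohort$truth
  for (cl in names(fix$config$signature_sizes)) {
    n_cl <- sum(truth$components == cl)
    expected <- fix$config$activation_effect *
      expected_loadings(fix$config$signature_sizes[[cl]])
    se <- 0.1 / sqrt(n_cl)
    expect_true(all(abs(fix$model$signatures[[cl]]$centroid - expected) < 3 * se + 1e-9))
  }
})

test_that("score of a class is the Pearson correlation with its centroid", {
  model <- toy_model()
  prof <- toy_profile("Luminal")
  sc <- score_sample(prof, model)
  expect_equal(unname(sc$scores["Luminal"]), 1.0, tolerance = 1e-12)
  expect_identical(sc$winning_class, "Luminal")
  # positive affine transform leaves every Pearson score unchanged
  sc2 <- score_sample(2 * prof + 5, model)
  expect_equal(sc$scores, sc2$scores, tolerance = 1e-12)
  # brute-force covariance-formula oracle on a 4-gene signature
  x <- c(1, 0, 2, 1)
  cent <- c(0.5, 0.2, 1.1, 0.7)
  m4 <- signature_model(list(A = list(genes = paste0("a", 1:4), centroid = cent)))
  n <- 4
  r_oracle <- (sum(x * cent) - n * mean(x) * mean(cent)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(cent^2) - n * mean(cent)^2))
  got <- score_sample(stats::setNames(x, paste0("a", 1:4)), m4)
  expect_equal(unname(got$scores["A"]), r_oracle, tolerance = 1e-12)
})

test_that("degenerate profiles raise errors instead of silent scores", {
  model <- toy_model()
  prof <- toy_profile()
  expect_error(score_sample(prof[-1], model), "L1")
  flat <- prof
  flat[paste0("B", 1:4)] <- 3
  expect_error(score_sample(flat, model), "zero variance")
})

test_that("standard classification is argmax with a fixed tie order", {
  expect_identical(standard_classify(c(Basal = 0.62, Luminal = 0.10, HER2 = -0.05),
                                     c("Luminal", "Basal", "HER2")), "Basal")
  expect_identical(standard_classify(c(Luminal = 0.4, Basal = 0.4, HER2 = 0.1),
                                     c("Luminal", "Basal", "HER2")), "Luminal")
  # tie order follows the supplied class order, not score-name order
  expect_identical(standard_classify(c(Basal = 0.4, Luminal = 0.4),
                                     c("Luminal", "Basal")), "Luminal")
})

test_that("cohort scoring matches per-sample scoring and handles edge shapes", {
  model <- toy_model()
  profs <- cbind(s1 = toy_profile("Luminal"), s2 = toy_profile("Basal"),
                 s3 = toy_profile("HER2"))
  st <- classify_cohort(profs, model)
  expect_identical(st$winning_class, c("Luminal", "Basal", "HER2"))
  for (i in 1:3) {
    sc <- score_sample(profs[, i], model)
    expect_equal(unname(unlist(st[i, paste0("score_", model$classes)])),
                 unname(sc$scores), tolerance = 1e-12)
  }
  expect_true(all(st$d_top >= 0))
  empty <- classify_cohort(profs[, 0, drop = FALSE], model)
  expect_identical(nrow(empty), 0L)
  expect_true(all(paste0("score_", model$classes) %in% names(empty)))
})

test_that("scores are invariant to a consistent gene permutation", {
  fix <- make_scored_cohort(n = 60, seed = 9)
  perm <- sample(nrow(fix$cohort$expression))
  st_perm <- classify_cohort(fix$cohort$expression[perm, ], fix$model)
  expect_equal(fix$scores, st_perm, tolerance = 1e-12)
})

test_that("noise-free cohorts are classified without error", {
  fix <- make_scored_cohort(n = 120, seed = 4, noise_sd = 0)
  truth <- fix$cohort$truth
  singles <- truth$kind == "Single"
  expect_identical(fix$scores$winning_class[singles],
                   first_component(truth$components[singles]))
  # a single sample's own class scores exactly 1, the repressed ones -1
  S <- as.matrix(fix$scores[singles, paste0("score_", fix$model$classes)])
  expect_equal(unname(apply(S, 1, max)), rep(1, sum(singles)), tolerance = 1e-9)
  expect_equal(unname(apply(S, 1, min)), rep(-1, sum(singles)), tolerance = 1e-9)
})
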