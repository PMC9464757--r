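test_that("hormone-receptor status follows the 1% positivity rule", {
  expect_identical(derive_hr_status(0, 0), "HR-")
  expect_identical(derive_hr_status(1, 0), "HR+")
  expect_identical(derive_hr_status(NA, 5), "HR+")
  expect_identical(derive_hr_status(NA, NA), NA_character_)
  # one marker low, the other unknown: status cannot be excluded
  expect_identical(derive_hr_status(0.5, NA), NA_character_)
  expect_error(derive_hr_status(150, 0), "\\[0, 100\\]")
  # totality over a grid of inputs: every combination maps or is NA
  grid <- expand.grid(er = c(NA, 0, 0.99, 1, 50), pr = c(NA, 0, 0.99, 1, 50))
  out <- derive_hr_status(grid$er, grid$pr)
  expect_true(all(out %in% c("HR+", "HR-", NA)))
  expect_identical(out == "HR+",
                   ifelse(is.na(out), NA, (grid$er >= 1 & !is.na(grid$er)) |
                                          (grid$pr >= 1 & !is.na(grid$pr))))
})

test_that("HER2 status combines IHC and FISH as specified", {
  expect_identical(derive_her2_status("3+"), "HER2+")
  expect_identical(derive_her2_status("2+", "non-amplified"), "HER2-")
  expect_identical(derive_her2_status("2+", "amplified"), "HER2+")
  expect_identical(derive_her2_status("0"), "HER2-")
  expect_identical(derive_her2_status("1+"), "HER2-")
  expect_identical(derive_her2_status("2+", NA), NA_character_)
  expect_error(derive_her2_status("4+"), "invalid HER2 IHC")
  expect_identical(derive_clinical_subtype("HR+", "HER2-"), "HR+HER2-")
  expect_identical(derive_clinical_subtype(NA, "HER2-"), NA_character_)
})

test_that("chi-square equals the brute-force double summation", {
  set.seed(71)
  brute <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  for (rep in 1:20) {
    r <- sample(2:4, 1)
    cc <- sample(2:5, 1)
    tab <- matrix(sample(1:50, r * cc, replace = TRUE), r, cc)
    got <- chi_square_test(tab)
    expect_equal(got$statistic, brute(tab), tolerance = 1e-10)
    expect_equal(got$df, (r - 1) * (cc - 1))
    expect_equal(got$p_value, stats::pchisq(brute(tab), (r - 1) * (cc - 1),
                                            lower.tail = FALSE), tolerance = 1e-12)
  }
})

test_that("chi-square reference cases behave", {
  # low-proliferation split between a dual group and its single counterpart
  tab <- matrix(c(34, 13, 59, 114), 2, byrow = TRUE)
  got <- chi_square_test(tab)
  expect_equal(got$statistic, 22.143, tolerance = 1e-3)
  expect_lt(got$p_value, 0.001)
  # perfectly proportional rows carry no association
  prop <- chi_square_test(matrix(c(10, 20, 30, 60), 2, byrow = TRUE))
  expect_equal(prop$statistic, 0, tolerance = 1e-12)
  expect_equal(prop$p_value, 1, tolerance = 1e-12)
  # a perfect 2x2 association attains the closed form n * 1
  expect_equal(chi_square_test(matrix(c(100, 0, 0, 100), 2))$statistic, 200,
               tolerance = 1e-10)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate")
})

test_that("Welch t behaves on identical and well-separated samples", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  expect_error(welch_t_test(1, c(1, 2)), "insufficient")
  set.seed(72)
  power <- mean(replicate(100, {
    welch_t_test(rnorm(200), rnorm(200, 1))$p_value < 0.05
  }))
  expect_gte(power, 0.99)
})

test_that("Wilson proportions reproduce printed cohort fractions", {
  expect_equal(round(100 * proportion_with_ci(15087, 15580)$point, 1), 96.8)
  expect_equal(round(100 * proportion_with_ci(34, 47)$point, 1), 72.3)
  p0 <- proportion_with_ci(0, 10)
  expect_equal(p0$point, 0)
  expect_equal(p0$lower, 0, tolerance = 1e-12)
  expect_gt(p0$upper, 0)
  # hand-computed Wilson interval oracle
  k <- 34; n <- 47; z <- stats::qnorm(0.975)
  ph <- k / n
  centre <- (ph + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  got <- proportion_with_ci(k, n)
  expect_equal(got$lower, centre - half, tolerance = 1e-10)
  expect_equal(got$upper, centre + half, tolerance = 1e-10)
  expect_error(proportion_with_ci(5, 0), "undefined")
  expect_error(proportion_with_ci(7, 5), "\\[0, n\\]")
})

test_that("logistic regression matches the closed-form 2x2 log odds ratio", {
  tab <- c(a = 30, b = 20, c = 10, d = 40)
  x <- c(rep(1, tab["a"] + tab["b"]), rep(0, tab["c"] + tab["d"]))
  y <- c(rep(1, tab["a"]), rep(0, tab["b"]), rep(1, tab["c"]), rep(0, tab["d"]))
  fit <- logistic_fit(data.frame(exposure = x), y)
  expect_equal(fit$estimate[fit$term == "exposure"], log(6), tolerance = 1e-6)
  expect_false(attr(fit, "separation"))
})

test_that("logistic regression under the null keeps coefficients near zero", {
  set.seed(73)
  design <- data.frame(x1 = rnorm(500), x2 = rbinom(500, 1, 0.4))
  y <- rbinom(500, 1, 0.3)
  fit <- logistic_fit(design, y)
  slopes <- fit[fit$term != "(Intercept)", ]
  expect_true(all(abs(slopes$estimate) < 3 * slopes$se))
})

test_that("degenerate logistic designs error or are flagged", {
  expect_error(logistic_fit(data.frame(x = rnorm(10)), rep(0, 10)), "identical")
  expect_error(logistic_fit(data.frame(x = rep(1, 10)), rep(c(0, 1), 5)), "constant")
  x <- rnorm(40)
  expect_error(logistic_fit(data.frame(a = x, b = 2 * x), rbinom(40, 1, 0.5)),
               "collinear")
  sep_x <- c(rnorm(20, -3), rnorm(20, 3))
  sep_y <- rep(c(0, 1), each = 20)
  expect_warning(fit <- logistic_fit(data.frame(x = sep_x), sep_y), "separation")
  expect_true(attr(fit, "separation"))
})

test_that("Ki-67 and ER-low tagging follow their cutoffs", {
  expect_identical(ki67_tnlp(c(29.9, 30, 45, NA)), c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(er_low_positive(c(0.5, 1, 10, 10.1, NA)),
                   c(FALSE, TRUE, TRUE, FALSE, FALSE))
})
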