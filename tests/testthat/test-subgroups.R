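test_that("two-group comparisons use Mann-Whitney and match exact enumeration", {
  # identical groups: the test statistic sits at its null center
  same <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$method, "mann-whitney")
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  # tie-free 4-vs-4 toys against full enumeration of assignments
  set.seed(13)
  for (i in 1:10) {
    v <- sample(seq(0.1, 40, by = 0.37), 8)
    g <- rep(c("x", "y"), each = 4)
    res <- compare_groups(v, g)
    expect_equal(res$p_value, mw_enumeration_p(v[1:4], v[5:8]), tolerance = 1e-9)
  }
})

test_that("more than two groups fall through to Kruskal-Wallis", {
  set.seed(3)
  v <- rnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  res <- compare_groups(v, g)
  expect_equal(res$method, "kruskal-wallis")
  expect_equal(res$p_value, kruskal.test(v, factor(g))$p.value)
  expect_error(compare_groups(v, rep(c("a", "b", "c"), c(30, 0, 0))), "2 groups|nonempty")
})

test_that("two-group Kruskal-Wallis equals the asymptotic Mann-Whitney p", {
  set.seed(19)
  for (i in 1:8) {
    v <- c(rnorm(15), rnorm(12, 0.8))
    v[sample(27, 4)] <- round(v[sample(27, 4)])  # inject some ties
    g <- rep(c("a", "b"), c(15, 12))
    expect_equal(compare_groups(v, g)$p_value,
                 kruskal.test(v, factor(g))$p.value, tolerance = 1e-9)
  }
})

test_that("malignant-vs-benign CM separates at study-like effect sizes", {
  cfg <- cohort_config(n_malignant = 110L, n_benign = 120L, seed = 6L)
  oc <- operating_characteristics(cfg, n = 300, seed = 61L)
  set.seed(62)
  age <- rep(50, 300)
  cm_m <- rowSums(cmdx:::draw_percent_matrix(110, TRUE, rep(50, 110), cfg))
  cm_b <- rowSums(cmdx:::draw_percent_matrix(120, FALSE, rep(50, 120), cfg))
  res <- compare_groups(c(cm_m, cm_b), rep(c("malignant", "benign"), c(110, 120)))
  expect_lt(res$p_value, 0.0001)
})

test_that("call-rate tables use exact or seeded Monte-Carlo Fisher tests", {
  # 2x2 (3,1; 1,3): two-sided hypergeometric p = 34/70 by hand
  calls <- rep(c("malignant", "benign"), c(4, 4))
  strata <- c("a", "a", "a", "b", "a", "b", "b", "b")
  res <- call_rate_table(calls, strata)
  expect_equal(unclass(res$table)[, "a"], c(malignant = 3, benign = 1))
  expect_equal(res$p_value, 34 / 70, tolerance = 1e-9)
  # identical call rates in two tiny strata
  res2 <- call_rate_table(rep(c("malignant", "benign"), 2), c("a", "a", "b", "b"))
  expect_equal(res2$p_value, 1)
  # 2x4 table goes Monte-Carlo, seeded and reproducible
  set.seed(77)
  calls4 <- sample(c("malignant", "benign"), 120, TRUE)
  strata4 <- sample(letters[1:4], 120, TRUE)
  a <- call_rate_table(calls4, strata4, b = 2e4, seed = 5L)
  b <- call_rate_table(calls4, strata4, b = 2e4, seed = 5L)
  expect_match(a$method, "monte-carlo")
  expect_equal(a$p_value, b$p_value)
  # equal positivity in every stratum by construction
  expect_gt(call_rate_table(rep(rep(c("malignant", "benign"), each = 5), 4),
                            rep(letters[1:4], each = 10), b = 2e4)$p_value, 0.05)
  expect_warning(call_rate_table(calls[1:4], factor(strata[1:4], levels = c("a", "b", "zz"))),
                 "empty")
})

test_that("age trend is exact least squares with sensible degenerate handling", {
  # zero-covariance construction: slope exactly 0, p exactly 1
  flat <- age_trend(c(1, 2, 2, 1), c(1, 2, 3, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$p_value, 1)
  two <- age_trend(c(1, 3), c(40, 60))
  expect_equal(two$slope, 0.1)            # exact interpolating line
  expect_true(is.na(two$p_value))         # no residual degrees of freedom
  expect_error(age_trend(c(1, 2, 3), rep(50, 3)), "constant")
  set.seed(41)
  cm <- rexp(10, 1 / 3); age <- runif(10, 30, 80)
  res <- age_trend(cm, age)
  or <- ols_oracle(age, cm)
  expect_equal(res$slope, or$slope, tolerance = 1e-12)
  expect_equal(res$intercept, or$intercept, tolerance = 1e-12)
  expect_equal(res$correlation, cor(cm, age), tolerance = 1e-12)
})

test_that("logistic misclassification fits match a manual IRLS oracle", {
  set.seed(55)
  age <- c(31, 35, 40, 44, 48, 52, 56, 60, 64, 68, 72, 76)
  cm <- c(1, 2, 1, 3, 2, 9, 4, 10, 3, 11, 12, 10)  # older benign drift upward
  truth <- rep("benign", 12)
  full <- c(cm, c(50, 60)); ages <- c(age, c(50, 55))
  truths <- c(truth, rep("malignant", 2))
  res <- misclassification_vs_age(full, ages, truths, thresholds = 8.5)
  ben <- res[res$class == "benign", ]
  or <- irls_oracle(age, as.numeric(cm > 8.5))
  expect_true(ben$converged)
  expect_equal(ben$coef_age, unname(or[2]), tolerance = 1e-6)
})

test_that("age-unrelated misclassification yields near-zero coefficients; drifted cohorts yield positive ones at low thresholds", {
  cfg <- cohort_config(n_malignant = 300L, n_benign = 300L, age_coef = 0,
                       seed = 14L)
  set.seed(15)
  age <- runif(600, 30, 80)
  cm <- c(rowSums(cmdx:::draw_percent_matrix(300, TRUE, age[1:300], cfg)),
          rowSums(cmdx:::draw_percent_matrix(300, FALSE, age[301:600], cfg)))
  truth <- rep(c("malignant", "benign"), each = 300)
  null_fit <- misclassification_vs_age(cm, age, truth, thresholds = c(2, 8.5))
  ben <- null_fit[null_fit$class == "benign" & null_fit$converged, ]
  expect_true(all(abs(ben$coef_age) < 3 * ben$se + 0.05))

  drift <- cohort_config(n_malignant = 300L, n_benign = 300L, age_coef = 0.05,
                         seed = 16L)
  set.seed(17)
  cm_b <- rowSums(cmdx:::draw_percent_matrix(300, FALSE, age[301:600], drift))
  cm2 <- c(cm[1:300], cm_b)
  fits <- misclassification_vs_age(cm2, age, truth, thresholds = c(2, 4))
  low <- fits[fits$class == "benign", ]
  expect_true(all(low$coef_age > 0))
})

test_that("group tests are invariant to sample order", {
  set.seed(71)
  v <- rexp(40); g <- sample(c("a", "b", "c"), 40, TRUE)
  perm <- sample(40)
  expect_equal(compare_groups(v, g)$p_value,
               compare_groups(v[perm], g[perm])$p_value)
  calls <- ifelse(v > 1, "malignant", "benign")
  expect_equal(call_rate_table(calls, g, b = 1e4, seed = 2L)$p_value,
               call_rate_table(calls[perm], g[perm], b = 1e4, seed = 2L)$p_value)
})
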