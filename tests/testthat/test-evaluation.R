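test_that("confusion counts partition the samples", {
  calls <- c("malignant", "malignant", "benign", "benign", "malignant", "benign")
  truth <- c("malignant", "benign", "benign", "malignant", "malignant", "benign")
  cc <- confusion_counts(calls, truth)
  expect_equal(cc, list(tp = 2L, fp = 1L, fn = 1L, tn = 2L))  # hand tally
  expect_equal(with(cc, tp + fp + fn + tn), 6L)
  all_right <- confusion_counts(c("malignant", "benign"), c("malignant", "benign"))
  expect_equal(all_right$fp + all_right$fn, 0L)
  expect_error(confusion_counts("benign", c("benign", "benign")), "equal length")
})

test_that("metrics reproduce the printed study arithmetic at one decimal", {
  # counts reconstructed from the printed cohort sizes (108 malignant, 110
  # benign) and the printed sensitivity/specificity
  m <- diagnostic_metrics(list(tp = 98, fp = 1, fn = 10, tn = 109))
  est <- setNames(round(m$estimate, 1), m$metric)
  expect_equal(est[["sensitivity"]], 90.7)
  expect_equal(est[["specificity"]], 99.1)
  expect_equal(est[["ppv"]], 99.0)
  expect_equal(est[["npv"]], 91.6)
})

test_that("exact intervals match the printed cytology confidence limits", {
  # cytology: 98/106 correct among malignant, 101/106 among benign
  m <- diagnostic_metrics(list(tp = 98, fp = 5, fn = 8, tn = 101))
  sens <- m[m$metric == "sensitivity", ]
  spec <- m[m$metric == "specificity", ]
  expect_equal(round(c(sens$lower, sens$upper), 2), c(85.67, 96.69))
  expect_equal(round(c(spec$lower, spec$upper), 2), c(89.33, 98.45))
})

test_that("metric formulas agree with direct ratios and flag empty denominators", {
  set.seed(2)
  for (i in 1:20) {
    cc <- as.list(setNames(rpois(4, 30) + 1L, c("tp", "fp", "fn", "tn")))
    m <- diagnostic_metrics(cc)
    est <- setNames(m$estimate, m$metric)
    expect_equal(est[["sensitivity"]], 100 * cc$tp / (cc$tp + cc$fn), tolerance = 1e-12)
    expect_equal(est[["specificity"]], 100 * cc$tn / (cc$tn + cc$fp), tolerance = 1e-12)
    expect_equal(est[["ppv"]], 100 * cc$tp / (cc$tp + cc$fp), tolerance = 1e-12)
    expect_equal(est[["npv"]], 100 * cc$tn / (cc$tn + cc$fn), tolerance = 1e-12)
    expect_true(all(m$lower <= m$estimate & m$estimate <= m$upper))
  }
  perfect <- diagnostic_metrics(list(tp = 20, fp = 0, fn = 0, tn = 20))
  expect_equal(perfect$estimate, rep(100, 4))
  none_pos <- diagnostic_metrics(list(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_true(is.na(none_pos$estimate[none_pos$metric == "sensitivity"]))
  expect_false(is.na(none_pos$estimate[none_pos$metric == "specificity"]))
})

test_that("metrics of pooled counts equal metrics of per-stratum counts summed first", {
  set.seed(9)
  strata <- lapply(1:3, function(i)
    as.list(setNames(rpois(4, 20) + 1L, c("tp", "fp", "fn", "tn"))))
  pooled <- Reduce(function(a, b) Map(`+`, a, b), strata)
  m1 <- diagnostic_metrics(pooled)
  m2 <- diagnostic_metrics(list(tp = sum(sapply(strata, `[[`, "tp")),
                                fp = sum(sapply(strata, `[[`, "fp")),
                                fn = sum(sapply(strata, `[[`, "fn")),
                                tn = sum(sapply(strata, `[[`, "tn"))))
  expect_equal(m1, m2)
})

test_that("AUC equals all-pairs enumeration, handles ties, and is rank-invariant", {
  # pROC notes that a CI on a perfect AUC is degenerate; only the point
  # estimate matters here
  r <- suppressWarnings(
    roc_auc(c(1, 2, 3, 10, 11, 12), rep(c("benign", "malignant"), each = 3)))
  expect_equal(r$auc, 1)
  set.seed(23)
  for (i in 1:15) {
    n1 <- sample(3:8, 1); n0 <- sample(3:8, 1)
    scores <- c(sample(0:6, n1, TRUE), sample(0:6, n0, TRUE))  # ties likely
    pos <- rep(c(TRUE, FALSE), c(n1, n0))
    r <- roc_auc(scores, pos)
    expect_equal(r$auc, auc_pairs_oracle(scores, pos), tolerance = 1e-12)
    # strictly monotone transform leaves the empirical AUC unchanged
    r2 <- roc_auc(exp(scores / 3), pos)
    expect_equal(r2$auc, r$auc, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep("malignant", 4)), "degenerate")
})

test_that("DeLong intervals bracket the point estimate", {
  set.seed(5)
  scores <- c(rexp(80, 1 / 2), rexp(80, 1 / 30))
  pos <- rep(c(FALSE, TRUE), each = 80)
  r <- roc_auc(scores, pos)
  expect_true(r$lower <= r$auc && r$auc <= r$upper)
  expect_true(r$upper - r$lower < 0.2)
  rb <- roc_auc(scores, pos, ci_method = "bootstrap")
  expect_true(rb$lower <= rb$auc && rb$auc <= rb$upper)
})

test_that("Spearman concordance uses average ranks and flags constant input", {
  expect_equal(spearman_concordance(1:10, 1:10)$spearman_r, 1)
  expect_equal(spearman_concordance(1:10, 10:1)$spearman_r, -1)
  x <- c(1, 2, 2, 4, 5); y <- c(2, 1, 3, 4, 4)
  expect_equal(spearman_concordance(x, y)$spearman_r,
               cor(rank(x), rank(y)), tolerance = 1e-12)  # tie-aware rank formula
  expect_true(is.na(spearman_concordance(rep(3, 5), 1:5)$spearman_r))
  expect_error(spearman_concordance(1:2, 1:2), "n >= 3")
})
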