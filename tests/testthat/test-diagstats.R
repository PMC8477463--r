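test_that("group comparisons reproduce textbook values", {
  x <- c(1.1, 2.2, 3.3, 4.1)
  same <- compare_groups(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  pooled <- compare_groups(c(1, 2, 3), c(4, 5, 6), var_equal = TRUE)
  expect_equal(pooled$statistic, -3.6742346, tolerance = 1e-6)
  expect_equal(pooled$p_value, 0.0213116, tolerance = 1e-5)
  # exhaustive rank enumeration: U = 0, one-sided p = 1/6, two-sided 1/3
  u <- compare_groups(c(1, 2), c(3, 4), test = "mannwhitney")
  expect_equal(unname(u$statistic), 0)
  expect_equal(u$p_value, 1 / 3, tolerance = 1e-12)
  degen <- compare_groups(c(2, 2), c(2, 2))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
  degen2 <- compare_groups(c(2, 2), c(3, 3))
  expect_true(degen2$degenerate)
  expect_equal(degen2$p_value, 0)
})

test_that("AUC handles separation, ties, and the 5-point worked example", {
  lab <- rep(c("PCa", "BPH"), each = 4)
  expect_equal(roc(c(5, 6, 7, 8, 1, 2, 3, 4), lab)$auc, 1)
  expect_equal(roc(rep(2, 8), lab)$auc, 0.5)
  r <- roc(c(1, 2, 3, 4, 5), c("PCa", "BPH", "PCa", "BPH", "BPH"))
  expect_equal(r$auc, 5 / 6)
  expect_equal(r$direction, "<=")     # positives score low
  expect_error(roc(1:4, rep("PCa", 4)), "both classes")
})

test_that("AUC equals brute-force pair counting on random tied data", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    scores <- sample(0:12, n, replace = TRUE) +
      ifelse(runif(n) < 0.5, 0, 0.5)
    is_pos <- runif(n) < 0.45
    if (!any(is_pos) || all(is_pos)) next
    labels <- ifelse(is_pos, "PCa", "BPH")
    r <- roc(scores, labels, direction = ">")
    expect_equal(r$auc, oracle_auc(scores, is_pos))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(52)
  scores <- rnorm(120)
  labels <- ifelse(runif(120) < 0.4, "PCa", "BPH")
  base <- roc(scores, labels)
  for (f in list(function(x) exp(x), function(x) x^3 + 5 * x,
                 function(x) rank(x)))
    expect_equal(roc(f(scores), labels)$auc, base$auc)
})

test_that("DeLong interval and test agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  for (rep in 1:5) {
    scores <- c(rnorm(40, 1), rnorm(50))
    labels <- rep(c("PCa", "BPH"), c(40, 50))
    r <- roc(scores, labels, direction = ">")
    pr <- pROC::roc(labels, scores, levels = c("BPH", "PCa"),
                    direction = "<", quiet = TRUE)
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(r$ci, ci[c(1, 3)], tolerance = 1e-9)
  }
})

test_that("Youden scan returns the J-optimal midpoint cutoff", {
  lab <- rep(c("PCa", "BPH"), each = 3)
  sep <- roc_analysis(c(10, 11, 12, 1, 2, 3), lab)
  expect_equal(sep$youden_j, 1)
  expect_equal(sep$cutoff, 6.5)       # midpoint of the separating gap
  r <- roc_analysis(c(1, 2, 3, 4, 5), c("PCa", "BPH", "PCa", "BPH", "BPH"))
  # exhaustive scan over the 4 midpoints
  cands <- c(1.5, 2.5, 3.5, 4.5)
  js <- vapply(cands, function(ct) {
    pred <- c(1, 2, 3, 4, 5) <= ct
    truth <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
    sum(pred & truth) / 2 + sum(!pred & !truth) / 3 - 1
  }, numeric(1))
  expect_equal(r$youden_j, max(js))
  expect_equal(r$cutoff, cands[which.max(js)])
})

test_that("J and likelihood-ratio identities hold at reported cutoffs", {
  set.seed(54)
  for (rep in 1:10) {
    n <- 60
    scores <- round(rnorm(n, ifelse(runif(n) < 0.5, 0, 0.8)), 1)
    labels <- ifelse(runif(n) < 0.5, "PCa", "BPH")
    if (length(unique(labels)) < 2) next
    r <- roc_analysis(scores, labels)
    pred <- if (r$direction == ">") scores > r$cutoff else scores <= r$cutoff
    truth <- labels == "PCa"
    sens <- sum(pred & truth) / sum(truth)
    spec <- sum(!pred & !truth) / sum(!truth)
    expect_equal(r$sensitivity, sens)
    expect_equal(r$specificity, spec)
    expect_equal(r$youden_j, sens + spec - 1)
    if (spec < 1) expect_equal(r$lr_pos, sens / (1 - spec))
    if (spec > 0) expect_equal(r$lr_neg, (1 - sens) / spec)
  }
})

test_that("likelihood ratios reproduce the two-class confusion arithmetic", {
  # 75/90 sensitivity, 100/112 specificity
  lr <- likelihood_ratios(75 / 90, 100 / 112)
  expect_equal(lr$lr_pos, 7.78, tolerance = 1e-3)
  expect_equal(lr$lr_neg, 0.19, tolerance = 2e-2)
  expect_equal(likelihood_ratios(1, 1), list(lr_pos = Inf, lr_neg = 0))
  expect_equal(likelihood_ratios(0.5, 0.5), list(lr_pos = 1, lr_neg = 1))
  expect_error(likelihood_ratios(1.2, 0.5), "\\[0, 1\\]")
})

test_that("logistic combination is consistent with single-feature ROC", {
  set.seed(55)
  n <- 200
  labels <- ifelse(runif(n) < 0.45, "PCa", "BPH")
  x <- rnorm(n, ifelse(labels == "PCa", 1, 0))
  single <- roc(x, labels)
  comb1 <- combine_parameters(data.frame(x = x), labels)
  expect_equal(comb1$roc$auc, single$auc, tolerance = 1e-9)
  # adding a strictly monotone transform of the same feature cannot move AUC
  comb2 <- combine_parameters(data.frame(x = x, y = exp(x / 2)), labels)
  expect_equal(comb2$roc$auc, single$auc, tolerance = 0.02)
})

test_that("complete separation falls back to a ridge-stabilized fit", {
  labels <- rep(c("PCa", "BPH"), each = 20)
  x <- c(rnorm(20, 10), rnorm(20, -10))
  expect_warning(cb <- combine_parameters(data.frame(x = x), labels),
                 "separation")
  expect_equal(cb$roc$auc, 1)
  expect_true(all(cb$score >= 0 & cb$score <= 1))
})

test_that("combining two informative independent features beats each margin", {
  set.seed(56)
  d <- sqrt(2) * qnorm(0.75)   # each feature alone has AUC 0.75
  aucs <- replicate(100, {
    n <- 250
    labels <- rep(c("PCa", "BPH"), each = n)
    X <- cbind(f1 = rnorm(2 * n, ifelse(labels == "PCa", d, 0)),
               f2 = rnorm(2 * n, ifelse(labels == "PCa", d, 0)))
    c(combined = combine_parameters(X, labels)$roc$auc,
      m1 = roc(X[, 1], labels)$auc, m2 = roc(X[, 2], labels)$auc)
  })
  med <- apply(aucs, 1, median)
  expect_gt(med["combined"], med["m1"])
  expect_gt(med["combined"], med["m2"])
  # bivariate optimum: Phi(sqrt(2) * z) for equal independent features
  expect_equal(unname(med["combined"]), pnorm(sqrt(2) * qnorm(0.75)),
               tolerance = 0.03)
})

test_that("cohort report emits the documented schema and a calibrated null", {
  set.seed(57)
  n <- 60
  tab <- data.frame(label = rep(c("PCa", "BPH"), each = n))
  for (f in paste0("f", 1:20)) tab[[f]] <- rnorm(2 * n)
  rep_null <- cohort_report(tab)
  expect_named(rep_null$roc,
               c("feature", "auc", "ci_low", "ci_high", "p_vs_half",
                 "cutoff", "direction", "sensitivity_pct", "specificity_pct",
                 "youden_j", "lr_pos", "lr_neg"))
  expect_named(rep_null$comparison,
               c("feature", "pos_mean", "pos_sd", "neg_mean", "neg_sd",
                 "statistic", "p_value"))
  # under the null, few CIs should exclude 0.5 (nominal 5% of 20 features)
  excl <- sum(rep_null$roc$ci_low > 0.5 | rep_null$roc$ci_high < 0.5)
  expect_lte(excl, 4)
  expect_true(all(rep_null$roc$auc >= 0.5 & rep_null$roc$auc < 0.75))
  # rounding contract
  expect_true(all(rep_null$roc$auc == round(rep_null$roc$auc, 3)))
  expect_true(all(rep_null$roc$lr_pos == round(rep_null$roc$lr_pos, 2),
                  na.rm = TRUE))
  expect_error(cohort_report(tab, features = "nope"), "absent")
  # combinations are appended as extra ROC rows
  rep_cb <- cohort_report(tab, features = c("f1", "f2"),
                          combinations = list(c("f1", "f2")))
  expect_equal(rep_cb$roc$feature[3], "f1 & f2")
})
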