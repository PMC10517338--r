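# Rank-sum testing, ROC/AUC and threshold selection.

test_that("rank-sum test reproduces exact reference cases", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 labelings at least as extreme
  expect_equal(r$method, "exact")

  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$u_statistic, 4.5)  # n1*n2/2 from midranks
  expect_gt(same$p_value, 0.99)

  # midrank U equals explicit pair counting with half credit for ties
  a <- c(1, 1, 2); b <- c(1, 2, 2)
  expect_equal(rank_sum_test(a, b)$u_statistic, pair_count_u(a, b))

  expect_error(rank_sum_test(numeric(0), 1), class = "utr_input_error")
})

test_that("exact p-values agree with full enumeration on random data", {
  set.seed(17)
  for (i in 1:60) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    repeat {
      x <- round(rnorm(n1 + n2), 3)
      if (!any(duplicated(x))) break
    }
    a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
    r <- rank_sum_test(a, b)
    expect_equal(r$method, "exact")
    expect_equal(r$p_value, enum_ranksum_p(a, b), tolerance = 1e-12)
  }
})

test_that("rank-sum agrees with the reference implementation", {
  set.seed(23)
  for (i in 1:20) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1))
    r <- rank_sum_test(a, b)
    w <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(r$u_statistic, unname(w$statistic))
    expect_equal(r$p_value, w$p.value, tolerance = 1e-10)
  }
  # large tied samples: normal approximation with tie + continuity
  # correction matches wilcox.test's corrected approximation
  set.seed(29)
  for (i in 1:10) {
    a <- sample(1:8, 20, replace = TRUE); b <- sample(2:9, 22, replace = TRUE)
    r <- rank_sum_test(a, b)
    expect_equal(r$method, "normal_approx")
    w <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(r$p_value, w$p.value, tolerance = 1e-10)
  }
})

test_that("the exact cap switches methods at n1 + n2 = 25", {
  a <- rnorm(12); b <- rnorm(13)
  expect_equal(rank_sum_test(a, b)$method, "exact")
  expect_equal(rank_sum_test(c(a, 99), b)$method, "normal_approx")
  expect_equal(rank_sum_test(c(a, 99), b, exact_cap = 26L)$method, "exact")
})

test_that("ROC AUC equals brute-force pair counting", {
  r <- roc_auc(c(0.9, 0.4), c(0.5, 0.1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(5, 6), c(1, 2))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  set.seed(41)
  for (i in 1:50) {
    pos <- sample(1:10, sample(2:8, 1), replace = TRUE) + runif(1)
    neg <- sample(1:10, sample(2:8, 1), replace = TRUE)
    expect_equal(roc_auc(pos, neg)$auc, pair_auc(pos, neg),
                 tolerance = 1e-12)
  }
})

test_that("AUC identities hold: complement and normalized U", {
  set.seed(43)
  for (i in 1:50) {
    pos <- rnorm(sample(2:12, 1)); neg <- rnorm(sample(2:12, 1))
    r <- roc_auc(pos, neg)
    expect_equal(r$auc + roc_auc(neg, pos)$auc, 1, tolerance = 1e-12)
    u <- rank_sum_test(pos, neg)$u_statistic
    expect_equal(r$auc, u / (length(pos) * length(neg)), tolerance = 1e-12)
  }
})

test_that("ROC curve is monotone along its threshold grid", {
  set.seed(47)
  pos <- rnorm(15, 1); neg <- rnorm(12)
  curve <- roc_auc(pos, neg)$curve
  # thresholds ascend, so TPR and FPR both descend
  expect_true(all(diff(curve$tpr) <= 0))
  expect_true(all(diff(curve$fpr) <= 0))
})

test_that("best threshold maximises Youden J with lowest-threshold ties", {
  expect_equal(threshold_separation(c(2, 3), c(0, 1)), 2)
  # fully overlapping distributions: J = 0 everywhere, lowest grid value
  expect_equal(threshold_separation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(threshold_separation(5, 3), 5)
  # exhaustive check against a grid search
  set.seed(53)
  for (i in 1:20) {
    pos <- sample(1:6, 5, replace = TRUE); neg <- sample(1:6, 5,
                                                         replace = TRUE)
    grid <- sort(unique(c(pos, neg)))
    j <- vapply(grid, function(t) mean(pos >= t) - mean(neg >= t),
                numeric(1))
    expect_equal(threshold_separation(pos, neg), grid[which.max(j)])
  }
})

test_that("benchmark evaluation reports the three tests and the ROC", {
  bm <- simulate_benchmark(simulation_config(seed = 61, n_plp = 24,
                                             n_benign = 18))
  rep <- evaluate_benchmark(bm$dataset, bm$scores, use_abs = TRUE)
  expect_named(rep$comparisons, c("matched_vs_benign",
                                  "matched_vs_mismatched",
                                  "plp_vs_benign"))
  expect_equal(unname(rep$group_sizes),
               c(12L, 12L, 18L))
  expect_lt(rep$comparisons$matched_vs_benign$p_value, 0.01)
  expect_gt(rep$roc$auc, 0.8)
  summary <- report_summary(rep)
  expect_equal(summary$auc_matched_vs_benign, rep$roc$auc)

  # missing scores are named in the error
  err <- expect_error(
    evaluate_benchmark(bm$dataset, bm$scores[-1, ]),
    class = "utr_input_error")
  expect_match(conditionMessage(err), bm$dataset$key[1], fixed = TRUE)
})

test_that("single-item groups still produce exact tests", {
  ds <- structure(data.frame(
    key = c("a", "b", "c"),
    group = c("plp_matched", "plp_mismatched", "benign"),
    mechanism = c("uorf_existing", "undetermined", NA),
    stringsAsFactors = FALSE), class = c("benchmark_dataset", "data.frame"))
  scores <- data.frame(variant_key = c("a", "b", "c"),
                       raw = c(3, 1, 0.1), abs = c(3, 1, 0.1))
  rep <- evaluate_benchmark(ds, scores)
  expect_equal(rep$comparisons$matched_vs_benign$method, "exact")
  expect_equal(rep$roc$auc, 1)
})

test_that("abs scores separate sign-symmetric effects better than raw", {
  # matched effects of both signs around +/-3, benign noise around zero
  set.seed(67)
  matched <- c(rnorm(15, 3, 0.5), rnorm(15, -3, 0.5))
  benign <- rnorm(30, 0, 0.5)
  raw_auc <- roc_auc(matched, benign)$auc
  abs_auc <- roc_auc(abs(matched), abs(benign))$auc
  expect_gt(abs_auc, raw_auc)
  expect_gt(abs_auc, 0.95)
  expect_lt(abs(raw_auc - 0.5), 0.2)
})
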