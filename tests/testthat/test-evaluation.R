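test_that("repeated stratified splits are leak-free and stratified", {
  set.seed(41)
  labels <- setNames(c(rep(0, 65), rep(1, 17), rep(2, 18)),
                     sprintf("S%03d", 1:100))
  plan <- repeated_stratified_splits(labels, repetitions = 10,
                                     val_fraction = 0.2)
  expect_equal(split_leakage_count(plan), 0)
  for (s in plan$splits) {
    expect_setequal(c(s$train, s$validation), names(labels))
    expect_length(s$validation, 13 + 3 + 4)
    vl <- labels[s$validation]
    expect_lte(abs(sum(vl == 0) - 0.2 * 65), 1)
    expect_lte(abs(sum(vl == 1) - 0.2 * 17), 1)
    expect_lte(abs(sum(vl == 2) - 0.2 * 18), 1)
  }
  set.seed(2); p1 <- repeated_stratified_splits(labels, 3)
  set.seed(2); p2 <- repeated_stratified_splits(labels, 3)
  expect_identical(p1$splits, p2$splits)
  expect_error(repeated_stratified_splits(setNames(c(0, 0, 1), letters[1:3])),
               "at least 2 subjects")
})

test_that("k-fold partition covers every subject exactly once", {
  set.seed(43)
  labels <- setNames(rep(0:2, times = c(20, 10, 10)), sprintf("K%02d", 1:40))
  plan <- kfold_splits(labels, k = 5)
  expect_equal(split_leakage_count(plan), 0)
  all_val <- unlist(lapply(plan$splits, `[[`, "validation"))
  expect_setequal(all_val, names(labels))
  expect_equal(length(all_val), 40)  # each subject in exactly one fold
})

test_that("metrics match hand-computed confusion-matrix values", {
  truth <- c(0, 0, 1, 1, 2, 2)
  m <- compute_metrics(truth, truth)
  expect_equal(unname(m["balanced_accuracy"]), 1)
  expect_equal(unname(m["f1"]), 1)

  const <- compute_metrics(c(0, 0, 0, 1, 1, 2), rep(0, 6))
  expect_equal(unname(const["balanced_accuracy"]), 1 / 3)

  # worked 2-class example: TP=2 FN=1 FP=1 TN=1
  tr <- c(1, 1, 1, 0, 0); pr <- c(1, 1, 0, 1, 0)
  mm <- compute_metrics(tr, pr)
  # recall_1 = 2/3, recall_0 = 1/2; precision_1 = 2/3, precision_0 = 1/2
  expect_equal(unname(mm["balanced_accuracy"]), (2 / 3 + 1 / 2) / 2)
  expect_equal(unname(mm["recall"]), (3 * 2 / 3 + 2 * 1 / 2) / 5)
  expect_equal(unname(mm["f1"]), (3 * (2 / 3) + 2 * (1 / 2)) / 5)
})

test_that("one-vs-one AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  n <- 300
  truth <- sample(0:1, n, replace = TRUE)
  score <- truth + rnorm(n)
  prob <- cbind(1 - plogis(score), plogis(score))
  got <- compute_metrics(truth, round(plogis(score)), prob)["auroc"]
  ref <- as.numeric(pROC::auc(pROC::roc(truth, prob[, 2], quiet = TRUE)))
  expect_equal(unname(got), ref, tolerance = 1e-10)
})

test_that("AUROC of random probabilities is near one half", {
  set.seed(45)
  n <- 10000
  truth <- sample(0:2, n, replace = TRUE)
  prob <- matrix(runif(3 * n), n, 3)
  prob <- prob / rowSums(prob)
  pred <- max.col(prob) - 1
  a <- compute_metrics(truth, pred, prob)["auroc"]
  se <- 1 / sqrt(n / 3)  # conservative scale for a pairwise AUC
  expect_lt(abs(a - 0.5), 3 * se)
})

test_that("fold summaries use the sample standard deviation", {
  e <- list(c(auroc = 0.8, f1 = 0.7), c(auroc = 1.0, f1 = 0.7))
  s <- summarize_folds(e)
  expect_equal(unname(s$mean["auroc"]), 0.9)
  expect_equal(unname(s$sd["auroc"]), sd(c(0.8, 1.0)))
  expect_equal(unname(s$sd["f1"]), 0)
  same <- summarize_folds(list(c(a = 0.5), c(a = 0.5), c(a = 0.5)))
  expect_equal(unname(same$sd["a"]), 0)
  single <- summarize_folds(list(c(a = 0.42)))
  expect_equal(unname(single$sd["a"]), 0)   # convention
  expect_equal(unname(single$mean["a"]), 0.42)
})
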