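two_clusters <- function(n_per_class, gap = 8, seed = 1) {
  withr::with_seed(seed, {
    x <- data.frame(
      pi = c(rnorm(n_per_class, 0), rnorm(n_per_class, gap)),
      pe = c(rnorm(n_per_class, 0), rnorm(n_per_class, gap))
    )
    list(x = x, y = rep(c("benign", "malignant"), each = n_per_class))
  })
}

test_that("stratified folds balance classes to within one sample", {
  y26 <- rep(c("benign", "malignant"), each = 13)
  f <- stratified_folds(y26, k = 5, seed = 0)
  expect_equal(sort(as.integer(table(f)), decreasing = TRUE),
               c(6, 5, 5, 5, 5))
  per_class <- table(y26, f)
  expect_true(all(per_class >= 2 & per_class <= 3))

  y10 <- rep(c("benign", "malignant"), 5)
  f10 <- stratified_folds(y10, k = 5, seed = 3)
  expect_true(all(table(y10, f10) == 1))
})

test_that("fold assignment is deterministic in the seed and varies across seeds", {
  y <- rep(c("benign", "malignant"), each = 20)
  assignments <- vapply(1:20, function(s) {
    paste(stratified_folds(y, seed = s), collapse = "")
  }, character(1))
  repeats <- vapply(1:20, function(s) {
    paste(stratified_folds(y, seed = s), collapse = "")
  }, character(1))
  expect_identical(assignments, repeats)
  expect_gt(length(unique(assignments)), 15)
  expect_error(stratified_folds(c("benign", rep("malignant", 9)), k = 5),
               "at least k")
})

test_that("binomial SE of the rounded accuracy matches the printed convention", {
  expect_equal(binomial_se(92.3, 26), 5.2)
  expect_equal(binomial_se(84.6, 26), 7.1)
  expect_equal(binomial_se(96.2, 26), 3.7)
  expect_equal(binomial_se(97.9, 140), 1.2)
  expect_equal(binomial_se(99.3, 140), 0.7)
  expect_equal(binomial_se(100, 26), 0)
  expect_equal(binomial_se(0, 50), 0)
})

test_that("AUC equals the rank statistic and handles the textbook cases", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "each class")
  # oracle equivalence against pROC on random score/label sets
  for (seed in 1:50) {
    withr::with_seed(seed, {
      n <- sample(6:40, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), 2)  # rounded: force ties
    })
    ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(roc_auc(scores, labels), ref, info = paste("seed", seed))
  }
})

test_that("perfectly separated clusters give CA 100 and AUC 1 for all models", {
  d <- two_clusters(15, gap = 10)
  for (kind in c("nn", "svm", "knn", "dt")) {
    cv <- run_cv(d$x, d$y, classifier = kind, seed = 0)
    expect_equal(cv$ca_percent, 100, info = kind)
    expect_equal(cv$auc, 1, info = kind)
    expect_equal(unname(cv$confusion), c(15, 15, 0, 0))
  }
})

test_that("accuracy on permuted labels hovers at chance", {
  d <- two_clusters(15, gap = 10)
  cas <- vapply(1:60, function(s) {
    y_perm <- withr::with_seed(1000 + s, sample(d$y))
    run_cv(d$x, y_perm, classifier = "knn", seed = s)$ca_percent
  }, numeric(1))
  expect_gt(mean(cas), 35)
  expect_lt(mean(cas), 65)
})

test_that("CV results satisfy the confusion-matrix identities", {
  d <- two_clusters(10, gap = 2, seed = 7)  # imperfect separation
  for (kind in c("svm", "knn", "dt")) {
    cv <- run_cv(d$x, d$y, classifier = kind, seed = 2)
    cm <- cv$confusion
    expect_equal(sum(cm), cv$n)
    expect_equal(cv$ca_percent, 100 * (cm[["tp"]] + cm[["tn"]]) / cv$n)
    expect_gte(cv$auc, 0); expect_lte(cv$auc, 1)
    # TPR from the confusion matrix equals recall on the malignant class
    pr <- cv$predictions
    expect_equal(cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]),
                 mean(pr$predicted[pr$truth == "malignant"] == "malignant"))
  }
})

test_that("1-NN's 0/1 scores make AUC = (TPR + TNR) / 2 exactly", {
  d <- two_clusters(12, gap = 2.5, seed = 11)
  cv <- run_cv(d$x, d$y, classifier = "knn", seed = 4)
  cm <- cv$confusion
  tpr <- cm[["tp"]] / (cm[["tp"]] + cm[["fn"]])
  tnr <- cm[["tn"]] / (cm[["tn"]] + cm[["fp"]])
  expect_equal(cv$auc, (tpr + tnr) / 2)
})

test_that("degenerate training folds are rejected", {
  x <- data.frame(pi = rnorm(12))
  y <- rep(c("benign", "malignant"), each = 6)
  # holding out fold 1 leaves only benign samples to train on
  folds <- ifelse(y == "benign", 2L, 1L)
  expect_error(run_cv(x, y, classifier = "knn", folds = folds),
               "single class")
})

test_that("tidy and glance expose the pooled results in broom shape", {
  d <- two_clusters(10, gap = 8)
  cv <- run_cv(d$x, d$y, classifier = "dt", seed = 0)
  td <- tidy(cv)
  expect_named(td, c("truth", "predicted", "n"))
  expect_equal(sum(td$n), 20)
  gl <- glance(cv)
  expect_equal(nrow(gl), 1)
  expect_named(gl, c("classifier", "n", "ca", "ca_se", "auc",
                     "tp", "tn", "fp", "fn"))
  expect_equal(gl$ca_se, binomial_se(round(gl$ca, 1), gl$n))
  expect_s3_class(autoplot(cv), "ggplot")
})
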