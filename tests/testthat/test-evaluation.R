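test_that("Monte Carlo splits have ceil(ratio * n) training examples", {
  for (n in c(4:12, 27, 50, 92, 137, 200)) {
    labels <- rep(c("good", "poor"), length.out = n)
    sp <- mc_splits(seq_len(n), labels, ratio = 0.7, n_iter = 2, seed = n)
    for (s in sp) {
      expect_identical(length(s$train), as.integer(ceiling(0.7 * n)))
      expect_identical(sort(c(s$train, s$test)), seq_len(n))
      expect_length(intersect(s$train, s$test), 0)
      expect_gt(length(unique(labels[s$train])), 1)
      if (length(s$test) >= 2) expect_gt(length(unique(labels[s$test])), 1)
    }
  }
  # the 92-patient design: 65 train / 27 test, every iteration
  labels92 <- rep(c("good", "poor"), c(50, 42))
  for (s in mc_splits(seq_len(92), labels92, n_iter = 5, seed = 3)) {
    expect_identical(length(s$train), 65L)
    expect_identical(length(s$test), 27L)
  }
  # exact split without stratification
  s10 <- mc_splits(1:10, NULL, ratio = 0.5, n_iter = 1, seed = 1)[[1]]
  expect_identical(length(s10$train), 5L)

  expect_identical(mc_splits(1:20, rep(c("a", "b"), 10), seed = 4),
                   mc_splits(1:20, rep(c("a", "b"), 10), seed = 4))
})

test_that("confusion counts match a hand tally", {
  truth <- rep(c("good", "poor"), each = 5)
  expect_identical(confusion(truth, truth),
                   c(tp = 5L, fp = 0L, tn = 5L, fn = 0L))
  all_pos <- rep("good", 10)
  expect_identical(confusion(truth, all_pos)[["fp"]], 5L)
  withr::with_seed(8, {
    for (i in 1:10) {
      t <- sample(c("good", "poor"), 30, replace = TRUE)
      p <- sample(c("good", "poor"), 30, replace = TRUE)
      cm <- confusion(t, p)
      expect_identical(cm[["tp"]], sum(t == "good" & p == "good"))
      expect_identical(cm[["fn"]], sum(t == "good" & p == "poor"))
      expect_identical(cm[["fp"]], sum(t == "poor" & p == "good"))
      expect_identical(cm[["tn"]], sum(t == "poor" & p == "poor"))
      expect_identical(sum(cm), 30L)
    }
  })
})

test_that("metric formulas follow their defining ratios", {
  perfect <- metrics(c(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(unname(perfect), rep(1, 4))
  m <- metrics(c(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(m[["accuracy"]], 0.7)
  expect_equal(m[["precision"]], 0.75)
  expect_equal(m[["recall"]], 0.6)
  expect_equal(m[["f1"]], 2 * 0.75 * 0.6 / 1.35)
  # zero denominators are reported missing, not fabricated
  m0 <- metrics(c(tp = 0, fp = 0, tn = 7, fn = 3))
  expect_true(is.na(m0[["precision"]]))
  expect_equal(m0[["accuracy"]], 0.7)
  expect_error(metrics(c(tp = 0, fp = 0, tn = 0, fn = 0)), "zero")
})

test_that("trapezoidal AUC equals the pairwise-concordance oracle", {
  truth <- rep(c("good", "poor"), each = 4)
  expect_equal(roc_auc(c(.9, .8, .7, .6, .4, .3, .2, .1), truth)$auc, 1)
  expect_equal(roc_auc(rep(0.5, 8), truth)$auc, 0.5)
  expect_error(roc_auc(1:4, rep("good", 4)), "both classes")

  withr::with_seed(17, {
    for (i in 1:20) {
      n <- sample(6:50, 1)
      truth <- sample(c("good", "poor"), n, replace = TRUE)
      if (length(unique(truth)) < 2) next
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
      expect_equal(roc_auc(scores, truth)$auc, oracle_auc(scores, truth))
    }
  })
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(23, {
    truth <- sample(c("good", "poor"), 40, replace = TRUE)
    scores <- runif(40) + 0.3 * (truth == "good")
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = scores, levels = c("poor", "good"),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(scores, truth)$auc, ref)
  })
})

test_that("aggregation reports mean, sample SD, and a vertically averaged ROC", {
  it <- list(c(accuracy = 0.8, auc = 0.9), c(accuracy = 0.9, auc = 0.7))
  rep2 <- aggregate_metrics(it)
  expect_equal(rep2$summary$mean[rep2$summary$metric == "accuracy"], 0.85)
  expect_equal(rep2$summary$sd[rep2$summary$metric == "accuracy"],
               sd(c(0.8, 0.9)))
  expect_equal(rep2$summary$sd[rep2$summary$metric == "accuracy"],
               0.0707, tolerance = 1e-3)

  # identical iterations: zero SD, mean ROC equals the common curve
  roc1 <- data.frame(fpr = c(0, 0.5, 1), tpr = c(0, 0.8, 1))
  rep3 <- aggregate_metrics(rep(list(c(auc = 0.9)), 5), rep(list(roc1), 5))
  expect_true(all(rep3$summary$sd == 0))
  expect_equal(rep3$mean_roc$tpr_mean,
               approx(roc1$fpr, roc1$tpr, xout = rep3$mean_roc$fpr)$y)
  expect_true(all(rep3$mean_roc$tpr_lo >= 0 & rep3$mean_roc$tpr_hi <= 1))

  expect_error(aggregate_metrics(it[1]), "at least 2")
})

test_that("metrics reports serialise to CSV and ROC plots render", {
  it <- list(c(accuracy = 0.8, auc = 0.9), c(accuracy = 0.9, auc = 0.8))
  roc1 <- data.frame(fpr = c(0, 0.4, 1), tpr = c(0, 0.9, 1))
  rep4 <- aggregate_metrics(it, list(roc1, roc1))
  dir <- withr::local_tempdir()
  write_metrics_csv(rep4, dir)
  expect_true(file.exists(file.path(dir, "metrics_summary.csv")))
  expect_true(file.exists(file.path(dir, "roc_mean.csv")))
  path <- file.path(dir, "roc.png")
  plot_mean_roc(rep4, rocs = rep4$rocs, path = path)
  expect_true(file.size(path) > 0)
})
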