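# Brute-force oracle: the published formulas evaluated in plain arithmetic.
oracle_metrics <- function(tp, fp, tn, fn) {
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  list(
    acc = (tp + tn) / (fn + tp + tn + fp),
    tpr = tp / (fn + tp),
    tnr = tn / (tn + fp),
    mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  )
}

test_that("worked examples of the binary metrics are exact", {
  expect_equal(accuracy(new_confusion_counts(5, 0, 5, 0)), 1)
  expect_equal(accuracy(new_confusion_counts(0, 3, 0, 7)), 0)
  expect_equal(accuracy(new_confusion_counts(3, 2, 4, 1)), 0.7)
  expect_equal(sensitivity(new_confusion_counts(8, 0, 0, 2)), 0.8)
  expect_equal(specificity(new_confusion_counts(0, 1, 9, 0)), 0.9)
  expect_equal(sensitivity(new_confusion_counts(5, 0, 3, 0)), 1)
  expect_equal(mcc(new_confusion_counts(10, 0, 10, 0)), 1)
  expect_equal(mcc(new_confusion_counts(0, 10, 0, 10)), -1)
  expect_equal(mcc(new_confusion_counts(6, 2, 3, 1)),
               16 / sqrt(8 * 7 * 5 * 4))
})

test_that("degenerate counts follow the documented conventions", {
  expect_error(accuracy(new_confusion_counts(0, 0, 0, 0)), "undefined")
  expect_error(sensitivity(new_confusion_counts(0, 3, 4, 0)), "undefined")
  expect_error(specificity(new_confusion_counts(3, 0, 0, 2)), "undefined")
  expect_equal(mcc(new_confusion_counts(5, 0, 0, 5)), 0) # zero factor -> 0
  expect_error(new_confusion_counts(-1, 0, 0, 0), "nonnegative")
})

test_that("metrics agree with brute-force arithmetic on random counts", {
  set.seed(42)
  for (i in 1:1000) {
    c4 <- sample(0:200, 4, replace = TRUE) + c(1, 0, 1, 0) # tpr/tnr defined
    counts <- new_confusion_counts(c4[1], c4[2], c4[3], c4[4])
    o <- oracle_metrics(c4[1], c4[2], c4[3], c4[4])
    expect_equal(accuracy(counts), o$acc, tolerance = 1e-12)
    expect_equal(sensitivity(counts), o$tpr, tolerance = 1e-12)
    expect_equal(specificity(counts), o$tnr, tolerance = 1e-12)
    expect_equal(mcc(counts), o$mcc, tolerance = 1e-12)
  }
})

test_that("mcc has no overflow up to 1e9 counts and swap symmetry", {
  big <- new_confusion_counts(1e9, 1e9, 1e9, 1e9)
  expect_equal(mcc(big), 0)
  set.seed(43)
  for (i in 1:50) {
    c4 <- sample(1:500, 4)
    expect_equal(mcc(new_confusion_counts(c4[1], c4[2], c4[3], c4[4])),
                 mcc(new_confusion_counts(c4[3], c4[4], c4[1], c4[2])))
  }
})

test_that("micro-averaged MCC sums one-vs-rest counts across classes", {
  truth <- c("a", "a", "b", "b", "c", "c")
  expect_equal(micro_mcc(truth, truth), 1)

  # oracle: build summed counts by hand from a random 3-class run
  set.seed(44)
  truth <- sample(c("a", "b", "c"), 300, replace = TRUE)
  est <- sample(c("a", "b", "c"), 300, replace = TRUE)
  sums <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (cl in c("a", "b", "c")) {
    sums <- sums + c(
      tp = sum(truth == cl & est == cl),
      fp = sum(truth != cl & est == cl),
      tn = sum(truth != cl & est != cl),
      fn = sum(truth == cl & est != cl)
    )
  }
  o <- oracle_metrics(sums["tp"], sums["fp"], sums["tn"], sums["fn"])
  expect_equal(micro_mcc(truth, est), unname(o$mcc), tolerance = 1e-12)
})

test_that("micro-MCC of random predictions on balanced classes is near 0", {
  set.seed(45)
  truth <- rep(c("a", "b", "c"), each = 1000)
  est <- sample(c("a", "b", "c"), 3000, replace = TRUE)
  expect_lt(abs(micro_mcc(truth, est)), 0.05)
})

test_that("micro-MCC is invariant to class relabeling", {
  set.seed(46)
  truth <- sample(c("a", "b", "c"), 200, replace = TRUE)
  est <- sample(c("a", "b", "c"), 200, replace = TRUE)
  perm <- c(a = "c", b = "a", c = "b")
  expect_equal(micro_mcc(truth, est),
               micro_mcc(perm[truth], perm[est]))
})

test_that("two-class micro-MCC reduces to binary MCC on symmetric runs", {
  # with a symmetric confusion matrix (tp = tn, fp = fn) the summed
  # one-vs-rest counts reproduce the binary MCC exactly
  truth <- c(rep(1, 10), rep(0, 10))
  est <- c(rep(1, 7), rep(0, 3), rep(0, 7), rep(1, 3))
  counts <- confusion_counts(truth, est, positive = "1")
  expect_equal(micro_mcc(truth, est), mcc(counts), tolerance = 1e-12)
})

test_that("AUC follows the rank formulation with ties at one half", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 100), rep(c(0, 1), 50)), 0.5) # all tied
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(47)
  scores <- stats::runif(2000)
  labels <- sample(0:1, 2000, replace = TRUE)
  expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.05)
})

test_that("AUC matches pROC and is invariant to monotone transforms", {
  set.seed(48)
  for (i in 1:10) {
    n <- 150
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.6, 0.4))
    scores <- stats::rnorm(n, mean = labels)
    ours <- roc_auc(scores, labels)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
    expect_equal(roc_auc(stats::plogis(3 * scores - 1), labels), ours,
                 tolerance = 1e-12)
  }
})

test_that("metrics_report assembles the binary panel", {
  rep1 <- metrics_report(c(1, 1, 0, 0), c(1, 0, 0, 0), positive = "1",
                         scores = c(0.9, 0.4, 0.2, 0.1))
  expect_named(rep1, c("acc", "tpr", "tnr", "mcc", "auc"))
  expect_equal(rep1$acc, 0.75)
  expect_equal(rep1$auc, 1)
})
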