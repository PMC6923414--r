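noise_features <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  tibble::as_tibble(m)
}

test_that("a perfectly predictive feature tops the importance ranking", {
  wins <- 0
  for (s in 1:20) {
    d <- noise_features(60, 9, seed = s)
    d$label <- rep(c("UPS", "INTRACELLULAR"), each = 30)
    d$oracle <- as.numeric(d$label == "UPS")
    rk <- rank_importance(d, repetitions = 10, trees_per_rep = 10, seed = s)
    wins <- wins + (rk$feature[rk$rank == 1] == "oracle")
  }
  expect_gte(wins, 20)
})

test_that("all-noise importances are stable and sum to one", {
  d <- noise_features(80, 10, seed = 99)
  set.seed(99)
  d$label <- sample(c("UPS", "INTRACELLULAR"), 80, replace = TRUE)
  rk <- rank_importance(d, repetitions = 50, trees_per_rep = 10, seed = 1)
  expect_equal(sum(rk$score), 1, tolerance = 1e-9)
  expect_lt(max(rk$score), 3 * stats::median(rk$score))
})

test_that("importance averaging reduces variance across master seeds", {
  d <- noise_features(60, 6, seed = 5)
  d$label <- rep(c("UPS", "INTRACELLULAR"), each = 30)
  d$weak <- as.numeric(d$label == "UPS") + stats::rnorm(60, sd = 2)
  top_score <- function(reps, seeds) {
    vapply(seeds, function(s) {
      rk <- rank_importance(d, repetitions = reps, trees_per_rep = 10,
                            seed = s)
      rk$score[rk$feature == "weak"]
    }, numeric(1))
  }
  v1 <- stats::var(top_score(1, 1:8))
  v25 <- stats::var(top_score(25, 1:8))
  expect_lt(v25, v1)
})

test_that("importance ranking is reproducible and flags constants", {
  d <- noise_features(50, 5, seed = 7)
  d$label <- rep(c("UPS", "INTRACELLULAR"), 25)
  expect_identical(
    rank_importance(d, repetitions = 5, seed = 3),
    rank_importance(d, repetitions = 5, seed = 3)
  )
  d$flat <- 1
  expect_warning(rk <- rank_importance(d, repetitions = 5, seed = 3),
                 "Constant")
  expect_equal(rk$score[rk$feature == "flat"], 0)
})

test_that("planted covariate shift is ranked first by drift analysis", {
  d <- noise_features(100, 6, seed = 12)
  ind <- d
  ind$f3 <- ind$f3 + 5 * stats::sd(d$f3) # 5-sigma shift
  rk <- rank_drift(d, ind, repetitions = 20, seed = 2)
  expect_equal(rk$feature[rk$rank == 1], "f3")
  expect_true(all(rk$score >= 0))
  expect_equal(sum(rk$score), 1, tolerance = 1e-9)
})

test_that("a bootstrap copy produces no dominant drift feature", {
  d <- noise_features(120, 6, seed = 13)
  set.seed(13)
  boot <- d[sample(120, replace = TRUE), ]
  rk <- rank_drift(d, boot, repetitions = 20, seed = 3)
  expect_lt(max(rk$score), 0.5)
})

test_that("identical sets trigger the uninformative-drift warning", {
  d <- noise_features(40, 4, seed = 14)
  expect_warning(rank_drift(d, d, repetitions = 3, seed = 1), "identical")
})

test_that("best-one search keeps only the informative candidate", {
  set.seed(20)
  d <- noise_features(80, 6, seed = 20)
  d$label <- rep(c("UPS", "INTRACELLULAR"), each = 40)
  d$signal <- as.numeric(d$label == "UPS")
  sel <- best_one_search(d, max_size = 4, seed = 2,
                         params = list(max_depth = 2, nrounds = 20,
                                       eta = 0.3))
  expect_equal(sel$feature[1], "signal")
  expect_equal(nrow(sel), 1) # noise cannot improve a perfect predictor
  expect_equal(sel$cv_mcc, 1)

  one <- best_one_search(d, max_size = 1, seed = 2,
                         params = list(max_depth = 2, nrounds = 20,
                                       eta = 0.3))
  expect_equal(nrow(one), 1)
  expect_equal(one$feature, "signal")
})

test_that("the greedy path has non-decreasing cross-validated MCC", {
  d <- generate_ups_dataset(50, 50, generator_config(seed = 22))
  feats <- dplyr::bind_cols(ups_feature_subset(generate_features(d)),
                            label = d$label)
  sel <- best_one_search(feats, max_size = 5, seed = 3,
                         params = list(max_depth = 2, nrounds = 20,
                                       eta = 0.3))
  expect_true(all(diff(sel$cv_mcc) >= 0))
})

test_that("nested CV produces 20 runs per setting and selects by MCC", {
  fit <- get_tiny_ups_fit() # 3 x 2 folds, grid of 1
  expect_equal(nrow(fit$cv_runs), 6)
  expect_equal(fit$best_params$max_depth, 2) # grid of one: trivial winner

  d <- generate_ups_dataset(40, 60, generator_config(seed = 103))
  feats <- dplyr::bind_cols(ups_feature_subset(generate_features(d)),
                            label = d$label)
  g2 <- tibble::tibble(max_depth = c(2, 3), nrounds = 20, eta = 0.3)
  fit2 <- train_ups(feats, grid = g2, outer_folds = 5, inner_folds = 4,
                    seed = 5)
  expect_equal(nrow(fit2$cv_runs), 2 * 20) # 5 x 4 = 20 runs per setting
  best_idx <- which.max(fit2$setting_summary$mean_test_mcc)
  expect_equal(fit2$best_params$max_depth, g2$max_depth[best_idx])
  expect_error(train_ups(feats, grid = tibble::tibble()), "empty")
})

test_that("all three model families train and predict probabilities", {
  d <- generate_ups_dataset(40, 60, generator_config(seed = 104))
  feats <- dplyr::bind_cols(ups_feature_subset(generate_features(d)),
                            label = d$label)
  for (fam in c("logistic", "random_forest")) {
    fit <- train_ups(feats, model_family = fam,
                     grid = if (fam == "random_forest") {
                       tibble::tibble(num.trees = 50, mtry = 2)
                     } else NULL,
                     outer_folds = 3, inner_folds = 2, seed = 6)
    p <- predict(fit, feats)
    expect_true(all(p$score >= 0 & p$score <= 1))
  }
})

test_that("prediction enforces the feature-name contract", {
  fit <- get_tiny_ups_fit()
  d <- generate_ups_dataset(5, 5, generator_config(seed = 105))
  feats <- ups_feature_subset(generate_features(d))
  broken <- feats[, 1:5]
  broken$surprise <- 1
  expect_error(predict(fit, broken), "missing")
  expect_error(predict(fit, broken), "surprise") # extras are listed too
})

test_that("labels flip at most once as the threshold sweeps", {
  fit <- get_tiny_ups_fit()
  d <- generate_ups_dataset(20, 20, generator_config(seed = 106))
  feats <- ups_feature_subset(generate_features(d))
  sweep <- seq(0, 1, by = 0.05)
  labels <- vapply(sweep, function(th) {
    predict(fit, feats, threshold = th)$label
  }, character(nrow(feats)))
  flips <- apply(labels, 1, function(r) sum(r[-1] != r[-length(r)]))
  expect_true(all(flips <= 1))
  # boundary: threshold 1 labels UPS only at exact score 1
  p1 <- predict(fit, feats, threshold = 1)
  expect_true(all((p1$label == "UPS") == (p1$score >= 1)))
})

test_that("calibration maps into [0,1], preserves ranks, needs two classes", {
  fit <- get_tiny_ups_fit()
  d <- generate_ups_dataset(40, 40, generator_config(seed = 107))
  feats <- dplyr::bind_cols(ups_feature_subset(generate_features(d)),
                            label = d$label)
  for (m in c("sigmoid", "isotonic")) {
    cfit <- calibrate(fit, m, feats)
    p <- predict(cfit, feats)$score
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(order(p), order(predict(fit, feats)$score))
  }
  single <- feats[feats$label == "UPS", ]
  expect_error(calibrate(fit, "sigmoid", single), "both classes")
})

test_that("isotonic calibration of separated scores approaches 0 and 1", {
  set.seed(31)
  scores <- c(stats::runif(30, 0, 0.3), stats::runif(30, 0.7, 1))
  y01 <- rep(0:1, each = 30)
  cal <- secretr:::fit_calibration(scores, y01, "isotonic")
  out <- secretr:::apply_calibration(cal, c(0.1, 0.9))
  expect_lt(out[1], 0.01)
  expect_gt(out[2], 0.99)
})

test_that("ups model summaries expose importance and fit quality", {
  fit <- get_tiny_ups_fit()
  td <- tidy(fit)
  expect_named(td, c("feature", "importance"))
  expect_equal(sort(td$feature), sort(ups_feature_names()))
  gl <- glance(fit)
  expect_equal(gl$n_features, 8)
  expect_true(gl$oof_auc >= 0 && gl$oof_auc <= 1)
  expect_s3_class(autoplot(fit), "ggplot")
})
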