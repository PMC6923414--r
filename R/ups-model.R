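# Feature columns of a UPS-style tibble = numeric columns that are not
# bookkeeping.
ups_feature_cols <- function(data) {
  setdiff(names(data)[vapply(data, is.numeric, logical(1))],
          c("origin"))
}

ranking_engine <- function(X, y, repetitions, trees_per_rep, seed) {
  const <- apply(X, 2, function(col) length(unique(col)) == 1)
  if (any(const)) {
    warning("Constant feature column(s): ",
            paste(colnames(X)[const], collapse = ", "),
            " (importance 0)", call. = FALSE)
  }
  df <- data.frame(X, .y = factor(y), check.names = FALSE)
  acc <- numeric(ncol(X))
  for (r in seq_len(repetitions)) {
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = trees_per_rep, importance = "impurity",
      seed = seed + r, num.threads = 1
    )
    imp <- pmax(fit$variable.importance, 0)
    if (sum(imp) > 0) imp <- imp / sum(imp)
    acc <- acc + imp
  }
  score <- unname(acc / repetitions)
  tibble::tibble(
    feature = colnames(X), score = score,
    rank = rank(-score, ties.method = "first")
  )
}

#' Rank features by averaged random-forest importance
#'
#' Fits `repetitions` independently seeded random forests and averages their
#' impurity importances (each repetition's importances are normalized to sum
#' to 1 before averaging). Deterministic given the master seed.
#'
#' @param data Tibble with `label` and numeric feature columns.
#' @param repetitions Number of single rankings to average (default 500).
#' @param trees_per_rep Trees per forest (default 25; many small forests give
#'   the averaging its stability).
#' @param seed Integer master seed.
#' @return A `feature_ranking` tibble: `feature`, `score` (mean normalized
#'   importance), `rank`.
#' @export
rank_importance <- function(data, repetitions = 500, trees_per_rep = 25,
                            seed = 1) {
  stopifnot("label" %in% names(data))
  cols <- ups_feature_cols(data)
  if (length(cols) < 2) stop("Need at least two features", call. = FALSE)
  if (length(unique(as.character(data$label))) < 2) {
    stop("Both classes must be present", call. = FALSE)
  }
  out <- ranking_engine(as.matrix(data[, cols]), as.character(data$label),
                        repetitions, trees_per_rep, as.integer(seed))
  structure(out, class = c("feature_ranking", class(out)),
            ranking_type = "importance")
}

#' Rank features by distributional drift between two datasets
#'
#' Sample-selection bias makes some features discriminate the training set
#' from the independent set rather than the classes. The drift score of a
#' feature is its averaged random-forest importance for classifying the
#' ORIGIN of a row (training vs independent): features whose distributions
#' differ between the sets score high and should be avoided.
#'
#' @param train_data,independent_data Tibbles sharing the same feature
#'   columns.
#' @inheritParams rank_importance
#' @return A `feature_ranking` tibble (`feature`, `score`, `rank`).
#' @export
rank_drift <- function(train_data, independent_data, repetitions = 100,
                       trees_per_rep = 25, seed = 1) {
  cols <- intersect(ups_feature_cols(train_data),
                    ups_feature_cols(independent_data))
  if (length(cols) < 2) {
    stop("The two sets must share at least two feature columns",
         call. = FALSE)
  }
  a <- as.matrix(train_data[, cols])
  b <- as.matrix(independent_data[, cols])
  if (nrow(a) == nrow(b) && isTRUE(all.equal(a, b, check.attributes = FALSE))) {
    warning("Training and independent sets are identical; drift scores are ",
            "uninformative (approximately uniform)", call. = FALSE)
  }
  X <- rbind(a, b)
  origin <- c(rep("train", nrow(a)), rep("independent", nrow(b)))
  out <- ranking_engine(X, origin, repetitions, trees_per_rep,
                        as.integer(seed))
  structure(out, class = c("feature_ranking", class(out)),
            ranking_type = "drift")
}

# ---- base model fits ------------------------------------------------------

fit_base_model <- function(X, y01, family, params, seed) {
  if (family == "gradient_boosting") {
    dtrain <- xgboost::xgb.DMatrix(X, label = y01)
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth %||% 3,
                    eta = params$eta %||% 0.1,
                    nthread = 1, seed = seed),
      data = dtrain, nrounds = params$nrounds %||% 100, verbose = 0
    )
    list(family = family, fit = booster, features = colnames(X))
  } else if (family == "random_forest") {
    df <- data.frame(X, .y = factor(y01, levels = c(0, 1)),
                     check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = params$num.trees %||% 500,
      mtry = min(params$mtry %||% floor(sqrt(ncol(X))), ncol(X)),
      probability = TRUE, seed = seed, num.threads = 1
    )
    list(family = family, fit = fit, features = colnames(X))
  } else if (family == "logistic") {
    df <- data.frame(X, .y = y01, check.names = FALSE)
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial())
    )
    list(family = family, fit = fit, features = colnames(X))
  } else {
    stop("Unknown model family: ", family, call. = FALSE)
  }
}

predict_base_scores <- function(model, X) {
  X <- X[, model$features, drop = FALSE]
  switch(model$family,
    gradient_boosting = as.numeric(
      stats::predict(model$fit, xgboost::xgb.DMatrix(X))
    ),
    random_forest = {
      p <- stats::predict(model$fit, data.frame(X, check.names = FALSE),
                          num.threads = 1)$predictions
      as.numeric(p[, "1"])
    },
    logistic = as.numeric(
      suppressWarnings(stats::predict(model$fit,
                                      data.frame(X, check.names = FALSE),
                                      type = "response"))
    )
  )
}

base_importance <- function(model) {
  if (model$family == "gradient_boosting") {
    imp <- xgboost::xgb.importance(model = model$fit)
    out <- stats::setNames(rep(0, length(model$features)), model$features)
    out[imp$Feature] <- imp$Gain
    out
  } else if (model$family == "random_forest") {
    stats::setNames(rep(NA_real_, length(model$features)), model$features)
  } else {
    cf <- stats::coef(model$fit)[-1]
    abs(stats::setNames(as.numeric(cf), model$features))
  }
}

default_ups_grid <- function(family) {
  switch(family,
    gradient_boosting = tidyr::expand_grid(
      max_depth = c(2, 3, 4), nrounds = c(50, 100, 200), eta = c(0.05, 0.1)
    ),
    random_forest = tidyr::expand_grid(
      num.trees = c(200, 500), mtry = c(2, 3)
    ),
    logistic = tibble::tibble(.intercept_only = FALSE)
  )
}

binary_mcc <- function(truth01, pred01) {
  mcc(new_confusion_counts(
    tp = sum(truth01 == 1 & pred01 == 1),
    fp = sum(truth01 == 0 & pred01 == 1),
    tn = sum(truth01 == 0 & pred01 == 0),
    fn = sum(truth01 == 1 & pred01 == 0)
  ))
}

#' Greedy forward ("best-one") feature selection by cross-validated MCC
#'
#' Starting from the empty set, repeatedly adds the candidate feature that
#' maximizes the cross-validated MCC of a reference gradient-boosted
#' classifier, and stops when no candidate improves the MCC or `max_size` is
#' reached. Candidates are normally pre-ordered by high importance and low
#' drift.
#'
#' @param data Tibble with `label` and numeric feature columns.
#' @param candidates Candidate feature names (default: all feature columns).
#' @param max_size Maximum number of selected features (default 8).
#' @param folds Cross-validation folds (default 5).
#' @param positive Positive class label (default `"UPS"`).
#' @param params Reference-classifier hyperparameters (list; defaults
#'   `max_depth = 3`, `nrounds = 50`, `eta = 0.1`).
#' @param seed Integer seed (fixes the fold split across all steps).
#' @return Tibble of the selected set in selection order: `step`, `feature`,
#'   `cv_mcc` (non-decreasing along the path).
#' @export
best_one_search <- function(data, candidates = NULL, max_size = 8, folds = 5,
                            positive = "UPS",
                            params = list(max_depth = 3, nrounds = 50,
                                          eta = 0.1),
                            seed = 1) {
  stopifnot("label" %in% names(data))
  all_cols <- ups_feature_cols(data)
  if (is.null(candidates)) candidates <- all_cols
  missing <- setdiff(candidates, all_cols)
  if (length(missing) > 0) {
    stop("Candidate(s) not in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(candidates) == 0) stop("No candidates", call. = FALSE)
  y01 <- as.integer(as.character(data$label) == positive)
  X <- as.matrix(data[, all_cols])
  fold <- make_stratified_folds(y01, folds, as.integer(seed))

  cv_mcc_for <- function(cols) {
    preds <- numeric(length(y01))
    for (f in seq_len(folds)) {
      tr <- fold != f
      m <- fit_base_model(X[tr, cols, drop = FALSE], y01[tr],
                          "gradient_boosting", params, seed = seed + f)
      preds[!tr] <- predict_base_scores(m, X[!tr, cols, drop = FALSE])
    }
    binary_mcc(y01, as.integer(preds >= 0.5))
  }

  selected <- character(0)
  path <- list()
  best_mcc <- -Inf
  while (length(selected) < max_size) {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0) break
    trial <- purrr::map_dbl(remaining, function(cand) {
      cv_mcc_for(c(selected, cand))
    })
    if (max(trial) <= best_mcc) break
    winner <- remaining[which.max(trial)]
    best_mcc <- max(trial)
    selected <- c(selected, winner)
    path[[length(path) + 1]] <- tibble::tibble(
      step = length(selected), feature = winner, cv_mcc = best_mcc
    )
  }
  dplyr::bind_rows(path)
}

# ---- calibration ----------------------------------------------------------

# Fit a monotone map from raw scores to calibrated probabilities.
fit_calibration <- function(scores, y01, method = c("sigmoid", "isotonic")) {
  method <- match.arg(method)
  if (length(unique(y01)) < 2) {
    stop("Calibration requires both classes in the calibration data",
         call. = FALSE)
  }
  if (method == "sigmoid") {
    # Platt scaling: logistic regression of the outcome on the raw score
    fit <- suppressWarnings(
      stats::glm(y01 ~ scores, family = stats::binomial())
    )
    list(method = "sigmoid", coef = as.numeric(stats::coef(fit)))
  } else {
    ord <- order(scores)
    iso <- stats::isoreg(scores[ord], y01[ord])
    knots <- tibble::tibble(x = iso$x, y = iso$yf) |> dplyr::distinct()
    list(method = "isotonic", knots = knots)
  }
}

# Calibrated scores are blended with a vanishingly small linear component in
# the raw score. The isotonic fit is piecewise constant over pooled blocks
# (and the sigmoid can saturate in floating point), which would introduce
# ties among scores the raw model distinguishes; the blend keeps the map
# strictly increasing on [0, 1] — so ranks and AUC are exactly preserved —
# while distorting probabilities by at most STRICTNESS_EPS.
STRICTNESS_EPS <- 1e-6

apply_calibration <- function(cal, scores) {
  if (is.null(cal)) return(scores)
  mapped <- if (cal$method == "sigmoid") {
    stats::plogis(cal$coef[1] + cal$coef[2] * scores)
  } else {
    k <- cal$knots
    if (nrow(k) == 1) {
      rep(min(max(k$y, 0), 1), length(scores))
    } else {
      pmin(pmax(stats::approx(k$x, k$y, xout = scores, rule = 2,
                              ties = "ordered")$y, 0), 1)
    }
  }
  (1 - STRICTNESS_EPS) * mapped + STRICTNESS_EPS * pmin(pmax(scores, 0), 1)
}

#' Attach (or refit) probability calibration on a trained UPS model
#'
#' Fits a monotone map from the model's raw scores to calibrated
#' probabilities on held-out data — parametric sigmoid (Platt scaling) or
#' nonparametric isotonic regression. Both maps are monotone, so score ranks
#' are preserved. The calibration data must be disjoint from the rows the
#' model was trained on; [train_ups()] uses the pooled out-of-fold
#' predictions of its outer loop by default.
#'
#' @param model A `ups_model` from [train_ups()].
#' @param method `"sigmoid"` or `"isotonic"`.
#' @param calibration_data Tibble with the model's feature columns and a
#'   `label` column.
#' @return The model with updated calibration.
#' @export
calibrate <- function(model, method = c("sigmoid", "isotonic"),
                      calibration_data) {
  stopifnot(inherits(model, "ups_model"))
  method <- match.arg(method)
  X <- ups_predict_matrix(model, calibration_data)
  raw <- predict_base_scores(model$model, X)
  y01 <- as.integer(as.character(calibration_data$label) == model$positive)
  model$calibration <- fit_calibration(raw, y01, method)
  model
}

# ---- nested-CV training ---------------------------------------------------

#' Train the UPS vs intracellular classifier by nested cross-validation
#'
#' Grid-searched nested cross-validation (5 outer x 4 inner folds = 20 runs
#' per hyperparameter setting): each run trains on the inner training
#' partition — with minority oversampling applied inside that partition only,
#' never to validation or test rows — and is scored on its inner validation
#' partition. The setting with the best mean test MCC over its 20 runs wins.
#' Outer-fold models refit with the winning setting provide honest per-fold
#' test MCCs and pooled out-of-fold scores, which also serve as the
#' calibration data. The returned model is refit on all rows.
#'
#' @param data Tibble with `label` (UPS / INTRACELLULAR), optional `id`, and
#'   numeric feature columns (typically the 8-feature subset from
#'   [ups_feature_subset()]).
#' @param model_family `"gradient_boosting"` (default), `"random_forest"` or
#'   `"logistic"`.
#' @param grid Hyperparameter tibble (one row per setting); defaults per
#'   family, e.g. depth {2,3,4} x rounds {50,100,200} x eta {0.05,0.1} for
#'   boosting.
#' @param outer_folds,inner_folds Nested fold counts (5 x 4).
#' @param oversample_method Passed to [oversample()].
#' @param calibration `"sigmoid"`, `"isotonic"` or `"none"`.
#' @param threshold Decision threshold on the calibrated score (default 0.5).
#' @param positive Positive class label (default `"UPS"`).
#' @param seed Integer master seed.
#' @return A `ups_model` with the fitted model, `best_params`, `cv_runs`
#'   (per-run tibble), `setting_summary`, `outer_metrics`, pooled `oof`
#'   scores, `auc`, `importance`, and `calibration`.
#' @export
train_ups <- function(data,
                      model_family = c("gradient_boosting", "random_forest",
                                       "logistic"),
                      grid = NULL, outer_folds = 5, inner_folds = 4,
                      oversample_method = "repeated",
                      calibration = c("sigmoid", "isotonic", "none"),
                      threshold = 0.5, positive = "UPS", seed = 1) {
  model_family <- match.arg(model_family)
  calibration <- match.arg(calibration)
  stopifnot("label" %in% names(data))
  if (is.null(grid)) grid <- default_ups_grid(model_family)
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0) stop("Hyperparameter grid is empty", call. = FALSE)
  seed <- as.integer(seed)

  feat_cols <- ups_feature_cols(data)
  y01 <- as.integer(as.character(data$label) == positive)
  if (length(unique(y01)) < 2) {
    stop("Both classes must be present", call. = FALSE)
  }
  outer_fold <- make_stratified_folds(y01, outer_folds, seed)

  train_once <- function(rows, params, fit_seed) {
    sub <- oversample(data[rows, c("label", feat_cols)],
                      method = oversample_method, positive = positive,
                      seed = fit_seed)
    fit_base_model(as.matrix(sub[, feat_cols]),
                   as.integer(as.character(sub$label) == positive),
                   model_family, as.list(params), seed = fit_seed)
  }
  mcc_on <- function(model, rows) {
    scores <- predict_base_scores(model, as.matrix(data[rows, feat_cols]))
    binary_mcc(y01[rows], as.integer(scores >= 0.5))
  }

  # grid search over all outer x inner runs
  runs <- list()
  for (g in seq_len(nrow(grid))) {
    params <- grid[g, ]
    for (o in seq_len(outer_folds)) {
      dev_rows <- which(outer_fold != o)
      inner_fold <- make_stratified_folds(y01[dev_rows], inner_folds,
                                          seed + 1000L * o)
      for (i in seq_len(inner_folds)) {
        tr <- dev_rows[inner_fold != i]
        va <- dev_rows[inner_fold == i]
        m <- train_once(tr, params, seed + 1000L * o + 10L * i + g)
        runs[[length(runs) + 1]] <- tibble::tibble(
          setting = g, outer_fold = o, inner_fold = i,
          train_mcc = mcc_on(m, tr), test_mcc = mcc_on(m, va)
        )
      }
    }
  }
  cv_runs <- dplyr::bind_rows(runs)
  setting_summary <- cv_runs |>
    dplyr::group_by(.data$setting) |>
    dplyr::summarise(mean_train_mcc = mean(.data$train_mcc),
                     mean_test_mcc = mean(.data$test_mcc),
                     .groups = "drop")
  best <- setting_summary$setting[which.max(setting_summary$mean_test_mcc)]
  best_params <- grid[best, ]

  # honest outer-fold performance + out-of-fold calibration scores
  oof_score <- numeric(nrow(data))
  outer_rows <- purrr::map(seq_len(outer_folds), function(o) {
    dev_rows <- which(outer_fold != o)
    test_rows <- which(outer_fold == o)
    m <- train_once(dev_rows, best_params, seed + 77L * o)
    s <- predict_base_scores(m, as.matrix(data[test_rows, feat_cols]))
    oof_score[test_rows] <<- s
    tibble::tibble(
      outer_fold = o, n_test = length(test_rows),
      mcc = binary_mcc(y01[test_rows], as.integer(s >= 0.5))
    )
  })
  outer_metrics <- dplyr::bind_rows(outer_rows)

  cal <- if (calibration == "none") NULL else {
    fit_calibration(oof_score, y01, calibration)
  }
  final <- train_once(seq_len(nrow(data)), best_params, seed + 7L)

  structure(
    list(
      model = final, family = model_family, best_params = best_params,
      feature_names = feat_cols, positive = positive,
      cv_runs = cv_runs, setting_summary = setting_summary,
      outer_metrics = outer_metrics,
      oof = tibble::tibble(
        id = if ("id" %in% names(data)) data$id else seq_len(nrow(data)),
        score = oof_score, label = as.character(data$label)
      ),
      auc = roc_auc(oof_score, y01),
      importance = base_importance(final),
      calibration = cal, threshold = threshold, seed = seed,
      oversample_method = oversample_method
    ),
    class = "ups_model"
  )
}

# Validate and assemble the prediction matrix for a ups_model.
ups_predict_matrix <- function(model, new_data) {
  missing <- setdiff(model$feature_names, names(new_data))
  if (length(missing) > 0) {
    extra <- setdiff(ups_feature_cols(new_data), model$feature_names)
    stop("Feature columns do not match the trained model.\n  missing: ",
         paste(missing, collapse = ", "),
         if (length(extra)) paste0("\n  extra: ",
                                   paste(extra, collapse = ", ")) else "",
         call. = FALSE)
  }
  as.matrix(new_data[, model$feature_names])
}

#' Predict unconventional secretion from a feature table
#'
#' Scores each protein with the trained (optionally calibrated) model and
#' labels it UPS when the score reaches the threshold.
#'
#' @param object A `ups_model` from [train_ups()].
#' @param new_data Feature tibble containing the model's feature columns
#'   (extra columns are ignored; missing ones are an error naming them).
#' @param threshold Decision threshold (defaults to the model's).
#' @param ... Unused.
#' @return Tibble with `id`, `score` (calibrated probability of UPS) and
#'   `label`.
#' @export
predict.ups_model <- function(object, new_data,
                              threshold = object$threshold, ...) {
  X <- ups_predict_matrix(object, new_data)
  raw <- predict_base_scores(object$model, X)
  score <- apply_calibration(object$calibration, raw)
  tibble::tibble(
    id = if ("id" %in% names(new_data)) new_data$id else seq_len(nrow(X)),
    score = score,
    label = ifelse(score >= threshold, object$positive, "INTRACELLULAR")
  )
}

#' @export
print.ups_model <- function(x, ...) {
  cat("UPS classifier (", x$family, ")\n", sep = "")
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  cat("  mean outer-fold MCC:", round(mean(x$outer_metrics$mcc), 3),
      "| out-of-fold AUC:", round(x$auc, 3), "\n")
  cat("  calibration:",
      if (is.null(x$calibration)) "none" else x$calibration$method,
      "| threshold:", x$threshold, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
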