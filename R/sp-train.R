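# Stratified fold assignment: within each class, shuffled examples are dealt
# round-robin into k folds. Errors when any class has fewer examples than k.
make_stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    stop("Stratification impossible: class(es) ",
         paste(names(tab)[tab < k], collapse = ", "),
         " have fewer than ", k, " examples", call. = FALSE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train the three-class N-terminal signal classifier by nested
#' cross-validation
#'
#' Stratified 5-fold outer cross-validation with a 4-fold inner loop: for each
#' outer held-out fold, four networks are trained on the inner training
#' partitions (each with one inner partition as its early-stopping validation
#' set), giving `outer_folds * inner_folds` members (20 by default) that form
#' the final ensemble. The outer test fold is never seen during the training
#' or selection of its members; its micro-averaged MCC is reported per fold.
#' Class imbalance is handled by a class-weighted loss.
#'
#' @param data Tibble with `sequence` and `label` columns (labels from
#'   SP / TM70 / IN_CELL); typically [read_label_table()] output or
#'   [generate_sp_dataset()].
#' @param config Network settings, see [sp_model_config()].
#' @param outer_folds,inner_folds Fold counts of the nested scheme (5 x 4).
#' @param seed Integer master seed; fixes fold assignment, weight
#'   initialisation and batch order.
#' @param verbose Print per-fold progress.
#' @return An `sp_ensemble` object with elements `members` (trained
#'   networks), `config`, `outer_metrics` (per-fold tibble with micro-MCC),
#'   `levels`, and `seed`.
#' @examples
#' \donttest{
#' toy <- generate_sp_dataset(n_per_class = 24, config = generator_config(seed = 7))
#' fit <- train_sp(toy, sp_model_config(n_motif_kernels = 8, epochs = 3),
#'                 outer_folds = 2, inner_folds = 2, seed = 7)
#' glance(fit)
#' }
#' @export
train_sp <- function(data, config = sp_model_config(), outer_folds = 5,
                     inner_folds = 4, seed = 1, verbose = FALSE) {
  stopifnot(all(c("sequence", "label") %in% names(data)))
  labels <- factor(as.character(data$label), levels = sp_label_levels)
  if (anyNA(labels)) {
    stop("Labels must come from {", paste(sp_label_levels, collapse = ", "),
         "}", call. = FALSE)
  }
  y <- as.integer(labels)
  idx_all <- encode_index_matrix(data$sequence, config$window_length)
  seed <- as.integer(seed)
  outer_fold <- make_stratified_folds(labels, outer_folds, seed)

  members <- list()
  outer_rows <- vector("list", outer_folds)
  for (o in seq_len(outer_folds)) {
    test_rows <- which(outer_fold == o)
    dev_rows <- which(outer_fold != o)
    inner_fold <- make_stratified_folds(labels[dev_rows], inner_folds,
                                        seed + 1000L * o)
    fold_members <- vector("list", inner_folds)
    for (i in seq_len(inner_folds)) {
      tr <- dev_rows[inner_fold != i]
      va <- dev_rows[inner_fold == i]
      fit <- cnn_train(
        idx_all[tr, , drop = FALSE], y[tr],
        idx_all[va, , drop = FALSE], y[va],
        config, seed = seed + 1000L * o + i
      )
      fold_members[[i]] <- structure(
        list(params = fit$params, config = config, trained = TRUE,
             outer_fold = o, inner_fold = i, best_epoch = fit$best_epoch,
             val_loss = fit$val_loss),
        class = "sp_network"
      )
      if (verbose) {
        message("outer ", o, " inner ", i, ": best epoch ", fit$best_epoch,
                ", val loss ", signif(fit$val_loss, 4))
      }
    }
    # outer test metrics from the fold's own 4-member sub-ensemble
    test_scores <- average_member_scores(fold_members, config,
                                         idx_all[test_rows, , drop = FALSE])
    test_pred <- score_to_label(test_scores)
    outer_rows[[o]] <- tibble::tibble(
      outer_fold = o,
      n_test = length(test_rows),
      micro_mcc = micro_mcc(as.character(labels[test_rows]), test_pred,
                            levels = sp_label_levels)
    )
    members <- c(members, fold_members)
  }

  structure(
    list(members = members, config = config,
         outer_metrics = dplyr::bind_rows(outer_rows),
         levels = sp_label_levels, seed = seed,
         outer_folds = outer_folds, inner_folds = inner_folds),
    class = "sp_ensemble"
  )
}

# Mean of member softmax scores (a convex combination, so rows still sum to 1).
average_member_scores <- function(members, config, idx_matrix,
                                  chunk_size = 256L) {
  n <- nrow(idx_matrix)
  acc <- matrix(0, n, config$n_classes)
  starts <- seq(1L, n, by = chunk_size)
  for (s0 in starts) {
    rows <- s0:min(s0 + chunk_size - 1L, n)
    for (m in members) {
      acc[rows, ] <- acc[rows, ] +
        cnn_forward(m$params, config, idx_matrix[rows, , drop = FALSE])$scores
    }
  }
  acc / length(members)
}

# Argmax with ties broken toward IN_CELL (the conservative no-signal call).
score_to_label <- function(scores, levels = sp_label_levels) {
  incell <- match("IN_CELL", levels)
  apply(scores, 1, function(s) {
    top <- which(s == max(s))
    if (incell %in% top) levels[incell] else levels[top[1]]
  })
}

#' Predict N-terminal signal classes with a trained ensemble
#'
#' Averages the softmax score vectors of all ensemble members and labels each
#' protein by the argmax of the averaged scores; exact ties resolve to
#' IN_CELL so borderline proteins fall through to the second stage rather
#' than being called SP/TM70.
#'
#' @param object A trained `sp_ensemble` from [train_sp()].
#' @param new_data Tibble with `id` and `sequence` columns (or a character
#'   vector of sequences).
#' @param ... Unused.
#' @return Tibble with `id`, `score_SP`, `score_TM70`, `score_INCELL`,
#'   `label`.
#' @export
predict.sp_ensemble <- function(object, new_data, ...) {
  if (is.character(new_data)) {
    new_data <- tibble::tibble(
      id = paste0("seq", seq_along(new_data)), sequence = new_data
    )
  }
  check_record_columns(new_data)
  if (length(object$members) == 0) {
    stop("Ensemble has no trained members", call. = FALSE)
  }
  idx <- encode_index_matrix(new_data$sequence, object$config$window_length)
  scores <- average_member_scores(object$members, object$config, idx)
  tibble::tibble(
    id = new_data$id,
    score_SP = scores[, 1],
    score_TM70 = scores[, 2],
    score_INCELL = scores[, 3],
    label = score_to_label(scores, object$levels)
  )
}

#' @export
print.sp_ensemble <- function(x, ...) {
  cat("Three-class N-terminal signal ensemble\n")
  cat("  members:", length(x$members), "(", x$outer_folds, "outer x",
      x$inner_folds, "inner folds )\n")
  cat("  mean outer micro-MCC:",
      round(mean(x$outer_metrics$micro_mcc), 3), "\n")
  invisible(x)
}
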