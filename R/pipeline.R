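#' Run the full two-stage secretion prediction cascade
#'
#' Stage one scores every protein with the N-terminal ensemble. Proteins
#' called SP or TM70 keep that final category and never receive a stage-two
#' score; proteins called IN_CELL are routed to the UPS classifier, which
#' assigns the final category UPS or INTRACELLULAR. Every protein ends with
#' exactly one final category.
#'
#' @param records Tibble with `id` and `sequence` (validated).
#' @param sp_model Trained `sp_ensemble` from [train_sp()].
#' @param ups_model Trained `ups_model` from [train_ups()].
#' @param force_ups Debug flag: also score SP/TM70 proteins with stage two
#'   (their final category is still decided by stage one). Non-canonical;
#'   off by default.
#' @return Tibble with `id`, the three stage-one scores, `sp_label`,
#'   `ups_score`, `ups_label` (NA for proteins not routed to stage two
#'   unless `force_ups`), and `category` in {SP, TM70, UPS, INTRACELLULAR}.
#' @export
run_pipeline <- function(records, sp_model, ups_model, force_ups = FALSE) {
  check_record_columns(records)
  stopifnot(inherits(sp_model, "sp_ensemble"), inherits(ups_model, "ups_model"))
  stage1 <- predict(sp_model, records)
  out <- dplyr::rename(stage1, sp_label = "label")
  out$ups_score <- NA_real_
  out$ups_label <- NA_character_

  route <- if (force_ups) rep(TRUE, nrow(out)) else out$sp_label == "IN_CELL"
  if (any(route)) {
    feats <- ups_feature_subset(generate_features(records[route, ]))
    stage2 <- predict(ups_model, feats)
    out$ups_score[route] <- stage2$score
    out$ups_label[route] <- stage2$label
  }
  out$category <- dplyr::case_when(
    out$sp_label != "IN_CELL" ~ out$sp_label,
    TRUE ~ out$ups_label
  )
  if (force_ups) {
    # non-canonical scores on SP/TM70 proteins never decide the category
    out$category <- ifelse(out$sp_label != "IN_CELL", out$sp_label,
                           out$ups_label)
  }
  out
}

#' Summarize pipeline results as category counts and fractions
#'
#' @param results Tibble from [run_pipeline()].
#' @return Tibble with `category`, `n` and `fraction` (fractions sum to 1).
#' @export
summarize_pipeline <- function(results) {
  stopifnot("category" %in% names(results), nrow(results) > 0)
  results |>
    dplyr::count(.data$category, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
}

#' Evaluate predictions against a label table
#'
#' Three-class tasks report per-class one-vs-rest metrics plus the
#' micro-averaged MCC; binary tasks report the standard binary panel.
#'
#' @param predicted Tibble with `id` and `label` (and optionally `score` for
#'   binary AUC).
#' @param truth Tibble with `id` and `label`.
#' @param task `"sp"` or `"ups"`.
#' @return A tibble of metrics.
#' @export
evaluate_predictions <- function(predicted, truth, task = c("sp", "ups")) {
  task <- match.arg(task)
  joined <- dplyr::inner_join(predicted, truth, by = "id",
                              suffix = c("_pred", "_true"))
  if (nrow(joined) == 0) stop("No overlapping ids", call. = FALSE)
  est <- as.character(joined$label_pred)
  tru <- as.character(joined$label_true)
  if (task == "sp") {
    per_class <- purrr::map(sp_label_levels, function(cl) {
      counts <- confusion_counts(tru, est, positive = cl)
      tibble::tibble(class = cl, acc = accuracy(counts),
                     tpr = sensitivity(counts), tnr = specificity(counts),
                     mcc = mcc(counts))
    })
    dplyr::bind_rows(per_class) |>
      dplyr::bind_rows(tibble::tibble(
        class = "micro",
        acc = mean(est == tru),
        mcc = micro_mcc(tru, est, levels = sp_label_levels)
      ))
  } else {
    metrics_report(tru, est, positive = "UPS",
                   scores = joined$score)
  }
}
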