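#' Plot outer-fold performance of a signal ensemble
#'
#' Bar chart of the micro-averaged MCC of each outer test fold.
#'
#' @param object An `sp_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sp_ensemble <- function(object, ...) {
  ggplot2::ggplot(object$outer_metrics,
                  ggplot2::aes(x = factor(.data$outer_fold),
                               y = .data$micro_mcc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = mean(object$outer_metrics$micro_mcc),
                        linetype = "dashed") +
    ggplot2::labs(x = "Outer fold", y = "Micro-averaged MCC",
                  title = "Held-out performance of the N-terminal classifier") +
    ggplot2::ylim(-0.05, 1)
}

#' Plot feature importances of a UPS model
#'
#' @param object A `ups_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ups_model <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$feature,
                                                     .data$importance),
                                  y = .data$importance)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Importance",
                  title = "UPS classifier feature importances")
}

#' Plot a feature ranking
#'
#' @param object A `feature_ranking` from [rank_importance()] or
#'   [rank_drift()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_ranking <- function(object, ...) {
  type <- attr(object, "ranking_type") %||% "importance"
  ggplot2::ggplot(object, ggplot2::aes(x = stats::reorder(.data$feature,
                                                          .data$score),
                                       y = .data$score)) +
    ggplot2::geom_col(fill = if (type == "drift") "firebrick" else "seagreen") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = if (type == "drift") {
                    "Drift score (origin-classification importance)"
                  } else {
                    "Mean normalized importance"
                  })
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
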