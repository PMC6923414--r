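#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-member summary of a trained signal ensemble
#'
#' @param x An `sp_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per ensemble member: fold indices, best epoch
#'   and validation loss.
#' @export
tidy.sp_ensemble <- function(x, ...) {
  purrr::map_dfr(x$members, function(m) {
    tibble::tibble(
      outer_fold = m$outer_fold, inner_fold = m$inner_fold,
      best_epoch = m$best_epoch, val_loss = m$val_loss
    )
  })
}

#' One-row summary of a trained signal ensemble
#'
#' @param x An `sp_ensemble`.
#' @param ... Unused.
#' @return Tibble with member count, fold structure and mean outer
#'   micro-averaged MCC.
#' @export
glance.sp_ensemble <- function(x, ...) {
  tibble::tibble(
    n_members = length(x$members),
    outer_folds = x$outer_folds,
    inner_folds = x$inner_folds,
    mean_outer_micro_mcc = mean(x$outer_metrics$micro_mcc),
    seed = x$seed
  )
}

#' Feature importances of a trained UPS model
#'
#' @param x A `ups_model`.
#' @param ... Unused.
#' @return Tibble with `feature` and `importance` (NA for model families
#'   without a native importance).
#' @export
tidy.ups_model <- function(x, ...) {
  tibble::tibble(
    feature = names(x$importance),
    importance = as.numeric(x$importance)
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' One-row summary of a trained UPS model
#'
#' @param x A `ups_model`.
#' @param ... Unused.
#' @return Tibble with the winning hyperparameters, mean outer-fold MCC and
#'   out-of-fold AUC.
#' @export
glance.ups_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      family = x$family,
      mean_outer_mcc = mean(x$outer_metrics$mcc),
      oof_auc = x$auc,
      n_features = length(x$feature_names),
      calibration = if (is.null(x$calibration)) "none" else {
        x$calibration$method
      },
      seed = x$seed
    ),
    x$best_params
  )
}
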