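#' Save a trained model as a directory bundle
#'
#' Writes the model object together with a small JSON manifest (model type,
#' package version, seed, feature names / network configuration) so bundles
#' are self-describing on disk.
#'
#' @param model A trained `sp_ensemble` or `ups_model`.
#' @param dir Directory to create (must not be an existing non-bundle
#'   directory's content concern; files are overwritten).
#' @return `dir`, invisibly.
#' @export
write_model_bundle <- function(model, dir) {
  stopifnot(inherits(model, c("sp_ensemble", "ups_model")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  type <- class(model)[1]
  manifest <- list(
    type = type,
    package = "secretr",
    version = as.character(utils::packageVersion("secretr")),
    seed = model$seed,
    alphabet = paste(aa_alphabet, collapse = "")
  )
  if (type == "sp_ensemble") {
    manifest$n_members <- length(model$members)
    manifest$config <- unclass(model$config)
  } else {
    manifest$features <- model$feature_names
    manifest$family <- model$family
    manifest$calibration <- if (is.null(model$calibration)) "none" else {
      model$calibration$method
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  # xgboost boosters carry external pointers; serialize them explicitly
  if (type == "ups_model" && model$family == "gradient_boosting") {
    raw <- xgboost::xgb.save.raw(model$model$fit)
    model$model$fit <- NULL
    model$model$xgb_raw <- raw
  }
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' Load a model bundle written by [write_model_bundle()]
#'
#' @param dir Bundle directory.
#' @return The restored model object.
#' @export
read_model_bundle <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  model_path <- file.path(dir, "model.rds")
  if (!file.exists(manifest_path) || !file.exists(model_path)) {
    stop("Not a model bundle (missing manifest.json or model.rds): ", dir,
         call. = FALSE)
  }
  model <- readRDS(model_path)
  if (!is.null(model$model$xgb_raw)) {
    model$model$fit <- xgboost::xgb.load.raw(model$model$xgb_raw)
    model$model$xgb_raw <- NULL
  }
  model
}
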