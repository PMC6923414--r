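#' Balance a two-class feature table by oversampling the minority class
#'
#' The minority (positive) class is grown to the size of the majority class;
#' negative rows are never altered. Three schemes:
#' \describe{
#'   \item{repeated}{cyclic duplication of positive rows, exactly matching
#'     the negative count.}
#'   \item{smote}{each synthetic positive is a convex combination
#'     `a + lambda * (b - a)`, `lambda ~ U(0,1)`, of a positive `a` and one of
#'     its `k` nearest positive neighbours `b` (neighbours found on
#'     standardized features, interpolation in the raw feature space).}
#'   \item{adasyn}{like SMOTE, but the number of synthetics per positive is
#'     proportional to the fraction of majority examples among its `k`
#'     nearest neighbours in the full data, so harder regions are
#'     oversampled more (class counts may differ by a rounding unit).}
#' }
#'
#' @param data Tibble with a `label` column, an optional `id` column, and
#'   numeric feature columns. Non-feature character columns are carried
#'   through for duplicates and set to `NA` on interpolated rows.
#' @param method `"repeated"`, `"smote"` or `"adasyn"`.
#' @param positive Label of the minority/positive class (default `"UPS"`).
#' @param k Neighbour count for smote/adasyn (default 5).
#' @param seed Integer seed.
#' @return The balanced tibble with an added `origin` column
#'   (`"original"`, `"duplicate"` or `"synthetic"`).
#' @export
oversample <- function(data, method = c("repeated", "smote", "adasyn"),
                       positive = "UPS", k = 5, seed = 1) {
  method <- match.arg(method)
  stopifnot("label" %in% names(data))
  lab <- as.character(data$label)
  classes <- unique(lab)
  if (length(classes) != 2 || !(positive %in% classes)) {
    stop("`data` must contain exactly two classes including `", positive,
         "`", call. = FALSE)
  }
  feat_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(feat_cols) == 0) stop("No numeric feature columns", call. = FALSE)
  pos_rows <- which(lab == positive)
  neg_rows <- which(lab != positive)
  n_extra <- length(neg_rows) - length(pos_rows)
  out <- dplyr::mutate(data, origin = "original")
  if (n_extra <= 0) return(out)

  set.seed(as.integer(seed))
  if (method == "repeated") {
    dup_rows <- pos_rows[rep_len(seq_along(pos_rows), n_extra)]
    extra <- dplyr::mutate(data[dup_rows, ], origin = "duplicate")
  } else {
    if (length(pos_rows) < k + 1) {
      stop("Too few positive examples (", length(pos_rows), ") for k = ", k,
           " neighbours; reduce `k` to at most ", length(pos_rows) - 1,
           call. = FALSE)
    }
    X <- as.matrix(data[, feat_cols])
    Xs <- scale(X)
    Xs[, attr(Xs, "scaled:scale") == 0 | is.nan(colSums(Xs))] <- 0
    pairs <- if (method == "smote") {
      smote_pairs(Xs, pos_rows, n_extra, k)
    } else {
      adasyn_pairs(Xs, pos_rows, neg_rows, n_extra, k)
    }
    lambda <- stats::runif(nrow(pairs))
    synth <- X[pairs[, 1], , drop = FALSE] +
      lambda * (X[pairs[, 2], , drop = FALSE] - X[pairs[, 1], , drop = FALSE])
    extra <- data[pairs[, 1], ]
    extra[, feat_cols] <- tibble::as_tibble(synth)
    char_cols <- setdiff(names(data)[vapply(data, is.character, logical(1))],
                         c("id", "label"))
    for (cc in char_cols) extra[[cc]] <- NA_character_
    extra$origin <- "synthetic"
  }
  if ("id" %in% names(extra)) {
    extra$id <- sprintf("%s_%s%04d", extra$id,
                        substr(extra$origin, 1, 3), seq_len(nrow(extra)))
  }
  dplyr::bind_rows(out, extra)
}

# k nearest positive neighbours of each positive (standardized space).
positive_neighbours <- function(Xs, pos_rows, k) {
  d <- as.matrix(stats::dist(Xs[pos_rows, , drop = FALSE]))
  diag(d) <- Inf
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

smote_pairs <- function(Xs, pos_rows, n_extra, k) {
  nn <- positive_neighbours(Xs, pos_rows, k)
  base <- rep_len(seq_along(pos_rows), n_extra)
  mate <- nn[cbind(base, sample.int(k, n_extra, replace = TRUE))]
  cbind(pos_rows[base], pos_rows[mate])
}

adasyn_pairs <- function(Xs, pos_rows, neg_rows, n_extra, k) {
  d_all <- as.matrix(stats::dist(Xs))
  diag(d_all) <- Inf
  # fraction of majority-class points among the k NNs of each positive
  r <- vapply(pos_rows, function(i) {
    nn <- order(d_all[i, ])[seq_len(k)]
    mean(nn %in% neg_rows)
  }, numeric(1))
  if (sum(r) == 0) r <- rep(1, length(r))
  # largest-remainder apportionment: synthetic counts sum to n_extra exactly
  quota <- r / sum(r) * n_extra
  g <- floor(quota)
  short <- n_extra - sum(g)
  if (short > 0) {
    g[order(quota - g, decreasing = TRUE)[seq_len(short)]] <-
      g[order(quota - g, decreasing = TRUE)[seq_len(short)]] + 1
  }
  nn_pos <- positive_neighbours(Xs, pos_rows, k)
  base <- rep(seq_along(pos_rows), g)
  if (length(base) == 0) base <- rep_len(seq_along(pos_rows), n_extra)
  mate <- nn_pos[cbind(base, sample.int(k, length(base), replace = TRUE))]
  cbind(pos_rows[base], pos_rows[mate])
}
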