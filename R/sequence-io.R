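#' Read protein sequences from a FASTA file
#'
#' Returns one row per FASTA entry, in file order. The record id is the first
#' whitespace-delimited token of the header; the full header is kept in
#' `description`. Sequences are upper-cased and trailing `*` stop characters
#' are stripped.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `sequence`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo protein", "MKTAYIAK*"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)))
  if (length(meaningful) == 0) {
    warning("FASTA file is empty: ", path, call. = FALSE)
    return(tibble::tibble(
      id = character(), description = character(), sequence = character()
    ))
  }
  first <- meaningful[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(
      "Malformed FASTA: sequence data before any header at line ", first,
      " of ", path, call. = FALSE
    )
  }
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  tibble::tibble(
    id = vapply(strsplit(headers, "[[:space:]]+"), `[[`, character(1), 1),
    description = headers,
    sequence = unname(sub("\\*+$", "", toupper(as.character(seqs))))
  )
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()]: headers are the stored `description` (falling
#' back to `id`), so `read_fasta(write_fasta(x, f))` reproduces ids and
#' sequences exactly.
#'
#' @param records Tibble with columns `id` and `sequence` (optionally
#'   `description`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  check_record_columns(records)
  headers <- records$id
  if ("description" %in% names(records)) {
    desc <- records$description
    headers <- ifelse(
      !nzchar(desc) | desc == records$id, records$id,
      ifelse(startsWith(desc, paste0(records$id, " ")) | desc == records$id,
             desc, paste(records$id, desc))
    )
  }
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

check_record_columns <- function(records) {
  if (!is.data.frame(records) || !all(c("id", "sequence") %in% names(records))) {
    stop("`records` must be a data frame with columns `id` and `sequence`",
         call. = FALSE)
  }
  invisible(records)
}

#' Validate amino-acid sequences against the standard alphabet
#'
#' Under `policy = "mask"` (the default), residues outside the 20-letter
#' alphabet are kept in place but recorded per record in the `nonstandard`
#' list-column; downstream encoders give them all-zero one-hot rows and
#' composition features exclude them from numerators while counting them in
#' length denominators. Under `policy = "strict"` any non-standard residue is
#' an error naming the record and positions.
#'
#' @param records Tibble with `id` and `sequence` columns.
#' @param policy `"mask"` or `"strict"`.
#' @return `records` with an added integer list-column `nonstandard` (positions
#'   of non-standard residues, possibly empty).
#' @examples
#' validate_sequences(tibble::tibble(id = "p", sequence = "MKXLL"))
#' @export
validate_sequences <- function(records, policy = c("mask", "strict")) {
  policy <- match.arg(policy)
  check_record_columns(records)
  if (any(!nzchar(records$sequence))) {
    stop("Empty sequence for record(s): ",
         paste(records$id[!nzchar(records$sequence)], collapse = ", "),
         call. = FALSE)
  }
  bad_pos <- purrr::map(records$sequence, function(s) {
    which(!(seq_chars(s) %in% aa_alphabet))
  })
  has_bad <- lengths(bad_pos) > 0
  if (policy == "strict" && any(has_bad)) {
    offender <- which(has_bad)[1]
    stop(
      "Non-standard residue(s) under strict policy in record '",
      records$id[offender], "' at position(s) ",
      paste(bad_pos[[offender]], collapse = ", "),
      if (sum(has_bad) > 1) {
        paste0(" (and ", sum(has_bad) - 1, " further record(s))")
      } else "",
      call. = FALSE
    )
  }
  if (any(has_bad)) {
    warning(sum(has_bad), " record(s) contain non-standard residues; ",
            "they are masked (zero one-hot rows, excluded from composition ",
            "numerators)", call. = FALSE)
  }
  records$nonstandard <- bad_pos
  records
}

#' Extract the N-terminal window of each sequence
#'
#' Returns the first `window` residues; sequences shorter than `window` are
#' returned whole (the encoder pads, see [one_hot_encode()]).
#'
#' @param sequence Character vector of sequences.
#' @param window Window length in residues (default 70).
#' @return Character vector of windows.
#' @export
n_terminal_window <- function(sequence, window = 70) {
  if (!is.numeric(window) || length(window) != 1 || window < 1) {
    stop("`window` must be a single integer >= 1", call. = FALSE)
  }
  substr(sequence, 1L, as.integer(window))
}

#' One-hot encode a sequence window
#'
#' Encodes a window as a `window_length` x 20 binary matrix. Row i carries a
#' single 1 in the column of residue i under the alphabetical ordering
#' ([aa_alphabet]: A=1, C=2, ..., Y=20). Rows past the end of the sequence
#' (C-terminal zero padding) and rows of non-standard residues are all zero,
#' so the matrix total equals the number of standard residues in the window.
#'
#' @param window A single sequence window (string). Windows longer than
#'   `window_length` are truncated to the first `window_length` residues.
#' @param window_length Number of rows of the output (default 70).
#' @return Integer matrix of dimension `window_length` x 20 with the alphabet
#'   as column names.
#' @examples
#' one_hot_encode("A", window_length = 1)
#' colSums(one_hot_encode("MKKLLF"))
#' @export
one_hot_encode <- function(window, window_length = 70) {
  stopifnot(is.character(window), length(window) == 1)
  if (!is.numeric(window_length) || length(window_length) != 1 ||
      window_length < 1) {
    stop("`window_length` must be a single integer >= 1", call. = FALSE)
  }
  window_length <- as.integer(window_length)
  m <- matrix(0L, nrow = window_length, ncol = 20,
              dimnames = list(NULL, aa_alphabet))
  idx <- aa_indices(window)
  if (length(idx) > window_length) idx <- idx[seq_len(window_length)]
  hit <- which(idx > 0L)
  m[cbind(hit, idx[hit])] <- 1L
  m
}

#' Join a TSV label table to loaded protein records
#'
#' The label table is a two-column TSV with header `id<TAB>label`. Labels must
#' come from the task's closed set (`sp`: SP, TM70, IN_CELL; `ups`: UPS,
#' INTRACELLULAR). Ids present on only one side are reported in the
#' `unmatched` attribute (and a warning); duplicate ids in the table are an
#' error.
#'
#' @param path Path to the label TSV.
#' @param records Tibble of records the labels refer to (from [read_fasta()]).
#' @param task `"sp"` or `"ups"`; selects the closed label set.
#' @return The matched records with an added `label` factor column; attribute
#'   `unmatched` lists ids found in only one input.
#' @export
read_label_table <- function(path, records, task = c("sp", "ups")) {
  task <- match.arg(task)
  check_record_columns(records)
  levels <- if (task == "sp") sp_label_levels else ups_label_levels
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("id", "label") %in% names(tab))) {
    stop("Label table must have columns `id` and `label`", call. = FALSE)
  }
  if (anyDuplicated(tab$id)) {
    stop("Duplicate id(s) in label table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(tab$label), levels)
  if (length(bad) > 0) {
    stop("Label(s) outside the closed set {", paste(levels, collapse = ", "),
         "}: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unmatched <- list(
    table_only = setdiff(tab$id, records$id),
    records_only = setdiff(records$id, tab$id)
  )
  if (length(unmatched$table_only) + length(unmatched$records_only) > 0) {
    warning(length(unmatched$table_only), " table id(s) and ",
            length(unmatched$records_only),
            " record id(s) had no counterpart", call. = FALSE)
  }
  out <- dplyr::inner_join(records, tab, by = "id")
  out$label <- factor(out$label, levels = levels)
  attr(out, "unmatched") <- unmatched
  out
}

#' Write a label table as TSV
#'
#' @param records Tibble with `id` and `label` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(records, path) {
  stopifnot(all(c("id", "label") %in% names(records)))
  readr::write_tsv(records[, c("id", "label")], path, progress = FALSE)
  invisible(path)
}
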