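#' Default segment scheme for positional group-frequency features
#'
#' Eight segments: the whole sequence; N-terminal 15/30/45; C-terminal
#' 15/30/45; and the middle remainder (sequence minus the first and last 45
#' residues, empty for sequences of 90 residues or fewer). Five group
#' frequencies per segment plus the 20 compositions and the molecular weight
#' give the 61-feature description. Segments shorter than their nominal size
#' use whatever residues exist.
#'
#' @return Tibble with columns `segment` (name), `anchor`
#'   (`whole`/`nterm`/`cterm`/`middle`) and `size` (residues, NA where not
#'   applicable).
#' @export
default_segment_scheme <- function() {
  tibble::tibble(
    segment = c("whole", "nterm15", "nterm30", "nterm45",
                "cterm15", "cterm30", "cterm45", "middle"),
    anchor  = c("whole", "nterm", "nterm", "nterm",
                "cterm", "cterm", "cterm", "middle"),
    size    = c(NA, 15, 30, 45, 15, 30, 45, NA)
  )
}

# Extract one segment from a sequence; may return "" (empty segment).
segment_substring <- function(sequence, anchor, size) {
  n <- nchar(sequence)
  switch(anchor,
    whole = sequence,
    nterm = substr(sequence, 1L, min(size, n)),
    cterm = substr(sequence, max(1L, n - size + 1L), n),
    middle = if (n > 90) substr(sequence, 46L, n - 45L) else "",
    stop("Unknown segment anchor: ", anchor, call. = FALSE)
  )
}

#' Amino-acid composition of a sequence
#'
#' Frequency of each standard residue: its count divided by the total sequence
#' length. Non-standard residues are excluded from numerators but count in the
#' denominator, so the 20 values sum to 1 only for all-standard sequences.
#'
#' @param sequence A single sequence string.
#' @return Named numeric vector of length 20 in [aa_alphabet] order.
#' @examples
#' aa_composition("AR")
#' @export
aa_composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!nzchar(sequence)) stop("Empty sequence", call. = FALSE)
  counts <- table(factor(seq_chars(sequence), levels = aa_alphabet))
  stats::setNames(as.numeric(counts) / nchar(sequence), aa_alphabet)
}

#' Average molecular weight of a protein
#'
#' Sum of Expasy average residue masses plus one water (18.01524 Da).
#' Non-standard residues contribute the mean standard-residue mass.
#'
#' @param sequence A single sequence string.
#' @return Molecular weight in Daltons.
#' @examples
#' molecular_weight("G") # glycine, ~75.07 Da
#' @export
molecular_weight <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!nzchar(sequence)) stop("Empty sequence", call. = FALSE)
  masses <- aa_residue_masses[seq_chars(sequence)]
  masses[is.na(masses)] <- mean(aa_residue_masses)
  sum(masses) + water_mass
}

#' Frequency of a residue group within a (possibly empty) segment
#'
#' Group-member count divided by segment length; an empty segment yields 0 by
#' convention (short proteins can leave the middle segment empty).
#'
#' @param sequence Segment string (may be `""`).
#' @param group Character vector of residues forming the group.
#' @return A frequency in `[0, 1]`.
#' @examples
#' group_frequency("KDKD", aa_groups()$pos_charged)
#' @export
group_frequency <- function(sequence, group) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  n <- nchar(sequence)
  if (n == 0) return(0)
  sum(seq_chars(sequence) %in% group) / n
}

#' Names of the 61 physicochemical features, in output order
#'
#' @param scheme Segment scheme, see [default_segment_scheme()].
#' @param groups Residue groups, see [aa_groups()].
#' @return Character vector: 20 compositions (`comp_A` ...), `mol_weight`,
#'   then `<group>_<segment>` for each segment and group.
#' @export
feature_names <- function(scheme = default_segment_scheme(),
                          groups = aa_groups()) {
  c(
    paste0("comp_", aa_alphabet),
    "mol_weight",
    as.vector(t(outer(scheme$segment, names(groups),
                      function(s, g) paste0(g, "_", s))))
  )
}

#' Generate the full physicochemical feature table
#'
#' One row per protein: the 20 amino-acid compositions, the molecular weight,
#' and the five group frequencies for each of the eight segments — 61 named
#' features under the default scheme.
#'
#' @param records Tibble with `id` and `sequence` columns (validated).
#' @param scheme Segment scheme tibble ([default_segment_scheme()]).
#' @param groups Named list of residue groups ([aa_groups()]).
#' @return Tibble: `id` plus one column per feature, in [feature_names()]
#'   order.
#' @examples
#' generate_features(tibble::tibble(id = "p", sequence = strrep("ARND", 30)))
#' @export
generate_features <- function(records, scheme = default_segment_scheme(),
                              groups = aa_groups()) {
  check_record_columns(records)
  if (any(!nzchar(records$sequence))) stop("Empty sequence", call. = FALSE)
  rows <- purrr::map(records$sequence, function(s) {
    segs <- purrr::map_chr(seq_len(nrow(scheme)), function(i) {
      segment_substring(s, scheme$anchor[i], scheme$size[i])
    })
    seg_freqs <- purrr::map(segs, function(seg) {
      purrr::map_dbl(groups, function(g) group_frequency(seg, g))
    })
    c(aa_composition(s), mol_weight = molecular_weight(s),
      unlist(seg_freqs, use.names = FALSE))
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- feature_names(scheme, groups)
  dplyr::bind_cols(tibble::tibble(id = records$id), tibble::as_tibble(mat))
}

#' Names of the eight features used by the UPS classifier
#'
#' Molecular weight; small, hydrophobic and positively charged frequencies in
#' the C-terminal 15 residues; positively charged frequency over the whole
#' sequence; and the tryptophan, phenylalanine and arginine compositions.
#'
#' @return Character vector of length 8.
#' @export
ups_feature_names <- function() {
  c("mol_weight", "small_cterm15", "hydrophobic_cterm15",
    "pos_charged_cterm15", "pos_charged_whole", "comp_W", "comp_F", "comp_R")
}

#' Restrict a full feature table to the UPS feature subset
#'
#' Pure column selection from the 61-feature table — values are never
#' recomputed, so the subset is numerically identical to the corresponding
#' entries of the full vector.
#'
#' @param features Feature tibble from [generate_features()].
#' @return Tibble: `id` (and `label`, if present) plus the 8 UPS features.
#' @export
ups_feature_subset <- function(features) {
  wanted <- ups_feature_names()
  missing <- setdiff(wanted, names(features))
  if (length(missing) > 0) {
    stop("Feature table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- intersect(c("id", "label"), names(features))
  features[, c(keep, wanted)]
}

#' Write a feature table as TSV
#'
#' @param features Feature tibble ( `id` + named feature columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  readr::write_tsv(features, path, progress = FALSE)
  invisible(path)
}
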