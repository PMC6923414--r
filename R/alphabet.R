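#' The 20-letter amino-acid alphabet, in strict alphabetical order
#'
#' One-hot columns, composition features and every alphabet-ordered output in
#' the package follow this constant: A=1, C=2, D=3, ..., Y=20.
#'
#' @format Character vector of length 20.
#' @export
aa_alphabet <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Ambiguity and non-standard residue codes tolerated under the mask policy
#'
#' B (Asx), Z (Glx), J (Leu/Ile), X (unknown), U (selenocysteine), O
#' (pyrrolysine). Under `policy = "mask"` these stay in the sequence but are
#' treated as non-standard: all-zero one-hot rows, excluded from composition
#' numerators while still counting toward length denominators.
#'
#' @format Character vector of length 6.
#' @export
aa_ambiguity_codes <- c("B", "Z", "J", "X", "U", "O")

#' Physicochemical amino-acid groups
#'
#' Standard Taylor-style groupings used for the segment features. Groups may
#' overlap (e.g. A is both hydrophobic and small); positively charged {K,R,H}
#' and negatively charged {D,E} are fixed.
#'
#' @return Named list of five character vectors: `hydrophobic`, `polar`,
#'   `pos_charged`, `neg_charged`, `small`.
#' @examples
#' aa_groups()$pos_charged
#' @export
aa_groups <- function() {
  list(
    hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "C"),
    polar       = c("S", "T", "N", "Q", "Y", "H"),
    pos_charged = c("K", "R", "H"),
    neg_charged = c("D", "E"),
    small       = c("A", "G", "S", "C", "T", "P", "D", "N", "V")
  )
}

# Expasy average residue masses (Da); free-chain mass = sum + one water.
aa_residue_masses <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760
)

water_mass <- 18.01524

# Closed label sets for the two classification tasks.
sp_label_levels  <- c("SP", "TM70", "IN_CELL")
ups_label_levels <- c("UPS", "INTRACELLULAR")

# Split a sequence string into single characters.
seq_chars <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

# Integer index of each residue in aa_alphabet; 0 for non-standard codes.
# This indexed form is what the network consumes (column 0 = all-zero one-hot).
aa_indices <- function(sequence) {
  idx <- match(seq_chars(sequence), aa_alphabet)
  idx[is.na(idx)] <- 0L
  idx
}
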