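#' @keywords internal
"_PACKAGE"

# Canonical residue ordering used everywhere internally: alphabetical
# one-letter codes, matching the p_A..p_Y column order of state tables.
AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP <- "-"
UNKNOWN <- "X"
ALPHABET <- c(AA, GAP, UNKNOWN)

aa_index <- stats::setNames(seq_along(AA), AA)

#' Amino-acid alphabet
#'
#' The 20 canonical amino acids in the alphabetical one-letter order used
#' throughout the package (the order of the `p_A` .. `p_Y` columns of state
#' tables).
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() AA

# Map residue characters to 1..20, with NA for gap/'X' (fully missing).
encode_residues <- function(x) {
  idx <- match(x, AA)
  idx[x %in% c(GAP, UNKNOWN)] <- NA_integer_
  idx
}
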