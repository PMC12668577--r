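#' Construct an amino-acid alignment
#'
#' An alignment is stored as a character matrix with one row per sequence,
#' one column per alignment column, and row names giving the (unique)
#' sequence identifiers. Legal characters are the 20 amino acids, `-` (gap)
#' and `X` (unknown residue, treated as fully missing in likelihood
#' computations). Lowercase letters are upper-cased and `.` is normalized to
#' `-` on construction.
#'
#' @param seqs Named character vector of aligned sequences (equal lengths),
#'   or a character matrix of single residues with row names.
#' @param column_mask Optional logical vector, one element per column:
#'   `TRUE` for columns retained in reconstruction, `FALSE` for stripped
#'   loop/tail columns. Defaults to all retained.
#' @return An object of class `aa_alignment`.
#' @export
aa_alignment <- function(seqs, column_mask = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
    if (nrow(m) > 0 && is.null(rownames(m))) {
      stop("alignment matrix must have row names (sequence ids)")
    }
  } else {
    if (length(seqs) == 0) stop("empty input: no sequences")
    ids <- names(seqs)
    if (is.null(ids) || any(!nzchar(ids))) stop("all sequences must have non-empty ids")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) {
      bad <- names(seqs)[lens != lens[1]]
      stop(sprintf("alignment error: unequal sequence lengths (e.g. '%s')", bad[1]))
    }
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- ids
  }
  m[] <- toupper(m)
  m[m == "."] <- GAP
  if (anyDuplicated(rownames(m))) {
    stop(sprintf("id error: duplicate sequence id '%s'",
                 rownames(m)[duplicated(rownames(m))][1]))
  }
  bad <- which(!(m %in% ALPHABET))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop(sprintf("alphabet error: illegal character '%s' in sequence '%s' at column %d",
                 m[bad[1]], rownames(m)[i], j))
  }
  if (is.null(column_mask)) column_mask <- rep(TRUE, ncol(m))
  if (length(column_mask) != ncol(m)) stop("column_mask length must equal number of columns")
  structure(m, column_mask = as.logical(column_mask), class = c("aa_alignment", "matrix"))
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("Amino-acid alignment: %d sequences x %d columns (%d retained)\n",
              nrow(x), ncol(x), sum(attr(x, "column_mask"))))
  show <- utils::head(rownames(x), 5)
  for (id in show) {
    row <- paste(x[id, seq_len(min(ncol(x), 60))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", id, row, if (ncol(x) > 60) "..." else ""))
  }
  if (nrow(x) > 5) cat(sprintf("  ... and %d more\n", nrow(x) - 5))
  invisible(x)
}

n_cols <- function(alignment) ncol(alignment)

alignment_strings <- function(alignment) {
  apply(unclass(alignment), 1, paste, collapse = "")
}

# Subset rows keeping class/attributes coherent.
subset_rows <- function(alignment, keep) {
  m <- unclass(alignment)[keep, , drop = FALSE]
  aa_alignment(m, column_mask = attr(alignment, "column_mask"))
}
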