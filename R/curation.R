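ungap <- function(s) gsub("[-]", "", s)

# Fraction identity between two sequences (strings). For equal-length
# (aligned) inputs, matches are counted over columns where both are
# non-gap; the denominator is the shorter ungapped length. Unequal-length
# unaligned inputs are compared positionally over the shorter length (no
# alignment is computed).
seq_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- min(length(ca), length(cb))
  ca2 <- ca[seq_len(n)]
  cb2 <- cb[seq_len(n)]
  both <- ca2 != "-" & cb2 != "-"
  matches <- sum(ca2[both] == cb2[both])
  denom <- min(nchar(ungap(a)), nchar(ungap(b)))
  if (denom == 0) return(0)
  matches / denom
}

#' Greedy identity clustering of sequences
#'
#' Deterministic greedy incremental clustering in the CD-HIT style:
#' sequences are sorted by descending ungapped length (ties keep input
#' order); each sequence joins the earliest-founded cluster whose
#' representative shares at least `threshold` identity (matches divided by
#' the length of the shorter ungapped sequence), otherwise it founds a new
#' cluster. Results are not bit-identical to CD-HIT, which applies
#' word-filter heuristics.
#'
#' @param records Named character vector of sequences (aligned or not), or
#'   an [aa_alignment].
#' @param threshold Identity fraction in (0, 1].
#' @return List with `representatives` (ids), `members` (data frame
#'   `cluster_id`, `representative`, `member`).
#' @export
cluster_by_identity <- function(records, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("parameter error: threshold must be in (0, 1]")
  }
  if (inherits(records, "aa_alignment")) records <- alignment_strings(records)
  if (length(records) == 0) {
    return(list(representatives = character(0),
                members = data.frame(cluster_id = integer(0),
                                     representative = character(0),
                                     member = character(0))))
  }
  ord <- order(-nchar(ungap(records)), seq_along(records))
  ids <- names(records)[ord]
  seqs <- records[ord]
  reps <- character(0)
  rep_seqs <- character(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- 0L
    for (c in seq_along(reps)) {
      if (seq_identity(seqs[i], rep_seqs[c]) >= threshold) { placed <- c; break }
    }
    if (placed == 0L) {
      reps <- c(reps, ids[i])
      rep_seqs <- c(rep_seqs, seqs[i])
      placed <- length(reps)
    }
    assign[i] <- placed
  }
  list(representatives = reps,
       members = data.frame(cluster_id = assign, representative = reps[assign],
                            member = ids, stringsAsFactors = FALSE))
}

#' Filter alignment rows by gap fraction and ambiguity
#'
#' Removes rows containing `X` (when `drop_ambiguous`) and rows whose gap
#' fraction over retained columns exceeds `max_gap_fraction`. The default
#' gap threshold (0.25) operationalizes the manual removal of sequences
#' with major gaps or insertions; it is a configurable guess.
#'
#' @param alignment An [aa_alignment].
#' @param max_gap_fraction Maximum allowed gap fraction (default 0.25).
#' @param drop_ambiguous Drop rows containing `X` (default TRUE).
#' @return Filtered [aa_alignment] with attribute `removals` (data frame
#'   `id`, `reason`). Warns and returns a 0-row alignment if everything is
#'   removed.
#' @export
filter_sequences <- function(alignment, max_gap_fraction = 0.25,
                             drop_ambiguous = TRUE) {
  mask <- attr(alignment, "column_mask")
  m <- unclass(alignment)
  sub <- m[, mask, drop = FALSE]
  gapfrac <- rowMeans(sub == GAP)
  has_x <- apply(m == UNKNOWN, 1, any)
  reason <- rep(NA_character_, nrow(m))
  reason[gapfrac > max_gap_fraction] <- sprintf("gap fraction %.3f > %.3f",
                                                gapfrac[gapfrac > max_gap_fraction],
                                                max_gap_fraction)
  if (drop_ambiguous) reason[has_x] <- "contains ambiguous residue 'X'"
  drop <- !is.na(reason)
  removals <- data.frame(id = rownames(m)[drop], reason = reason[drop],
                         stringsAsFactors = FALSE)
  if (all(drop)) warning("all sequences removed by filtering")
  out <- aa_alignment(m[!drop, , drop = FALSE], column_mask = mask)
  attr(out, "removals") <- removals
  out
}

#' Restrict an alignment to retained columns
#'
#' @param alignment An [aa_alignment].
#' @param column_mask Logical vector (length `n_cols`): TRUE = keep.
#' @return [aa_alignment] over the retained columns with attribute
#'   `column_map` giving, for each retained column, its original column
#'   index (use [unmap_columns] to invert).
#' @export
strip_columns <- function(alignment, column_mask) {
  m <- unclass(alignment)
  if (length(column_mask) != ncol(m)) {
    stop("mask/alignment length mismatch")
  }
  keep <- which(column_mask)
  out <- aa_alignment(m[, keep, drop = FALSE])
  attr(out, "column_map") <- keep
  out
}

#' Map retained-column indices back to original columns
#'
#' @param stripped Result of [strip_columns].
#' @param idx Retained-column indices.
#' @return Original column indices.
#' @export
unmap_columns <- function(stripped, idx) {
  map <- attr(stripped, "column_map")
  if (is.null(map)) stop("no column_map attribute: not a strip_columns result")
  if (any(idx < 1 | idx > length(map))) stop("index out of range")
  map[idx]
}

#' Build a reference-numbering map
#'
#' Maps 1-based residue numbers of the ungapped reference sequence to
#' alignment column indices; the bijection behind dual `ref:target`
#' numbering.
#'
#' @param alignment An [aa_alignment].
#' @param reference_id Row id of the reference sequence.
#' @return An object of class `reference_map`: integer vector of column
#'   indices named by reference residue number, with attributes
#'   `reference_id` and `length`.
#' @export
build_reference_map <- function(alignment, reference_id) {
  m <- unclass(alignment)
  if (!reference_id %in% rownames(m)) {
    stop(sprintf("reference id '%s' not found in alignment", reference_id))
  }
  row <- m[reference_id, ]
  cols <- which(row != GAP)
  map <- stats::setNames(cols, seq_along(cols))
  structure(map, reference_id = reference_id, length = length(cols),
            class = "reference_map")
}

#' @export
print.reference_map <- function(x, ...) {
  cat(sprintf("Reference map: '%s', %d residues -> alignment columns\n",
              attr(x, "reference_id"), attr(x, "length")))
  invisible(x)
}

#' Look up alignment columns for reference residue numbers
#'
#' @param map A [build_reference_map] result.
#' @param positions Reference residue numbers (1-based).
#' @return Alignment column indices.
#' @export
map_ref_to_col <- function(map, positions) {
  n <- attr(map, "length")
  if (any(positions < 1 | positions > n)) {
    stop(sprintf("lookup error: reference position outside 1..%d", n))
  }
  unname(map[as.character(positions)])
}

# Inverse lookup: alignment column -> reference residue number (NA if the
# column is a gap in the reference).
map_col_to_ref <- function(map, cols) {
  idx <- match(cols, unclass(map))
  as.integer(names(map)[idx])
}

#' Resolve reference-numbered spans to alignment columns
#'
#' @param spans List of `c(start, end)` pairs, or a two-column matrix/data
#'   frame of inclusive reference residue numbers.
#' @param map A [build_reference_map] result.
#' @return Sorted unique alignment column indices; positions that fall
#'   outside the reference are recorded in the `skipped` attribute rather
#'   than raising an error.
#' @export
resolve_columns <- function(spans, map) {
  if (is.data.frame(spans) || is.matrix(spans)) {
    spans <- lapply(seq_len(nrow(spans)), function(i) as.numeric(spans[i, 1:2]))
  }
  if (length(spans) == 0) {
    out <- integer(0)
    attr(out, "skipped") <- integer(0)
    return(out)
  }
  n <- attr(map, "length")
  positions <- unlist(lapply(spans, function(sp) seq(sp[1], sp[2])))
  ok <- positions >= 1 & positions <= n
  skipped <- positions[!ok]
  cols <- sort(unique(map_ref_to_col(map, positions[ok])))
  attr(cols, "skipped") <- skipped
  cols
}
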