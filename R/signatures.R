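#' Construct a signature scheme
#'
#' A scheme is a set of constraints `(reference residue number, allowed
#' residue set)` diagnostic of an ion-coupling mode. Bundled schemes (see
#' [read_scheme]) are keyed to Glt_Ph numbering: `na_complete` is the full
#' Na+-binding residue set ([S/T]92-93, N310, [M/S]311, [D/E]312,
#' [D/E]405), `h_signature` the H+-coupling set ([A/L/I/V/M/F]92, L311,
#' N405), and `h_transition` the main-text transition variant.
#'
#' @param positions Integer reference residue numbers (unique).
#' @param allowed List of character vectors of allowed residues, one per
#'   position.
#' @param name Scheme name.
#' @return Object of class `signature_scheme`.
#' @export
signature_scheme <- function(positions, allowed, name = "custom") {
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) stop("scheme positions must be unique")
  if (length(allowed) != length(positions)) stop("one allowed set per position")
  allowed <- lapply(allowed, function(a) {
    a <- toupper(a)
    if (length(a) == 0 || !all(a %in% AA)) stop("allowed sets must be non-empty amino-acid subsets")
    a
  })
  structure(list(positions = positions, allowed = allowed, name = name),
            class = "signature_scheme")
}

#' @export
print.signature_scheme <- function(x, ...) {
  cat(sprintf("Signature scheme '%s': %d constraint(s)\n", x$name, length(x$positions)))
  for (i in seq_along(x$positions)) {
    cat(sprintf("  [%s]%d\n", paste(x$allowed[[i]], collapse = "/"), x$positions[i]))
  }
  invisible(x)
}

#' Test a sequence against a signature scheme
#'
#' @param alignment An [aa_alignment] (or a single aligned row as a
#'   character string).
#' @param id Row id to test (ignored when `alignment` is a string).
#' @param scheme A [signature_scheme].
#' @param reference_map A [build_reference_map] result for the alignment.
#' @param unmappable `"fail"` (default) or `"skip"`: what an unmappable
#'   scheme position does to the verdict.
#' @return Logical (`TRUE` iff every constrained, mapped position carries an
#'   allowed residue; a gap fails its constraint) with attribute `detail`, a
#'   per-constraint data frame.
#' @export
matches_signature <- function(alignment, id = NULL, scheme, reference_map,
                              unmappable = c("fail", "skip")) {
  unmappable <- match.arg(unmappable)
  if (inherits(alignment, "aa_alignment")) {
    if (is.null(id)) stop("give the row id to test")
    row <- unclass(alignment)[id, ]
  } else {
    row <- strsplit(toupper(alignment), "")[[1]]
  }
  n <- attr(reference_map, "length")
  detail <- data.frame(position = scheme$positions,
                       allowed = vapply(scheme$allowed, paste, "", collapse = "/"),
                       column = NA_integer_, residue = NA_character_,
                       pass = NA, note = "", stringsAsFactors = FALSE)
  for (i in seq_along(scheme$positions)) {
    pos <- scheme$positions[i]
    if (pos < 1 || pos > n) {
      detail$pass[i] <- (unmappable == "skip")
      detail$note[i] <- "position not mappable through reference"
      next
    }
    col <- map_ref_to_col(reference_map, pos)
    res <- row[col]
    detail$column[i] <- col
    detail$residue[i] <- res
    if (res == GAP) {
      detail$pass[i] <- FALSE
      detail$note[i] <- sprintf("gap at %d", pos)
    } else {
      detail$pass[i] <- res %in% scheme$allowed[[i]]
    }
  }
  ok <- all(detail$pass)
  attr(ok, "detail") <- detail
  ok
}

#' Assign tree leaves to clades by subtree-root labels
#'
#' @param tree A rooted `ape::phylo` with internal node labels.
#' @param clade_nodes Named character vector: clade label -> internal node
#'   label whose descendant leaves form the clade.
#' @return Named character vector mapping leaf id -> clade label
#'   (`"unassigned"` for leaves under none of the nodes). Errors if clades
#'   overlap.
#' @export
assign_clades <- function(tree, clade_nodes) {
  tree <- label_internal_nodes(tree)
  ntip <- length(tree$tip.label)
  out <- stats::setNames(rep("unassigned", ntip), tree$tip.label)
  for (lab in names(clade_nodes)) {
    nd <- match(clade_nodes[[lab]], tree$node.label)
    if (is.na(nd)) stop(sprintf("clade node label '%s' not in tree", clade_nodes[[lab]]))
    tips <- tree$tip.label[phangorn_free_descendants(tree, ntip + nd)]
    clash <- tips[out[tips] != "unassigned"]
    if (length(clash)) stop(sprintf("clades overlap at leaf '%s'", clash[1]))
    out[tips] <- lab
  }
  out
}

# Tip numbers descending from an internal node (iterative, no extra deps).
phangorn_free_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  stack <- node
  tips <- integer(0)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) next
    tips <- c(tips, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  sort(tips)
}

#' Per-clade signature statistics
#'
#' @param alignment An [aa_alignment].
#' @param clades Named character vector leaf id -> clade label (see
#'   [assign_clades]).
#' @param scheme A [signature_scheme].
#' @param reference_map A [build_reference_map] result.
#' @return Data frame with `clade`, `n`, `n_matching`, `percent` (one
#'   decimal; `NA` for empty clades).
#' @export
clade_signature_stats <- function(alignment, clades, scheme, reference_map) {
  labs <- setdiff(unique(clades), "unassigned")
  rows <- lapply(labs, function(cl) {
    ids <- names(clades)[clades == cl]
    ids <- intersect(ids, rownames(alignment))
    n <- length(ids)
    nm <- sum(vapply(ids, function(id)
      as.logical(matches_signature(alignment, id, scheme, reference_map)), logical(1)))
    data.frame(clade = cl, n = n, n_matching = nm,
               percent = if (n > 0) round(100 * nm / n, 1) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Pairwise percent-identity matrix
#'
#' `identity(a, b) = 100 * matches / compared`, where `compared` counts the
#' selected columns at which both sequences are non-gap. Symmetric with a
#' diagonal of 100; pairs with zero comparable columns get `NA` with a
#' warning.
#'
#' @param alignment An [aa_alignment] (>= 2 rows).
#' @param columns Optional column subset (default: all columns).
#' @return Symmetric numeric matrix of percentages.
#' @export
pairwise_identity <- function(alignment, columns = NULL) {
  m <- unclass(alignment)
  if (nrow(m) < 2) stop("need at least 2 sequences")
  if (!is.null(columns)) m <- m[, columns, drop = FALSE]
  n <- nrow(m)
  out <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- m[i, ] != GAP & m[j, ] != GAP
      cmp <- sum(both)
      if (cmp == 0) {
        out[i, j] <- out[j, i] <- NA_real_
        warned <- TRUE
      } else {
        out[i, j] <- out[j, i] <- 100 * sum(m[i, both] == m[j, both]) / cmp
      }
    }
  }
  if (warned) warning("pair(s) with zero comparable columns set to NA")
  out
}

parse_mutation <- function(token) {
  m <- regmatches(token, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", token))[[1]]
  if (length(m) != 4) stop(sprintf("parse error: malformed mutation token '%s'", token))
  list(from = toupper(m[2]), pos = as.integer(m[3]), to = toupper(m[4]))
}

#' Apply point mutations in reference numbering
#'
#' Mutations are given as `"X<refpos>Y"` tokens (e.g. `"K105H"`): the
#' residue at the mapped position must equal `X` and is replaced by `Y`.
#' Applying a mutation and then its reverse restores the input.
#'
#' @param sequence Character string (aligned row or plain sequence).
#' @param mutations Character vector of mutation tokens.
#' @param reference_map A [build_reference_map] result whose columns index
#'   into `sequence`.
#' @return The mutated sequence string with attribute `log` (data frame of
#'   applied changes).
#' @export
apply_mutations <- function(sequence, mutations, reference_map) {
  chars <- strsplit(sequence, "")[[1]]
  log <- data.frame(position = integer(0), column = integer(0),
                    from = character(0), to = character(0))
  for (tok in mutations) {
    mu <- parse_mutation(tok)
    col <- map_ref_to_col(reference_map, mu$pos)
    if (chars[col] != mu$from) {
      stop(sprintf("expected-residue error: position %d has '%s', mutation '%s' expects '%s'",
                   mu$pos, chars[col], tok, mu$from))
    }
    chars[col] <- mu$to
    log <- rbind(log, data.frame(position = mu$pos, column = col,
                                 from = mu$from, to = mu$to))
  }
  out <- paste(chars, collapse = "")
  attr(out, "log") <- log
  out
}

#' Assemble an expression construct from an ancestor and a donor
#'
#' Builds a full-length protein sequence by interleaving the reconstructed
#' ancestor (over retained columns) with loop/tail residues grafted from a
#' donor row of the full (unstripped) alignment, then applies validated
#' point mutations in reference numbering. Mirrors the construct-design step
#' in which variable loops and tails excluded from reconstruction are taken
#' from a closely related extant sequence.
#'
#' @param ancestor_states Character vector (or string) of ancestor residues,
#'   one per retained column.
#' @param full_alignment The unstripped [aa_alignment] containing the donor.
#' @param donor_id Donor row id.
#' @param column_mask Logical vector over the full alignment: TRUE =
#'   retained (ancestor provides the residue), FALSE = stripped (donor
#'   provides it).
#' @param mutations Optional mutation tokens in reference numbering,
#'   validated against the assembled sequence.
#' @param reference_map Optional [build_reference_map] over the full
#'   alignment; required when `mutations` are given.
#' @return Ungapped construct sequence (string) with attribute `log`
#'   listing every grafted span and substitution.
#' @export
design_construct <- function(ancestor_states, full_alignment, donor_id,
                             column_mask, mutations = NULL,
                             reference_map = NULL) {
  m <- unclass(full_alignment)
  if (!donor_id %in% rownames(m)) stop(sprintf("donor '%s' not in alignment", donor_id))
  if (length(column_mask) != ncol(m)) stop("column_mask length mismatch")
  if (length(ancestor_states) == 1 && nchar(ancestor_states[1]) > 1) {
    ancestor_states <- strsplit(ancestor_states, "")[[1]]
  }
  if (length(ancestor_states) != sum(column_mask)) {
    stop("ancestor length must equal the number of retained columns")
  }
  donor <- m[donor_id, ]
  if (any(donor[!column_mask] == GAP)) {
    stop(sprintf("donor '%s' has a gap inside a graft span (column %d)",
                 donor_id, which(!column_mask & donor == GAP)[1]))
  }
  full <- character(ncol(m))
  full[column_mask] <- ancestor_states
  full[!column_mask] <- donor[!column_mask]
  # grafted spans (runs of stripped columns), for the change log
  r <- rle(!column_mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  graft <- data.frame(start_col = starts[r$values], end_col = ends[r$values],
                      source = rep(donor_id, sum(r$values)))
  if (!is.null(mutations) && length(mutations)) {
    if (is.null(reference_map)) stop("mutations require a reference_map")
    mutated <- apply_mutations(paste(full, collapse = ""), mutations, reference_map)
    mlog <- attr(mutated, "log")
    full <- strsplit(as.character(mutated), "")[[1]]
  } else {
    mlog <- data.frame(position = integer(0), column = integer(0),
                       from = character(0), to = character(0))
  }
  seq <- paste(full[full != GAP], collapse = "")
  structure(seq, log = list(grafts = graft, mutations = mlog))
}
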