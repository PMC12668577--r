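#' Read an aligned protein FASTA file
#'
#' @param path Path to a FASTA file of aligned amino-acid sequences.
#' @return An [aa_alignment].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0) stop("empty-input error: FASTA file is empty")
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0) stop("empty-input error: no FASTA records")
  seqs <- vapply(recs, function(r) as.character(r)[1], character(1))
  names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1))
  aa_alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param alignment An [aa_alignment] (or named character vector of sequences).
#' @param path Output path.
#' @export
write_fasta <- function(alignment, path) {
  if (inherits(alignment, "aa_alignment")) {
    seqs <- alignment_strings(alignment)
  } else {
    seqs <- alignment
  }
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 60)
  invisible(path)
}

#' Read a rooted or unrooted Newick tree
#'
#' Wraps the ape parser with validation: missing branch lengths default to
#' zero, negative branch lengths are rejected, and internal nodes without
#' labels are assigned stable labels `Node1`, `Node2`, ... (in ape node
#' order) so that ancestors can be addressed by name.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(gsub("\\s", "", txt))) stop("empty-input error: no Newick string")
  no <- gsub("[^()]", "", txt)
  if (nchar(gsub("\\(", "", no)) != nchar(gsub("\\)", "", no))) {
    stop("parse error: unbalanced parentheses in Newick input")
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop(sprintf("parse error: %s", conditionMessage(e))))
  if (is.null(tree)) stop("parse error: invalid Newick input")
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  if (anyNA(tree$edge.length)) tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(!is.finite(tree$edge.length))) stop("parse error: non-finite branch length")
  if (any(tree$edge.length < 0)) stop("parse error: negative branch length")
  tree <- label_internal_nodes(tree)
  tree
}

#' Assign labels to unlabeled internal nodes
#'
#' @param tree An `ape::phylo` tree.
#' @return The tree with every internal node labeled (`Node<k>` where absent).
#' @export
label_internal_nodes <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  empty <- !nzchar(lab) | is.na(lab)
  lab[empty] <- paste0("Node", which(empty))
  tree$node.label <- lab
  tree
}

#' Write a tree to Newick
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

state_table_cols <- function() c("Node", "Site", "State", paste0("p_", AA))

#' Read a per-node posterior state table
#'
#' Tab-separated with one header line; required columns are `Node`, `Site`,
#' `State` and `p_A` ... `p_Y` (alphabetical one-letter order). Extra leading
#' columns (as some reconstruction tools emit) are tolerated and ignored.
#'
#' @param path Path to the table.
#' @param state_mismatch What to do when `State` is not the argmax of the
#'   probabilities: `"warn"` (default) or `"error"`.
#' @return A `data.frame` with the canonical columns.
#' @export
read_state_table <- function(path, state_mismatch = c("warn", "error")) {
  state_mismatch <- match.arg(state_mismatch)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- state_table_cols()
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("state-table error: missing column(s) %s", paste(missing, collapse = ", ")))
  }
  df <- df[, need]
  p <- as.matrix(df[, paste0("p_", AA)])
  if (anyNA(p) || !is.numeric(p)) stop("state-table error: probabilities must be numeric")
  s <- rowSums(p)
  bad <- which(abs(s - 1) > 1e-4)
  if (length(bad)) {
    stop(sprintf("normalization error: row %d (node '%s', site %d) probabilities sum to %.6f",
                 bad[1], df$Node[bad[1]], df$Site[bad[1]], s[bad[1]]))
  }
  argmax <- AA[max.col(p, ties.method = "first")]
  off <- which(argmax != df$State)
  if (length(off)) {
    msg <- sprintf("state-table consistency: %d row(s) where State is not the argmax (first: node '%s', site %d)",
                   length(off), df$Node[off[1]], df$Site[off[1]])
    if (state_mismatch == "error") stop(msg) else warning(msg)
  }
  for (node in unique(df$Node)) {
    sites <- sort(df$Site[df$Node == node])
    if (!identical(sites, seq(min(sites), max(sites)))) {
      stop(sprintf("state-table error: non-contiguous site indices for node '%s'", node))
    }
  }
  df
}

#' Write a posterior state table
#'
#' @param state_table A data frame as returned by [read_state_table] or
#'   [as_state_table].
#' @param path Output path.
#' @export
write_state_table <- function(state_table, path) {
  utils::write.table(state_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a substitution-model parameter file
#'
#' Flat text with named blocks. `[frequencies]` holds 20 numbers
#' (alphabetical residue order, whitespace/newline separated);
#' `[exchangeabilities]` holds the 19 lower-triangle rows of the symmetric
#' exchangeability matrix in the same order; the optional `[categories]`
#' block holds one `weight rate` pair per line. Values copied out of a tree
#' program's report parse as long as the block structure is supplied.
#'
#' @param path Path to the file.
#' @return A [substitution_model].
#' @export
read_model_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  heads <- grep("^\\[.+\\]$", lines)
  if (!length(heads)) stop("model-file error: no [block] headers found")
  blocks <- list()
  for (i in seq_along(heads)) {
    name <- gsub("^\\[|\\]$", "", lines[heads[i]])
    from <- heads[i] + 1
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    body <- if (from <= to) lines[from:to] else character(0)
    blocks[[tolower(name)]] <- body
  }
  nums <- function(x) as.numeric(unlist(strsplit(paste(x, collapse = " "), "\\s+")))
  if (is.null(blocks$frequencies)) stop("model-file error: missing [frequencies] block")
  pi <- nums(blocks$frequencies)
  if (length(pi) != 20) stop("model-file error: [frequencies] must hold 20 values")
  if (is.null(blocks$exchangeabilities)) stop("model-file error: missing [exchangeabilities] block")
  ex <- nums(blocks$exchangeabilities)
  if (length(ex) != 190) stop("model-file error: [exchangeabilities] must hold 190 lower-triangle values")
  S <- matrix(0, 20, 20, dimnames = list(AA, AA))
  # rows are written row-major (row i holds S[i, 1:(i-1)]); filling the
  # upper triangle column-major visits the same (j, i) sequence
  S[upper.tri(S)] <- ex
  S <- S + t(S)
  cats <- data.frame(weight = 1, rate = 1)
  if (!is.null(blocks$categories)) {
    v <- nums(blocks$categories)
    if (length(v) %% 2 != 0) stop("model-file error: [categories] must hold weight/rate pairs")
    cm <- matrix(v, ncol = 2, byrow = TRUE)
    cats <- data.frame(weight = cm[, 1], rate = cm[, 2])
  }
  substitution_model(S, pi, cats)
}

#' Write a substitution model to a parameter file
#'
#' @param model A [substitution_model].
#' @param path Output path.
#' @export
write_model_file <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("[frequencies]", con)
  writeLines(paste(sprintf("%.10g", model$pi), collapse = " "), con)
  writeLines("[exchangeabilities]", con)
  for (i in 2:20) {
    writeLines(paste(sprintf("%.10g", model$S[i, 1:(i - 1)]), collapse = " "), con)
  }
  writeLines("[categories]", con)
  for (k in seq_len(nrow(model$categories))) {
    writeLines(sprintf("%.10g %.10g", model$categories$weight[k],
                       model$categories$rate[k]), con)
  }
  invisible(path)
}

#' Read a signature-scheme file
#'
#' Tab-separated with columns `ref_position` (reference residue number) and
#' `allowed_residues` (a string of allowed one-letter codes).
#'
#' @param path Path to the scheme file, or the name of a bundled scheme
#'   (`"na_complete"`, `"h_signature"`, `"h_transition"`).
#' @return A [signature_scheme].
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) {
    bundled <- system.file("extdata", paste0("scheme_", path, ".tsv"), package = "asrkit")
    if (nzchar(bundled)) path <- bundled else stop(sprintf("file not found: %s", path))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("ref_position", "allowed_residues") %in% names(df))) {
    stop("scheme error: need columns ref_position, allowed_residues")
  }
  signature_scheme(df$ref_position, strsplit(toupper(df$allowed_residues), ""),
                   name = sub("\\.tsv$", "", basename(path)))
}

#' Read a gene-neighborhood table
#'
#' Tab-separated with columns `genome_id`, `gene_index`, `gene_id`,
#' `is_transporter` (logical or 0/1) and `annotations`
#' (semicolon-separated labels).
#'
#' @param path Path to the table.
#' @return A validated gene-table `data.frame`.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_gene_table(df)
}

validate_gene_table <- function(df) {
  need <- c("genome_id", "gene_index", "gene_id", "is_transporter", "annotations")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("gene-table error: missing column(s) %s", paste(missing, collapse = ", ")))
  }
  df$is_transporter <- as.logical(df$is_transporter)
  df$gene_index <- as.integer(df$gene_index)
  for (g in unique(df$genome_id)) {
    idx <- sort(df$gene_index[df$genome_id == g])
    if (anyDuplicated(idx)) stop(sprintf("gene-table error: duplicate gene_index in genome '%s'", g))
    if (!identical(idx, seq(min(idx), max(idx)))) {
      stop(sprintf("gene-table error: non-consecutive gene_index in genome '%s'", g))
    }
  }
  df
}
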