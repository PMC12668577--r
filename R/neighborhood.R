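#' Gene-neighborhood enzyme pairing
#'
#' A transporter is considered paired when a gene annotated with one of the
#' enzyme labels lies within `window` gene ranks of it on the same genome
#' (1 <= |index difference| <= window; distance is ordinal gene rank,
#' ignoring strand). Transporters whose genome has no other gene rows are
#' excluded from the denominator with a warning, mirroring the exclusion of
#' transporters without neighborhood information.
#'
#' @param gene_table Data frame with columns `genome_id`, `gene_index`,
#'   `gene_id`, `is_transporter`, `annotations` (semicolon-separated labels).
#' @param enzyme_labels Character vector of annotation labels counting as
#'   target enzymes.
#' @param window Gene-rank window (default 3).
#' @param clades Optional named character vector gene_id -> clade label; a
#'   per-clade fraction table is then returned alongside.
#' @return List with `transporters` (data frame: gene_id, genome_id, clade,
#'   informative, paired), `fraction` (overall paired / informative) and
#'   `by_clade` (data frame, when clades given).
#' @export
pair_transporters <- function(gene_table, enzyme_labels, window = 3,
                              clades = NULL) {
  if (window < 1) stop("window must be >= 1")
  gt <- validate_gene_table(gene_table)
  ann <- strsplit(gt$annotations, ";", fixed = TRUE)
  is_enzyme <- vapply(ann, function(a) any(trimws(a) %in% enzyme_labels), logical(1))
  tr <- which(gt$is_transporter)
  if (!length(tr)) stop("gene table contains no transporters")
  informative <- logical(length(tr))
  paired <- logical(length(tr))
  for (i in seq_along(tr)) {
    row <- tr[i]
    same <- gt$genome_id == gt$genome_id[row]
    others <- same & seq_len(nrow(gt)) != row
    informative[i] <- any(others)
    if (!informative[i]) next
    d <- abs(gt$gene_index[others] - gt$gene_index[row])
    paired[i] <- any(is_enzyme[others] & d >= 1 & d <= window)
  }
  if (any(!informative)) {
    warning(sprintf("%d transporter(s) without neighborhood information excluded",
                    sum(!informative)))
  }
  cl <- if (is.null(clades)) rep("all", length(tr)) else {
    unname(ifelse(is.na(clades[gt$gene_id[tr]]), "unassigned", clades[gt$gene_id[tr]]))
  }
  transporters <- data.frame(gene_id = gt$gene_id[tr], genome_id = gt$genome_id[tr],
                             clade = cl, informative = informative, paired = paired,
                             stringsAsFactors = FALSE)
  by_clade <- do.call(rbind, lapply(unique(cl), function(x) {
    sel <- transporters$clade == x & transporters$informative
    data.frame(clade = x, n_informative = sum(sel),
               n_paired = sum(transporters$paired[sel]),
               fraction = if (any(sel)) sum(transporters$paired[sel]) / sum(sel) else NA_real_)
  }))
  list(transporters = transporters,
       fraction = sum(paired[informative]) / max(1, sum(informative)),
       by_clade = by_clade)
}
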