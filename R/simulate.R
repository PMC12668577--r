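#' Simulate amino-acid sequence evolution along a tree
#'
#' Forward simulation under a reversible 20-state model with FreeRate
#' mixtures: per site, a rate category is drawn with probability `w_k`, the
#' root state is drawn from the stationary frequencies, and states propagate
#' down each branch with the transition matrix `P(rate * t)`. Draws are
#' site-major (category, root state, then preorder edge transitions for that
#' site) from a single seeded stream, so extending `n_sites` never perturbs
#' earlier sites. Planted clade signatures (if any) overwrite the designated
#' subtree leaves at the constrained positions after simulation, with the
#' overwritten cells flagged in the truth object.
#'
#' @param tree Rooted `ape::phylo` tree.
#' @param model A [substitution_model].
#' @param n_sites Number of sites.
#' @param seed Integer seed; fixes the entire output.
#' @param planted Optional list of plantings, each a list with `node`
#'   (internal node label), `scheme` (a [signature_scheme] whose positions
#'   index simulated columns directly, the simulation being gap-free).
#' @return List with `alignment` (leaf rows, an [aa_alignment]), `truth`
#'   (list: `node_states` character matrix over all nodes x sites,
#'   `categories` per-site category index, `overwritten` logical leaf x site
#'   matrix), and the labeled `tree`.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed, planted = NULL) {
  if (!ape::is.rooted(tree) && tree$Nnode > 1) stop("tree must be rooted")
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  K <- nrow(model$categories)
  set.seed(as.integer(seed))

  # Preorder edge ordering (parent before child)
  tr <- ape::reorder.phylo(tree, "postorder")
  edge_order <- rev(seq_len(nrow(tr$edge)))
  # Per-edge, per-category transition matrices (row-wise CDFs for sampling)
  Pcdf <- vector("list", nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    Pcdf[[e]] <- lapply(seq_len(K), function(k)
      t(apply(transition_matrix(model, tr$edge.length[e], model$categories$rate[k]),
              1, cumsum)))
  }
  wcdf <- cumsum(model$categories$weight)
  pcdf <- cumsum(model$pi)
  root <- ntip + 1L

  states <- matrix(0L, nn, n_sites)
  cats <- integer(n_sites)
  for (s in seq_len(n_sites)) {
    k <- findInterval(stats::runif(1), wcdf) + 1L
    cats[s] <- k
    states[root, s] <- findInterval(stats::runif(1), pcdf) + 1L
    for (e in edge_order) {
      par <- tr$edge[e, 1]
      ch <- tr$edge[e, 2]
      states[ch, s] <- findInterval(stats::runif(1), Pcdf[[e]][[k]][states[par, s], ]) + 1L
    }
  }

  node_states <- matrix(AA[states], nn, n_sites)
  rownames(node_states) <- c(tree$tip.label, tree$node.label)
  overwritten <- matrix(FALSE, ntip, n_sites,
                        dimnames = list(tree$tip.label, NULL))

  if (!is.null(planted)) {
    for (pl in planted) {
      nd <- match(pl$node, tree$node.label)
      if (is.na(nd)) stop(sprintf("planted clade node '%s' not in tree", pl$node))
      tips <- phangorn_free_descendants(tree, ntip + nd)
      sch <- pl$scheme
      if (any(sch$positions > n_sites)) stop("planted positions exceed simulated columns")
      for (i in seq_along(sch$positions)) {
        pos <- sch$positions[i]
        allowed <- sch$allowed[[i]]
        for (tp in tips) {
          if (!node_states[tp, pos] %in% allowed) {
            node_states[tp, pos] <- allowed[findInterval(stats::runif(1), seq_along(allowed) / length(allowed)) + 1L]
            overwritten[tp, pos] <- TRUE
          }
        }
      }
    }
  }

  aln <- aa_alignment(node_states[seq_len(ntip), , drop = FALSE])
  list(alignment = aln,
       truth = list(node_states = node_states, categories = cats,
                    overwritten = overwritten),
       tree = tree)
}

#' Simulate a gene-neighborhood table with known pairing truth
#'
#' Each genome gets `genes_per_genome` consecutively indexed genes with one
#' transporter at a seeded random position; with probability `p_enzyme_near`
#' an enzyme-annotated gene is placed uniformly within `window` ranks of the
#' transporter. Remaining genes carry a background annotation.
#'
#' @param n_genomes Number of genomes.
#' @param genes_per_genome Genes per genome (>= 2 * window + 1 recommended).
#' @param p_enzyme_near Probability a genome's transporter has a nearby
#'   enzyme.
#' @param window Placement window in gene ranks (default 3).
#' @param seed Integer seed.
#' @param enzyme_label Annotation label used for placed enzymes.
#' @return List with `gene_table` (data frame) and `truth_fraction`, the
#'   realized fraction of transporters with a placed nearby enzyme.
#' @export
simulate_gene_table <- function(n_genomes, genes_per_genome, p_enzyme_near,
                                window = 3, seed = 1,
                                enzyme_label = "aa_metabolism") {
  if (p_enzyme_near < 0 || p_enzyme_near > 1) stop("p_enzyme_near must be in [0, 1]")
  set.seed(as.integer(seed))
  rows <- vector("list", n_genomes)
  placed <- logical(n_genomes)
  for (g in seq_len(n_genomes)) {
    idx <- seq_len(genes_per_genome)
    tpos <- sample.int(genes_per_genome, 1)
    ann <- rep("other", genes_per_genome)
    if (stats::runif(1) < p_enzyme_near) {
      cand <- setdiff(intersect(idx, (tpos - window):(tpos + window)), tpos)
      epos <- cand[sample.int(length(cand), 1)]
      ann[epos] <- enzyme_label
      placed[g] <- TRUE
    }
    rows[[g]] <- data.frame(
      genome_id = sprintf("genome%04d", g),
      gene_index = idx,
      gene_id = sprintf("genome%04d_g%03d", g, idx),
      is_transporter = idx == tpos,
      annotations = ann,
      stringsAsFactors = FALSE)
  }
  list(gene_table = do.call(rbind, rows), truth_fraction = mean(placed))
}
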