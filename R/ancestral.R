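#' Marginal ancestral reconstruction at internal nodes
#'
#' For each requested internal node and retained alignment site, computes
#' the posterior probability of each of the 20 amino acids given all leaf
#' data (Yang's marginal method): downward partial likelihoods from the
#' pruning pass are combined with an upward message carrying the rest of the
#' tree, and rate categories are mixed per site with weights proportional to
#' `w_k` times the category-conditional site likelihood (empirical-Bayes
#' site assignment). Root posteriors use the stationary frequencies as the
#' prior.
#'
#' @param tree A rooted `ape::phylo` tree (root by outgroup first if
#'   needed); unlabeled internal nodes are auto-labeled `Node<k>`.
#' @param alignment An [aa_alignment]; reconstruction runs over retained
#'   columns.
#' @param model A [substitution_model].
#' @param nodes Character vector of internal-node labels to reconstruct
#'   (default: all internal nodes).
#' @param ambiguity_threshold Posterior threshold for calling a site
#'   ambiguous (strict `>`; default 0.2): a site is ambiguous when two or
#'   more states exceed it.
#' @return An object of class `asr`: posterior matrices (`n_sites` x 20, one
#'   per node), the per-site mixed log-likelihood, and the inputs needed by
#'   the downstream statistics.
#' @export
marginal_posteriors <- function(tree, alignment, model, nodes = NULL,
                                ambiguity_threshold = 0.2) {
  # A basal polytomy with further internal structure is genuinely unrooted;
  # a pure star tree has no alternative root placement and is accepted.
  if (!ape::is.rooted(tree) && tree$Nnode > 1) {
    stop("tree is unrooted: root it (e.g. by outgroup with ape::root) before reconstruction")
  }
  tree <- label_internal_nodes(tree)
  ntip <- length(tree$tip.label)
  all_internal <- tree$node.label
  if (is.null(nodes)) nodes <- all_internal
  unknown <- setdiff(nodes, all_internal)
  if (length(unknown)) {
    stop(sprintf("unknown node label '%s'", unknown[1]))
  }
  prep <- prune_prepare(tree, alignment)
  tr <- prep$tree
  S <- prep$n_sites
  K <- nrow(model$categories)
  node_ids <- ntip + match(nodes, all_internal)

  children <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])

  post_k <- vector("list", K)     # per category: list node -> 20 x S posterior
  by_cat <- matrix(0, K, S)
  for (k in seq_len(K)) {
    rate <- model$categories$rate[k]
    down <- prune_pass(prep, model, rate, keep = TRUE)
    by_cat[k, ] <- down$site_loglik
    # Upward messages, proportional per site (constants cancel on normalization)
    U <- vector("list", ntip + tree$Nnode)
    U[[prep$root]] <- matrix(model$pi, 20, S)
    # Preorder: visit edges parent-before-child = reverse postorder
    for (e in rev(seq_len(nrow(tr$edge)))) {
      par <- tr$edge[e, 1]
      ch <- tr$edge[e, 2]
      if (ch <= ntip) next
      sib_edges <- setdiff(children[[as.character(par)]], e)
      acc <- U[[par]]
      for (se in sib_edges) acc <- acc * down$msgs[[se]]
      P <- transition_matrix(model, tr$edge.length[e], rate)
      Uch <- crossprod(P, acc)          # t(P) %*% acc
      sc <- colSums(Uch)
      sc[sc == 0] <- 1
      U[[ch]] <- Uch / rep(sc, each = 20)
    }
    posts <- vector("list", length(node_ids))
    for (i in seq_along(node_ids)) {
      v <- node_ids[i]
      p <- down$partial[[v]] * U[[v]]
      tot <- colSums(p)
      tot[tot == 0] <- 1
      posts[[i]] <- p / rep(tot, each = 20)
    }
    post_k[[k]] <- posts
  }

  # Mix categories per site: weight_k(s) = softmax(log w_k + loglik_k(s))
  lw <- by_cat + log(model$categories$weight)
  site_loglik <- logsumexp_rows(lw)
  mix <- exp(sweep(lw, 2, site_loglik, "-"))  # K x S, columns sum to 1

  posteriors <- vector("list", length(nodes))
  names(posteriors) <- nodes
  for (i in seq_along(nodes)) {
    p <- matrix(0, 20, S)
    for (k in seq_len(K)) p <- p + rep(mix[k, ], each = 20) * post_k[[k]][[i]]
    pm <- t(p)
    colnames(pm) <- AA
    posteriors[[i]] <- pm
  }

  structure(list(posteriors = posteriors, nodes = nodes, tree = tree,
                 model = model, n_sites = S, site_loglik = site_loglik,
                 total_loglik = sum(site_loglik),
                 ambiguity_threshold = ambiguity_threshold),
            class = "asr")
}

#' @rdname marginal_posteriors
#' @export
reconstruct_ancestors <- marginal_posteriors

get_posterior <- function(asr, node) {
  if (inherits(asr, "asr")) {
    if (is.null(node)) {
      if (length(asr$posteriors) != 1) stop("specify which node to use")
      return(asr$posteriors[[1]])
    }
    p <- asr$posteriors[[node]]
    if (is.null(p)) stop(sprintf("node '%s' was not reconstructed", node))
    return(p)
  }
  p <- as.matrix(asr)
  if (ncol(p) != 20) stop("posterior matrix must have 20 columns")
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-6)) {
    stop("posterior rows must be probabilities summing to 1")
  }
  colnames(p) <- AA
  p
}

#' @export
print.asr <- function(x, ...) {
  cat(sprintf("Marginal ancestral reconstruction: %d node(s), %d sites, logL = %.4f\n",
              length(x$nodes), x$n_sites, x$total_loglik))
  for (nd in utils::head(x$nodes, 8)) {
    s <- pp_summary(x, node = nd)
    cat(sprintf("  %-12s mean PP %.3f  ln PP %.2f  ambiguous %.1f%%\n",
                nd, s$mean_pp, s$ln_pp, 100 * s$fraction_ambiguous))
  }
  if (length(x$nodes) > 8) cat(sprintf("  ... and %d more\n", length(x$nodes) - 8))
  invisible(x)
}

#' @export
summary.asr <- function(object, ...) {
  rows <- lapply(object$nodes, function(nd) {
    s <- pp_summary(object, node = nd)
    data.frame(node = nd, mean_pp = s$mean_pp, ln_pp = s$ln_pp,
               fraction_ambiguous = s$fraction_ambiguous)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.asr", "data.frame")
  out
}

#' @export
print.summary.asr <- function(x, ...) {
  cat("Posterior-probability summary per ancestor\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.asr <- function(x, node = NULL, ...) {
  p <- get_posterior(x, if (is.null(node)) x$nodes[1] else node)
  mx <- apply(p, 1, max)
  plot(seq_along(mx), mx, type = "h", ylim = c(0, 1),
       xlab = "site (retained columns)", ylab = "max posterior probability",
       main = sprintf("Per-site reconstruction confidence (%s)",
                      if (is.null(node)) x$nodes[1] else node), ...)
  invisible(x)
}

#' Maximum-likelihood ancestral sequence
#'
#' Per-site argmax of the posterior matrix; exact ties are broken by
#' alphabetical one-letter code.
#'
#' @param asr An `asr` object or an `n_sites` x 20 posterior matrix.
#' @param node Node label when `asr` holds several nodes.
#' @return List with `sequence` (string), `max_pp` (per-site numeric) and
#'   `states` (per-site characters).
#' @export
ml_sequence <- function(asr, node = NULL) {
  p <- get_posterior(asr, node)
  idx <- max.col(p, ties.method = "first")  # columns in alphabetical order
  states <- AA[idx]
  list(sequence = paste(states, collapse = ""), states = states,
       max_pp = p[cbind(seq_len(nrow(p)), idx)])
}

#' Flag ambiguously reconstructed sites
#'
#' A site is ambiguous when two or more amino acids have posterior
#' probability strictly greater than the threshold.
#'
#' @inheritParams ml_sequence
#' @param threshold Strict posterior cutoff (default 0.2).
#' @return Logical vector over sites.
#' @export
flag_ambiguous <- function(asr, node = NULL, threshold = 0.2) {
  p <- get_posterior(asr, node)
  rowSums(p > threshold) >= 2
}

#' AltALL alternative ancestral sequence
#'
#' Equal to the ML sequence except at ambiguous sites, where the
#' second-most-probable state is substituted (second-rank ties broken
#' alphabetically).
#'
#' @inheritParams flag_ambiguous
#' @return List with `sequence`, `states`, and `ambiguous` (logical per
#'   site).
#' @export
altall_sequence <- function(asr, node = NULL, threshold = 0.2) {
  p <- get_posterior(asr, node)
  ml <- ml_sequence(asr, node)
  amb <- flag_ambiguous(asr, node, threshold)
  states <- ml$states
  if (any(amb)) {
    for (s in which(amb)) {
      ord <- order(-p[s, ], AA)  # by prob desc, then alphabetical
      states[s] <- AA[ord[2]]
    }
  }
  list(sequence = paste(states, collapse = ""), states = states, ambiguous = amb)
}

#' Posterior-probability summary of an ancestor
#'
#' Mean per-site ML-state posterior probability, natural log of the total
#' posterior probability of the ML sequence (sum of log max-PP), and the
#' fraction of ambiguous sites, optionally restricted to a column subset.
#'
#' @inheritParams flag_ambiguous
#' @param columns Optional integer vector of retained-column indices
#'   (1-based) to restrict to, e.g. from [resolve_columns].
#' @return List with `mean_pp`, `ln_pp`, `fraction_ambiguous`, `n_sites`.
#' @export
pp_summary <- function(asr, node = NULL, columns = NULL, threshold = 0.2) {
  p <- get_posterior(asr, node)
  if (!is.null(columns)) {
    if (length(columns) == 0) stop("empty column subset")
    if (any(columns < 1 | columns > nrow(p))) stop("column subset out of range")
    p <- p[columns, , drop = FALSE]
  }
  idx <- max.col(p, ties.method = "first")
  mx <- p[cbind(seq_len(nrow(p)), idx)]
  amb <- rowSums(p > threshold) >= 2
  list(mean_pp = mean(mx), ln_pp = sum(log(mx)),
       fraction_ambiguous = mean(amb), n_sites = nrow(p))
}

#' Compare two reconstructed ancestors
#'
#' Lists the sites where the ML sequences differ and classifies each by
#' whether the ML-state posterior probability exceeds `high_pp` in the
#' first ancestor only, the second only, both, or neither.
#'
#' @param asr1,asr2 `asr` objects (or posterior matrices) over identical
#'   retained columns.
#' @param node1,node2 Node labels within `asr1`/`asr2`.
#' @param columns Optional retained-column subset.
#' @param high_pp Posterior cutoff for a confidently reconstructed state
#'   (strict `>`; default 0.9).
#' @param reference_map Optional [build_reference_map] result (over retained
#'   columns) used to label sites in reference numbering.
#' @return A `data.frame` (class `diff_report`) with one row per differing
#'   site and attributes `identity` (percent identical over compared sites),
#'   `n_compared` and `class_counts`.
#' @export
ancestor_diff <- function(asr1, asr2, node1 = NULL, node2 = NULL,
                          columns = NULL, high_pp = 0.9, reference_map = NULL) {
  p1 <- get_posterior(asr1, node1)
  p2 <- get_posterior(asr2, node2)
  if (nrow(p1) != nrow(p2)) stop("ancestors are defined over different column sets")
  sites <- if (is.null(columns)) seq_len(nrow(p1)) else columns
  if (any(sites < 1 | sites > nrow(p1))) stop("column subset out of range")
  m1 <- ml_sequence(p1)
  m2 <- ml_sequence(p2)
  differing <- sites[m1$states[sites] != m2$states[sites]]
  cls <- character(length(differing))
  for (i in seq_along(differing)) {
    s <- differing[i]
    hi1 <- m1$max_pp[s] > high_pp
    hi2 <- m2$max_pp[s] > high_pp
    cls[i] <- if (hi1 && hi2) "both" else if (hi1) "first_only" else if (hi2) "second_only" else "neither"
  }
  label <- as.character(differing)
  if (!is.null(reference_map)) {
    ref <- map_col_to_ref(reference_map, differing)
    label <- ifelse(is.na(ref), label, paste0(ref, ":", differing))
  }
  out <- data.frame(site = differing, label = label,
                    state1 = m1$states[differing], state2 = m2$states[differing],
                    pp1 = m1$max_pp[differing], pp2 = m2$max_pp[differing],
                    class = cls, stringsAsFactors = FALSE)
  attr(out, "n_compared") <- length(sites)
  attr(out, "identity") <- 100 * (1 - length(differing) / length(sites))
  attr(out, "class_counts") <- table(factor(cls, levels = c("first_only", "second_only", "both", "neither")))
  class(out) <- c("diff_report", "data.frame")
  out
}

#' @export
print.diff_report <- function(x, ...) {
  cat(sprintf("Ancestor comparison: %d differing site(s) of %d compared (identity %.1f%%)\n",
              nrow(x), attr(x, "n_compared"), attr(x, "identity")))
  print(attr(x, "class_counts"))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 20), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Residue-frequency (logo) matrix
#'
#' For an `asr` object/posterior matrix, returns the posterior vectors for
#' the requested columns. For a set of extant sequences (an
#' [aa_alignment]), returns observed residue frequencies per column with
#' gaps excluded from the denominator (all-gap columns become zero columns,
#' with a warning).
#'
#' @param x An `asr` object, posterior matrix, or [aa_alignment].
#' @param columns Integer column indices (retained-column space for `asr`).
#' @param node Node label when `x` is a multi-node `asr`.
#' @param reference_map Optional map used to label columns in reference
#'   numbering.
#' @return 20 x length(columns) matrix; rows named by amino acid.
#' @export
logo_matrix <- function(x, columns, node = NULL, reference_map = NULL) {
  if (length(columns) == 0) stop("empty column set")
  if (inherits(x, "aa_alignment")) {
    m <- unclass(x)[, columns, drop = FALSE]
    L <- apply(m, 2, function(col) {
      obs <- col[col %in% AA]
      if (length(obs) == 0) return(rep(0, 20))
      as.numeric(table(factor(obs, levels = AA))) / length(obs)
    })
    if (any(colSums(L) == 0)) warning("all-gap column(s) produce zero logo columns")
  } else {
    p <- get_posterior(x, node)
    if (any(columns < 1 | columns > nrow(p))) stop("column subset out of range")
    L <- t(p[columns, , drop = FALSE])
  }
  rownames(L) <- AA
  lab <- as.character(columns)
  if (!is.null(reference_map)) {
    ref <- map_col_to_ref(reference_map, columns)
    lab <- ifelse(is.na(ref), lab, paste0(ref, ":", columns))
  }
  colnames(L) <- lab
  L
}

#' Export reconstructed posteriors as a state table
#'
#' @param asr An `asr` object.
#' @param nodes Node labels to include (default all).
#' @return Data frame in the state-table dialect (`Node`, `Site`, `State`,
#'   `p_A` ... `p_Y`), sites 1-based over retained columns.
#' @export
as_state_table <- function(asr, nodes = NULL) {
  if (is.null(nodes)) nodes <- asr$nodes
  rows <- lapply(nodes, function(nd) {
    p <- get_posterior(asr, nd)
    ml <- ml_sequence(p)
    df <- data.frame(Node = nd, Site = seq_len(nrow(p)), State = ml$states,
                     stringsAsFactors = FALSE)
    pm <- as.data.frame(p)
    names(pm) <- paste0("p_", AA)
    cbind(df, pm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
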