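# Independent oracles for likelihood and marginal posteriors: exhaustive
# enumeration over internal-state assignments, with transition matrices from
# Matrix::expm (a different algorithm from the package's eigendecomposition).

oracle_transition <- function(S, pi, t, rate = 1) {
  Q <- S * rep(pi, each = nrow(S))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  as.matrix(Matrix::expm(Q * t * rate))
}

# Exhaustive enumeration over all 20^n_internal internal-state assignments.
# Returns per-site log-likelihood and the mixed marginal posterior
# (sites x 20) for every internal node.
enum_oracle <- function(tree, alignment, model) {
  aa <- amino_acids()
  mask <- attr(alignment, "column_mask")
  m <- unclass(alignment)[, mask, drop = FALSE]
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  n_sites <- ncol(m)
  leafst <- matrix(match(as.vector(m[tree$tip.label, , drop = FALSE]), aa),
                   nrow = ntip)
  grid <- as.matrix(expand.grid(rep(list(1:20), nint)))
  K <- nrow(model$categories)
  w <- model$categories$weight
  r <- model$categories$rate
  edges <- tree$edge
  internal_edge <- edges[, 2] > ntip

  sitelik <- matrix(0, K, n_sites)
  num <- lapply(seq_len(nint), function(j) matrix(0, n_sites, 20))
  for (k in seq_len(K)) {
    P <- lapply(seq_len(nrow(edges)), function(e)
      oracle_transition(model$S, model$pi, tree$edge.length[e], r[k]))
    # site-independent part: root prior and internal-internal edges
    base <- model$pi[grid[, 1]]
    for (e in which(internal_edge)) {
      gp <- grid[, edges[e, 1] - ntip]
      gc <- grid[, edges[e, 2] - ntip]
      base <- base * P[[e]][cbind(gp, gc)]
    }
    for (s in seq_len(n_sites)) {
      pr <- base
      for (e in which(!internal_edge)) {
        st <- leafst[edges[e, 2], s]
        if (is.na(st)) next  # gap/'X': sums to 1 over leaf states
        gp <- grid[, edges[e, 1] - ntip]
        pr <- pr * P[[e]][cbind(gp, st)]
      }
      tot <- sum(pr)
      sitelik[k, s] <- tot
      for (j in seq_len(nint)) {
        num[[j]][s, ] <- num[[j]][s, ] + w[k] *
          as.numeric(rowsum(pr, factor(grid[, j], levels = 1:20)))
      }
    }
  }
  denom <- as.numeric(w %*% sitelik)
  posteriors <- lapply(num, function(x) {
    p <- x / denom
    colnames(p) <- aa
    p
  })
  names(posteriors) <- tree$node.label
  list(site_loglik = log(denom), posteriors = posteriors)
}

# Seeded random ingredients for property tests.
random_tree <- function(n_leaves, min_bl = 0.02, max_bl = 0.6) {
  tree <- ape::rtree(n_leaves, br = function(n) stats::runif(n, min_bl, max_bl))
  label_internal_nodes(tree)
}

random_model <- function(K = 1) {
  S <- matrix(exp(stats::rnorm(400, sd = 0.7)), 20, 20)
  S <- (S + t(S)) / 2
  diag(S) <- 0
  pi <- stats::rgamma(20, 2, 1)
  pi <- pi / sum(pi)
  cats <- if (K == 1) NULL else {
    w <- stats::rgamma(K, 2, 1); w <- w / sum(w)
    r <- sort(stats::rgamma(K, 2, 1)) + 0.05
    data.frame(weight = w, rate = r)
  }
  substitution_model(S, pi, cats)
}

random_alignment <- function(tree, n_sites, model, seed) {
  simulate_alignment(tree, model, n_sites, seed = seed)$alignment
}

uniform_model <- function(categories = NULL) {
  S <- matrix(1, 20, 20)
  diag(S) <- 0
  substitution_model(S, rep(1 / 20, 20), categories)
}
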