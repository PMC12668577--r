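# Felsenstein pruning with per-node rescaling, shared by the likelihood and
# marginal-reconstruction code paths.

# Precompute everything that does not depend on model parameters: postorder
# edge list, children per node, and the 20 x S tip partial matrices (one-hot
# columns; all-ones for gaps/'X').
prune_prepare <- function(tree, alignment) {
  mask <- attr(alignment, "column_mask")
  m <- unclass(alignment)[, mask, drop = FALSE]
  missing <- setdiff(tree$tip.label, rownames(m))
  if (length(missing)) {
    stop(sprintf("leaf '%s' has no sequence in the alignment", missing[1]))
  }
  S <- ncol(m)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  tips <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    st <- encode_residues(m[tree$tip.label[i], ])
    L <- matrix(0, 20, S)
    obs <- which(!is.na(st))
    L[cbind(st[obs], obs)] <- 1
    if (length(obs) < S) L[, setdiff(seq_len(S), obs)] <- 1
    tips[[i]] <- L
  }
  list(tree = tr, ntip = ntip, nnode = tree$Nnode, n_sites = S,
       tips = tips, root = ntip + 1L,
       node_labels = c(tree$tip.label, tree$node.label))
}

# One pruning pass at a single rate. Returns per-site log-likelihood at the
# root plus (optionally) the scaled partials and per-edge messages needed by
# the marginal-reconstruction up pass.
prune_pass <- function(prep, model, rate, keep = FALSE) {
  tr <- prep$tree
  ntip <- prep$ntip
  S <- prep$n_sites
  nn <- ntip + prep$nnode
  partial <- vector("list", nn)
  partial[seq_len(ntip)] <- prep$tips
  logsc <- vector("list", nn)
  zero <- numeric(S)
  msgs <- if (keep) vector("list", nrow(tr$edge)) else NULL
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]
    ch <- tr$edge[e, 2]
    P <- transition_matrix(model, tr$edge.length[e], rate)
    msg <- P %*% partial[[ch]]
    if (keep) msgs[[e]] <- msg
    ch_sc <- if (is.null(logsc[[ch]])) zero else logsc[[ch]]
    if (is.null(partial[[par]])) {
      partial[[par]] <- msg
      logsc[[par]] <- ch_sc
    } else {
      partial[[par]] <- partial[[par]] * msg
      logsc[[par]] <- logsc[[par]] + ch_sc
    }
    sc <- colSums(partial[[par]])
    ok <- sc > 0
    if (any(ok)) {
      partial[[par]][, ok] <- partial[[par]][, ok, drop = FALSE] /
        rep(sc[ok], each = 20)
      logsc[[par]][ok] <- logsc[[par]][ok] + log(sc[ok])
    }
    if (any(!ok)) logsc[[par]][!ok] <- -Inf
  }
  root <- prep$root
  sitelik <- colSums(model$pi * partial[[root]])
  loglik <- log(sitelik) + logsc[[root]]
  if (any(!is.finite(loglik))) {
    warning(sprintf("%d site(s) have zero likelihood under this rate category",
                    sum(!is.finite(loglik))))
  }
  out <- list(site_loglik = loglik)
  if (keep) {
    out$partial <- partial
    out$msgs <- msgs
  }
  out
}

logsumexp_rows <- function(x) {
  # x: K x S matrix of logs; returns length-S vector log(colSums(exp(x)))
  m <- apply(x, 2, max)
  m + log(colSums(exp(sweep(x, 2, m, "-"))))
}

#' Per-site log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning under a reversible amino-acid model with FreeRate
#' mixtures: per site, the likelihood is the weighted sum over rate
#' categories of the category-conditional pruning likelihood. Gaps and `X`
#' contribute all-ones partial vectors. Underflow is handled by per-node
#' rescaling with accumulated log scalers.
#'
#' @param tree An `ape::phylo` tree whose tip labels are alignment ids.
#' @param alignment An [aa_alignment]; only retained columns are used.
#' @param model A [substitution_model].
#' @return An object of class `site_lik`: list with `site_loglik` (per-site
#'   values), `total`, and `by_category` (K x S matrix of category-conditional
#'   per-site log-likelihoods).
#' @export
prune_loglik <- function(tree, alignment, model) {
  prep <- prune_prepare(tree, alignment)
  K <- nrow(model$categories)
  by_cat <- matrix(0, K, prep$n_sites)
  for (k in seq_len(K)) {
    by_cat[k, ] <- prune_pass(prep, model, model$categories$rate[k])$site_loglik
  }
  lw <- log(model$categories$weight)
  site <- logsumexp_rows(by_cat + lw)
  structure(list(site_loglik = site, total = sum(site), by_category = by_cat),
            class = "site_lik")
}

#' @export
print.site_lik <- function(x, ...) {
  cat(sprintf("Tree log-likelihood: %.6f over %d sites (%d rate categories)\n",
              x$total, length(x$site_loglik), nrow(x$by_category)))
  invisible(x)
}

#' @export
logLik.site_lik <- function(object, ...) {
  structure(object$total, df = NA_integer_, class = "logLik")
}

#' Fit FreeRate category weights and rates
#'
#' Maximizes the pruning log-likelihood over the K category weights and
#' rates (topology, branch lengths, exchangeabilities and frequencies held
#' fixed) under the constraints `sum(w) = 1`, `sum(w * r) = 1`, `r > 0`.
#' The constrained problem is reparameterized (log-weights via softmax,
#' log-rates rescaled to unit mean rate) and solved by quasi-Newton descent
#' from several deterministic starts spread over rate space; ties are broken
#' by best log-likelihood then lowest start index.
#'
#' @param tree Tree with fixed branch lengths.
#' @param alignment An [aa_alignment].
#' @param S Exchangeability matrix (e.g. `lg_model()$S`).
#' @param pi Stationary frequencies.
#' @param K Number of rate categories (>= 1).
#' @param n_starts Number of deterministic multistarts (default 5).
#' @param control Passed to [stats::optim] (method BFGS).
#' @return An object of class `freerate_fit` with the fitted
#'   [substitution_model], the achieved log-likelihood and per-start
#'   diagnostics.
#' @export
fit_freerate <- function(tree, alignment, S, pi, K, n_starts = 5,
                         control = list(reltol = 1e-8, maxit = 200)) {
  if (K < 1) stop("K must be >= 1")
  base <- substitution_model(S, pi)
  prep <- prune_prepare(tree, alignment)

  cat_loglik <- function(w, r) {
    by_cat <- matrix(0, K, prep$n_sites)
    for (k in seq_len(K)) by_cat[k, ] <- prune_pass(prep, base, r[k])$site_loglik
    sum(logsumexp_rows(by_cat + log(w)))
  }

  if (K == 1) {
    ll <- cat_loglik(1, 1)
    model <- substitution_model(S, pi, data.frame(weight = 1, rate = 1))
    return(structure(list(model = model, logLik = ll, K = 1,
                          starts = data.frame(start = 1, logLik = ll,
                                              converged = TRUE)),
                     class = "freerate_fit"))
  }

  theta_to_wr <- function(theta) {
    theta <- pmin(pmax(theta, -20), 20)  # keep exp() in range during line search
    lw <- c(0, theta[seq_len(K - 1)])
    w <- exp(lw - max(lw)); w <- w / sum(w)
    r <- exp(theta[K:(2 * K - 1)])
    r <- r / sum(w * r)
    list(w = w, r = r)
  }
  negll <- function(theta) {
    wr <- theta_to_wr(theta)
    ll <- tryCatch(suppressWarnings(cat_loglik(wr$w, wr$r)),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  # Deterministic starts: equal weights, rates spread geometrically with
  # increasing dispersion.
  spreads <- seq(0.5, 2.5, length.out = n_starts)
  results <- vector("list", n_starts)
  for (m in seq_len(n_starts)) {
    r0 <- exp(seq(-spreads[m], spreads[m], length.out = K))
    r0 <- r0 / mean(r0)
    theta0 <- c(rep(0, K - 1), log(r0))
    fit <- tryCatch(
      stats::optim(theta0, negll, method = "BFGS", control = control),
      error = function(e) NULL)
    if (!is.null(fit)) {
      results[[m]] <- list(value = fit$value, par = fit$par,
                           converged = fit$convergence == 0)
    }
  }
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) stop("FreeRate optimization failed from every start")
  vals <- vapply(results, function(x) if (is.null(x)) Inf else x$value, numeric(1))
  best_i <- which.min(vals)
  best <- results[[best_i]]
  if (!best$converged) {
    warning("FreeRate optimization did not converge; returning best parameters found")
  }
  wr <- theta_to_wr(best$par)
  ord <- order(wr$r)
  model <- substitution_model(S, pi, data.frame(weight = wr$w[ord], rate = wr$r[ord]))
  structure(list(model = model, logLik = -best$value, K = K,
                 starts = data.frame(start = seq_len(n_starts),
                                     logLik = -vals,
                                     converged = vapply(results, function(x)
                                       !is.null(x) && x$converged, logical(1)))),
            class = "freerate_fit")
}

#' @export
print.freerate_fit <- function(x, ...) {
  cat(sprintf("FreeRate fit: K = %d, log-likelihood = %.4f\n", x$K, x$logLik))
  print(x$model$categories, row.names = FALSE)
  invisible(x)
}

#' @export
coef.freerate_fit <- function(object, ...) {
  k <- nrow(object$model$categories)
  stats::setNames(c(object$model$categories$weight, object$model$categories$rate),
                  c(paste0("w", seq_len(k)), paste0("r", seq_len(k))))
}

#' @export
logLik.freerate_fit <- function(object, ...) {
  structure(object$logLik, df = 2 * object$K - 2, class = "logLik")
}
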