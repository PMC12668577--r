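#' Construct a reversible amino-acid substitution model
#'
#' A model is a symmetric exchangeability matrix `S` (zero diagonal),
#' stationary frequencies `pi` and a set of FreeRate categories
#' `(weight, rate)` normalized so the mean rate is 1. The generator is
#' `Q[i,j] = c * S[i,j] * pi[j]` with `c` chosen so the expected number of
#' substitutions per unit time at stationarity is 1.
#'
#' @param S 20x20 symmetric non-negative exchangeability matrix.
#' @param pi Length-20 stationary frequencies (alphabetical residue order),
#'   all positive, summing to 1 (renormalized if within 1e-6).
#' @param categories Data frame with columns `weight` and `rate`, or `NULL`
#'   for a single unit-rate category. Weights are renormalized to sum to 1
#'   and rates rescaled so that `sum(weight * rate) == 1`.
#' @return An object of class `substitution_model` with elements `S`, `pi`,
#'   `categories`, `Q` and a cached eigendecomposition used by
#'   [transition_matrix].
#' @export
substitution_model <- function(S, pi, categories = NULL) {
  S <- as.matrix(S)
  if (!all(dim(S) == c(20, 20))) stop("S must be 20x20")
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  if (any(S < 0)) stop("S must be non-negative")
  diag(S) <- 0
  pi <- as.numeric(pi)
  if (length(pi) != 20) stop("pi must have 20 entries")
  if (any(pi <= 0)) stop("all frequencies must be strictly positive")
  if (abs(sum(pi) - 1) > 1e-3) stop("frequencies must sum to 1")
  pi <- pi / sum(pi)
  if (is.null(categories)) categories <- data.frame(weight = 1, rate = 1)
  categories <- as.data.frame(categories)
  if (!all(c("weight", "rate") %in% names(categories))) {
    stop("categories must have columns weight and rate")
  }
  w <- categories$weight
  r <- categories$rate
  if (any(w < 0) || sum(w) <= 0) stop("category weights must be non-negative with positive sum")
  if (any(r <= 0)) stop("category rates must be strictly positive")
  w <- w / sum(w)
  r <- r / sum(w * r)
  categories <- data.frame(weight = w, rate = r)

  rm <- build_rate_matrix(S, pi)
  structure(list(S = S, pi = pi, categories = categories,
                 Q = rm$Q, eig = rm$eig),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  K <- nrow(x$categories)
  cat(sprintf("Reversible amino-acid substitution model (20 states, %d rate categor%s)\n",
              K, if (K == 1) "y" else "ies"))
  cat("  frequencies: ", paste(sprintf("%s=%.3f", AA[1:5], x$pi[1:5]), collapse = " "), "...\n")
  if (K > 1) {
    cat(sprintf("  rates: %s\n", paste(sprintf("%.3f", x$categories$rate), collapse = ", ")))
    cat(sprintf("  weights: %s\n", paste(sprintf("%.3f", x$categories$weight), collapse = ", ")))
  }
  invisible(x)
}

#' Build the normalized generator matrix from exchangeabilities and frequencies
#'
#' `Q[i,j] = c * S[i,j] * pi[j]` for `i != j`, diagonal set so rows sum to 0,
#' and `c` chosen so the mean substitution rate `-sum(pi * diag(Q))` is 1.
#' Also returns the symmetric eigendecomposition used for matrix
#' exponentials: with `B = D^(1/2) Q D^(-1/2)` (D = diag(pi)) symmetric,
#' `P(t) = U exp(L t) U^-1` where `U = D^(-1/2) V`.
#'
#' @param S Symmetric 20x20 exchangeability matrix.
#' @param pi Stationary frequencies.
#' @return List with `Q` and `eig` (`values`, `U`, `Uinv`).
#' @export
build_rate_matrix <- function(S, pi) {
  if (any(pi <= 0)) stop("zero or negative frequency")
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  Q <- S * rep(pi, each = nrow(S))   # Q_ij = S_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))         # B_ij = sqrt(pi_i) Q_ij / sqrt(pi_j)
  B <- (B + t(B)) / 2                # symmetrize numerical noise
  e <- eigen(B, symmetric = TRUE)
  U <- e$vectors / sq                # rows scaled: U = D^{-1/2} V
  Uinv <- t(e$vectors * sq)          # U^{ -1} = V' D^{1/2}
  dimnames(Q) <- list(AA, AA)
  list(Q = Q, eig = list(values = e$values, U = U, Uinv = Uinv))
}

#' Transition probability matrix P(r * t)
#'
#' @param model A [substitution_model] (its cached eigendecomposition is
#'   used).
#' @param t Branch length in expected substitutions per site (>= 0).
#' @param rate Rate multiplier (> 0), e.g. a FreeRate category rate.
#' @return 20x20 row-stochastic matrix. Entries below -1e-12 trigger an
#'   error; tiny negative round-off is clipped to 0 and rows renormalized.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length t must be >= 0")
  if (rate <= 0) stop("rate must be > 0")
  e <- model$eig
  P <- e$U %*% (exp(e$values * t * rate) * e$Uinv)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(AA, AA)
  P
}

#' The bundled LG substitution model
#'
#' Loads the published LG exchangeabilities and stationary frequencies from
#' the package's data file. Pass empirical frequencies (the `+F` variant)
#' and/or FreeRate categories to override the defaults.
#'
#' @param pi Optional replacement frequencies (e.g. from
#'   [empirical_frequencies]).
#' @param categories Optional FreeRate category data frame (`weight`,
#'   `rate`).
#' @return A [substitution_model].
#' @export
lg_model <- function(pi = NULL, categories = NULL) {
  path <- system.file("extdata", "lg.model", package = "asrkit")
  base <- read_model_file(path)
  substitution_model(base$S, if (is.null(pi)) base$pi else pi, categories)
}

#' Empirical amino-acid frequencies of an alignment
#'
#' Counts residues over the retained columns of the alignment (gaps and `X`
#' excluded from the counts, no pseudocount). Zero counts are nudged to a
#' tiny positive floor so the model stays reversible and ergodic.
#'
#' @param alignment An [aa_alignment].
#' @return Length-20 frequency vector in alphabetical residue order.
#' @export
empirical_frequencies <- function(alignment) {
  mask <- attr(alignment, "column_mask")
  m <- unclass(alignment)[, mask, drop = FALSE]
  counts <- table(factor(m, levels = AA))
  f <- as.numeric(counts)
  if (sum(f) == 0) stop("alignment has no residues over retained columns")
  f[f == 0] <- 1e-10
  f / sum(f)
}

#' Flag long branches on a tree
#'
#' Leaves whose pendant branch exceeds the threshold (strictly) are flagged
#' for removal before reconstruction; long internal branches are reported
#' but not flagged for removal.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param threshold Substitutions-per-site cutoff (default 0.7; strict `>`).
#' @return List with `leaves` (tip labels to remove) and `internal`
#'   (data frame of long internal branches: parent/child node numbers and
#'   lengths).
#' @export
detect_long_branches <- function(tree, threshold = 0.7) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  long <- tree$edge.length > threshold
  is_pendant <- tree$edge[, 2] <= ntip
  leaves <- tree$tip.label[tree$edge[long & is_pendant, 2]]
  internal_idx <- which(long & !is_pendant)
  internal <- data.frame(parent = tree$edge[internal_idx, 1],
                         child = tree$edge[internal_idx, 2],
                         length = tree$edge.length[internal_idx])
  list(leaves = leaves, internal = internal)
}
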