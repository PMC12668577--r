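test_that("rate-matrix construction satisfies its algebraic identities", {
  # uniform exchangeabilities and frequencies: closed-form generator
  S1 <- matrix(1, 20, 20); diag(S1) <- 0
  rm <- build_rate_matrix(S1, rep(1 / 20, 20))
  expect_equal(unname(rm$Q[1, 2]), 1 / 19, tolerance = 1e-12)
  expect_equal(unname(diag(rm$Q)), rep(-1, 20), tolerance = 1e-12)

  set.seed(5)
  m <- random_model()
  expect_lt(max(abs(m$pi %*% m$Q)), 1e-10)                       # stationarity
  lg <- lg_model()
  flux <- lg$pi * lg$Q                                           # pi_i Q_ij = pi_j Q_ji
  expect_lt(max(abs(flux - t(flux))), 1e-10)
  expect_equal(-sum(lg$pi * diag(lg$Q)), 1, tolerance = 1e-10)   # mean rate 1

  expect_error(build_rate_matrix(S1, c(0, rep(1 / 19, 19))), "frequency")
  S_bad <- S1; S_bad[1, 2] <- 5
  expect_error(build_rate_matrix(S_bad, rep(1 / 20, 20)), "symmetric")
})

test_that("transition matrices obey P(0)=I, ergodic limit, closed form and semigroup", {
  lg <- lg_model()
  expect_equal(transition_matrix(lg, 0), diag(20), ignore_attr = TRUE,
               tolerance = 1e-12)
  Pinf <- transition_matrix(lg, 1e6)
  expect_lt(max(abs(sweep(Pinf, 2, lg$pi))), 1e-6)

  # uniform model closed form: P_ii(t) = 1/20 + (19/20) exp(-20 t / 19)
  u <- uniform_model()
  for (t in c(0.05, 0.3, 1.2)) {
    P <- transition_matrix(u, t)
    expect_equal(unname(diag(P)), rep(1 / 20 + (19 / 20) * exp(-20 * t / 19), 20),
                 tolerance = 1e-9)
  }

  set.seed(8)
  m <- random_model()
  for (i in 1:5) {
    t1 <- runif(1, 0, 1); t2 <- runif(1, 0, 1)
    P12 <- transition_matrix(m, t1) %*% transition_matrix(m, t2)
    expect_equal(P12, transition_matrix(m, t1 + t2), ignore_attr = TRUE,
                 tolerance = 1e-9)
    expect_equal(unname(rowSums(transition_matrix(m, t1))), rep(1, 20),
                 tolerance = 1e-10)
  }
  expect_error(transition_matrix(m, -0.1), ">= 0")
})

test_that("pruning log-likelihood matches base cases and the enumeration oracle", {
  lg <- lg_model()
  aa <- amino_acids()

  # single leaf: log pi_x
  t1 <- ape::read.tree(text = "(a:0.1);")
  t1 <- label_internal_nodes(t1)
  ll <- prune_loglik(t1, aa_alignment(c(a = "W")), lg)
  expect_equal(ll$total, log(lg$pi[which(aa == "W")]), tolerance = 1e-12)

  # two leaves: log(pi_i P_ij(t1 + t2)) by reversibility
  t2 <- label_internal_nodes(ape::read.tree(text = "(a:0.12,b:0.34);"))
  ll2 <- prune_loglik(t2, aa_alignment(c(a = "M", b = "L")), lg)
  P <- transition_matrix(lg, 0.46)
  expect_equal(ll2$total, log(lg$pi[which(aa == "M")] * P[which(aa == "M"), which(aa == "L")]),
               tolerance = 1e-10)

  # gap and 'X' leaves contribute all-ones partials
  llg <- prune_loglik(t2, aa_alignment(c(a = "M", b = "X")), lg)
  expect_equal(llg$total, log(lg$pi[which(aa == "M")]), tolerance = 1e-12)

  # 4 leaves, 3 sites, 2 categories vs exhaustive enumeration
  set.seed(21)
  tree <- random_tree(4)
  model <- random_model(K = 2)
  aln <- random_alignment(tree, 3, model, seed = 9)
  mine <- prune_loglik(tree, aln, model)
  oracle <- enum_oracle(tree, aln, model)
  expect_equal(mine$site_loglik, oracle$site_loglik, tolerance = 1e-8)
})

test_that("likelihood is invariant to root placement and degree-2 nodes", {
  lg <- lg_model()
  aln <- aa_alignment(c(a = "MKL", b = "MRL", c = "AKI", d = "AQI"))
  ta <- label_internal_nodes(ape::read.tree(
    text = "((a:0.1,b:0.2):0.05,(c:0.3,d:0.4):0.15);"))
  tb <- label_internal_nodes(ape::read.tree(
    text = "((a:0.1,b:0.2):0.12,(c:0.3,d:0.4):0.08);"))
  expect_equal(prune_loglik(ta, aln, lg)$total, prune_loglik(tb, aln, lg)$total,
               tolerance = 1e-8)

  t_plain <- label_internal_nodes(ape::read.tree(text = "(a:0.1,b:0.2);"))
  t_single <- label_internal_nodes(ape::read.tree(text = "((a:0.1):0.0,b:0.2);"))
  two <- aa_alignment(c(a = "M", b = "L"))
  expect_equal(prune_loglik(t_plain, two, lg)$total,
               prune_loglik(t_single, two, lg)$total, tolerance = 1e-10)
})

test_that("pruning agrees with an independent implementation on larger trees", {
  skip_if_not_installed("phangorn")
  set.seed(14)
  tree <- random_tree(10)
  model <- lg_model()
  aln <- random_alignment(tree, 120, model, seed = 2)
  mine <- prune_loglik(tree, aln, model)
  m <- unclass(aln); class(m) <- "matrix"
  fit <- phangorn::pml(tree, phangorn::phyDat(m, type = "AA"), model = "LG")
  expect_equal(mine$total, fit$logLik, tolerance = 1e-6)
})

test_that("FreeRate fitting honors constraints and nesting", {
  set.seed(30)
  tree <- random_tree(8, 0.05, 0.3)
  lg <- lg_model()
  aln <- random_alignment(tree, 150, lg, seed = 4)

  f1 <- fit_freerate(tree, aln, lg$S, lg$pi, K = 1)
  expect_equal(coef(f1), c(w1 = 1, r1 = 1))
  expect_equal(f1$logLik, prune_loglik(tree, aln, lg)$total, tolerance = 1e-10)

  f2 <- fit_freerate(tree, aln, lg$S, lg$pi, K = 2, n_starts = 2,
                     control = list(reltol = 1e-6, maxit = 60))
  cats <- f2$model$categories
  expect_equal(sum(cats$weight), 1, tolerance = 1e-8)
  expect_equal(sum(cats$weight * cats$rate), 1, tolerance = 1e-8)
  expect_true(all(cats$rate > 0))
  expect_gte(f2$logLik, f1$logLik - 1e-6)
})

test_that("long branches are flagged strictly above the threshold", {
  tree <- label_internal_nodes(ape::read.tree(
    text = "((a:0.71,b:0.70):0.75,(c:0.1,d:0.1):0.1);"))
  out <- detect_long_branches(tree, 0.7)
  expect_equal(out$leaves, "a")
  expect_equal(nrow(out$internal), 1)
  expect_equal(out$internal$length, 0.75)

  tree2 <- label_internal_nodes(ape::read.tree(text = "((a:0.1,b:0.1):0.1,c:0.1);"))
  out2 <- detect_long_branches(tree2, 0.7)
  expect_equal(length(out2$leaves), 0)
  expect_equal(nrow(out2$internal), 0)
})
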