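post_mat <- function(...) {
  # build a sites x 20 posterior matrix from named per-site probability lists
  rows <- list(...)
  p <- matrix(0, length(rows), 20, dimnames = list(NULL, amino_acids()))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    p[i, names(r)] <- unlist(r)
    rest <- setdiff(amino_acids(), names(r))
    p[i, rest] <- (1 - sum(unlist(r))) / length(rest)
  }
  p
}

test_that("marginal posteriors obey limiting and symmetry cases", {
  lg <- lg_model()
  t0 <- label_internal_nodes(ape::read.tree(text = "(a:1e-9,b:1e-9);"))
  asr <- marginal_posteriors(t0, aa_alignment(c(a = "M", b = "M")), lg)
  expect_gt(asr$posteriors[[1]][1, "M"], 1 - 1e-6)

  # star tree, uniform model, 2 x A and 2 x C: symmetric root posterior
  star <- label_internal_nodes(ape::read.tree(text = "(a:0.2,b:0.2,c:0.2,d:0.2);"))
  u <- uniform_model()
  asr2 <- marginal_posteriors(star, aa_alignment(c(a = "A", b = "A", c = "C", d = "C")), u)
  p <- asr2$posteriors[[1]]
  expect_equal(unname(p[1, "A"]), unname(p[1, "C"]), tolerance = 1e-12)

  unrooted <- ape::unroot(ape::rtree(4))
  expect_error(marginal_posteriors(unrooted, aa_alignment(c(t1 = "A", t2 = "A", t3 = "A", t4 = "A")), lg),
               "unrooted|root")
  tr <- label_internal_nodes(ape::rtree(3))
  expect_error(marginal_posteriors(tr, aa_alignment(c(t1 = "A", t2 = "A", t3 = "A")), lg,
                                   nodes = "NoSuchNode"), "unknown node")
})

test_that("posteriors match the enumeration oracle with rate mixtures", {
  set.seed(77)
  tree <- random_tree(4)
  model <- random_model(K = 2)
  aln <- random_alignment(tree, 4, model, seed = 3)
  asr <- marginal_posteriors(tree, aln, model)
  oracle <- enum_oracle(tree, aln, model)
  for (nd in tree$node.label) {
    expect_equal(asr$posteriors[[nd]], oracle$posteriors[[nd]], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(unname(rowSums(asr$posteriors[[nd]])), rep(1, asr$n_sites),
                 tolerance = 1e-6)
  }
  expect_equal(asr$site_loglik, oracle$site_loglik, tolerance = 1e-8)
})

test_that("ML sequence takes the per-site argmax with alphabetical tie-break", {
  p <- post_mat(list(M = 0.9), list(A = 0.5, C = 0.5), list(W = 1))
  ml <- ml_sequence(p)
  expect_equal(ml$sequence, "MAW")
  expect_equal(ml$max_pp, c(0.9, 0.5, 1))

  # point-mass sites reproduce the generating sequence
  gen <- c("K", "Y", "D")
  pm <- matrix(0, 3, 20, dimnames = list(NULL, amino_acids()))
  pm[cbind(1:3, match(gen, amino_acids()))] <- 1
  expect_equal(ml_sequence(pm)$states, gen)
})

test_that("ambiguity flagging uses a strict threshold over two or more states", {
  p <- post_mat(list(A = 0.5, C = 0.3, D = 0.2),
                list(A = 0.95, C = 0.05),
                list(A = 0.21, C = 0.21, D = 0.21, E = 0.37))
  expect_equal(flag_ambiguous(p), c(TRUE, FALSE, TRUE))
  # exactly 0.2 does not count
  p2 <- post_mat(list(A = 0.8, C = 0.2))
  expect_false(flag_ambiguous(p2)[1])
})

test_that("AltALL swaps exactly the ambiguous sites to second-ranked states", {
  p <- post_mat(list(A = 0.5, C = 0.3, D = 0.2), list(M = 0.95))
  alt <- altall_sequence(p)
  expect_equal(alt$sequence, "CM")
  ml <- ml_sequence(p)
  expect_equal(sum(strsplit(alt$sequence, "")[[1]] != ml$states),
               sum(flag_ambiguous(p)))

  # no ambiguity: AltALL equals the ML sequence
  p2 <- post_mat(list(W = 0.99), list(K = 0.97))
  expect_equal(altall_sequence(p2)$sequence, ml_sequence(p2)$sequence)
})

test_that("PP summaries cover point-mass, uniform and subset cases", {
  pm <- matrix(0, 5, 20, dimnames = list(NULL, amino_acids()))
  pm[cbind(1:5, 1:5)] <- 1
  s <- pp_summary(pm)
  expect_equal(s$mean_pp, 1)
  expect_equal(s$ln_pp, 0)
  expect_equal(s$fraction_ambiguous, 0)

  un <- matrix(1 / 20, 4, 20, dimnames = list(NULL, amino_acids()))
  expect_equal(pp_summary(un)$mean_pp, 0.05)

  expect_error(pp_summary(pm, columns = integer(0)), "empty")
  expect_equal(pp_summary(pm, columns = 1:2)$n_sites, 2)

  # mean PP invariant to site permutation
  set.seed(2)
  p <- matrix(rgamma(200, 1), 10, 20)
  p <- p / rowSums(p)
  colnames(p) <- amino_acids()
  expect_equal(pp_summary(p)$mean_pp, pp_summary(p[sample(10), ])$mean_pp)
})

test_that("ancestor comparison classifies differing sites by confidence", {
  p1 <- post_mat(list(M = 0.95), list(A = 0.99), list(K = 0.5, R = 0.3))
  p2 <- post_mat(list(M = 0.95), list(C = 0.5, D = 0.3), list(K = 0.5, R = 0.3))
  d <- ancestor_diff(p1, p2)
  expect_equal(nrow(d), 1)
  expect_equal(d$class, "first_only")
  expect_equal(attr(d, "identity"), 100 * 2 / 3, tolerance = 1e-12)

  # identical ancestors
  d0 <- ancestor_diff(p1, p1)
  expect_equal(nrow(d0), 0)
  expect_equal(attr(d0, "identity"), 100)

  # antisymmetry of class labels under argument swap
  dr <- ancestor_diff(p2, p1)
  expect_equal(dr$class, "second_only")

  pbad <- post_mat(list(M = 1))
  expect_error(ancestor_diff(p1, pbad), "different column sets")
})

test_that("logo matrices are frequencies for clades and posteriors for ancestors", {
  aln <- aa_alignment(c(x = "AAC", y = "AAC", z = "ACC"))
  L <- logo_matrix(aln, columns = 1:3)
  expect_equal(unname(L["A", ]), c(1, 2 / 3, 0))
  expect_equal(unname(colSums(L)), rep(1, 3))

  a2 <- aa_alignment(c(x = "A-", y = "C-"))
  expect_warning(L2 <- logo_matrix(a2, columns = 1:2), "all-gap")
  expect_equal(unname(L2[, 2]), rep(0, 20))
  expect_equal(unname(L2["A", 1]), 0.5)

  p <- post_mat(list(A = 0.7, C = 0.3))
  Lp <- logo_matrix(p, columns = 1)
  expect_equal(unname(Lp["A", 1]), 0.7)
})

test_that("asr objects export valid state tables and summaries", {
  set.seed(9)
  tree <- random_tree(6)
  lg <- lg_model()
  aln <- random_alignment(tree, 30, lg, seed = 5)
  asr <- marginal_posteriors(tree, aln, lg)
  st <- as_state_table(asr)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_state_table(st, f)
  back <- read_state_table(f)
  expect_equal(nrow(back), length(tree$node.label) * 30)
  expect_equal(back$State[back$Node == tree$node.label[1]],
               ml_sequence(asr, tree$node.label[1])$states)

  sm <- summary(asr)
  expect_true(all(sm$mean_pp >= 0 & sm$mean_pp <= 1))
  expect_true(all(sm$ln_pp <= 0))
  expect_output(print(asr), "Marginal ancestral reconstruction")
})
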