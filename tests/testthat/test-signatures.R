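# A toy "reference" row: residues chosen so the bundled Glt_Ph-numbered
# schemes can be probed on a short synthetic alignment via a custom map.
toy_scheme <- function() {
  signature_scheme(c(2, 4, 5), list(c("S", "T"), "N", c("D", "E")), name = "toy_na")
}

test_that("signature matching checks allowed sets, gaps and unmappable positions", {
  aln <- aa_alignment(c(ref = "ASKND", na_ok = "GTKND", h_like = "GAKND",
                        gappy = "AS-N-"))
  map <- build_reference_map(aln, "ref")
  sch <- toy_scheme()

  expect_true(as.logical(matches_signature(aln, "na_ok", sch, map)))
  m2 <- matches_signature(aln, "h_like", sch, map)
  expect_false(as.logical(m2))
  detail <- attr(m2, "detail")
  expect_false(detail$pass[detail$position == 2])

  g <- matches_signature(aln, "gappy", sch, map)
  expect_false(as.logical(g))
  expect_match(attr(g, "detail")$note[3], "gap at 5")

  # unmappable constraint: fail by default, skippable by option
  far <- signature_scheme(c(2, 99), list(c("S", "T"), "N"))
  expect_false(as.logical(matches_signature(aln, "na_ok", far, map)))
  expect_true(as.logical(matches_signature(aln, "na_ok", far, map,
                                           unmappable = "skip")))
})

test_that("removing a constraint never flips a match from true to false", {
  set.seed(41)
  aln_rows <- vapply(1:20, function(i)
    paste(sample(c(amino_acids(), "-"), 12, replace = TRUE, prob = c(rep(1, 20), 3)),
          collapse = ""), character(1))
  names(aln_rows) <- paste0("s", 1:20)
  aln_rows["ref"] <- paste(sample(amino_acids(), 12, replace = TRUE), collapse = "")
  aln_rows["hit"] <- "MAKLNYWTDKLV"  # satisfies every constraint below
  aln <- aa_alignment(aln_rows)
  map <- build_reference_map(aln, "ref")
  sch <- signature_scheme(c(2, 5, 9), list(c("A", "S"), c("N", "Q"), c("D", "E")))
  sub <- signature_scheme(c(2, 5), list(c("A", "S"), c("N", "Q")))
  n_checked <- 0
  for (id in c(paste0("s", 1:20), "hit")) {
    if (as.logical(matches_signature(aln, id, sch, map))) {
      expect_true(as.logical(matches_signature(aln, id, sub, map)))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 1)
})

test_that("bundled schemes load and describe the expected constraints", {
  na <- read_scheme("na_complete")
  expect_setequal(na$positions, c(92, 93, 310, 311, 312, 405))
  expect_setequal(na$allowed[[which(na$positions == 311)]], c("M", "S"))
  h <- read_scheme("h_signature")
  expect_setequal(h$allowed[[which(h$positions == 92)]],
                  c("A", "L", "I", "V", "M", "F"))
  expect_equal(h$allowed[[which(h$positions == 311)]], "L")
  expect_equal(h$allowed[[which(h$positions == 405)]], "N")
})

test_that("clade statistics report per-clade match percentages", {
  aln <- aa_alignment(c(ref = "ASKND",
                        a1 = "ASKND", a2 = "GTKND", a3 = "GAKND",
                        b1 = "GAKND", b2 = "GLKND"))
  map <- build_reference_map(aln, "ref")
  clades <- c(a1 = "cladeA", a2 = "cladeA", a3 = "cladeA",
              b1 = "cladeB", b2 = "cladeB")
  st <- clade_signature_stats(aln, clades, toy_scheme(), map)
  a <- st[st$clade == "cladeA", ]
  expect_equal(a$n, 3)
  expect_equal(a$n_matching, 2)
  expect_equal(a$percent, 66.7)
  b <- st[st$clade == "cladeB", ]
  expect_equal(b$percent, 0)
})

test_that("clade assignment follows subtree roots and rejects overlap", {
  tree <- label_internal_nodes(ape::read.tree(
    text = "((a:1,b:1)cladeX:1,(c:1,d:1)cladeY:1)root;"))
  cl <- assign_clades(tree, c(X = "cladeX", Y = "cladeY"))
  expect_equal(unname(cl[c("a", "b", "c", "d")]), c("X", "X", "Y", "Y"))
  expect_error(assign_clades(tree, c(X = "cladeX", ALL = "root")), "overlap")
  expect_error(assign_clades(tree, c(Z = "nope")), "not in tree")
})

test_that("pairwise identity is symmetric with unit diagonal and gap-aware denominator", {
  aln <- aa_alignment(c(a = "MKLVAYTRDD", b = "MKLVAYTRDA", c = "MKLVAYTRDD"))
  pid <- pairwise_identity(aln)
  expect_equal(unname(diag(pid)), rep(100, 3))
  expect_equal(pid, t(pid))
  expect_equal(pid["a", "b"], 90)
  expect_equal(pid["a", "c"], 100)

  g <- aa_alignment(c(a = "MK--", b = "--LV"))
  expect_warning(pg <- pairwise_identity(g), "zero comparable")
  expect_true(is.na(pg["a", "b"]))

  expect_error(pairwise_identity(aa_alignment(c(a = "MK"))), "at least 2")
})

test_that("mutations parse, validate and invert", {
  aln <- aa_alignment(c(ref = "PKQS"))
  map <- build_reference_map(aln, "ref")
  s <- "PKQS"
  m1 <- apply_mutations(s, "P1S", map)
  expect_equal(as.character(m1), "SKQS")
  back <- apply_mutations(as.character(m1), "S1P", map)
  expect_equal(as.character(back), s)

  # order independence on disjoint sites
  ab <- apply_mutations(as.character(apply_mutations(s, "P1S", map)), "Q3N", map)
  ba <- apply_mutations(as.character(apply_mutations(s, "Q3N", map)), "P1S", map)
  expect_equal(as.character(ab), as.character(ba))

  expect_error(apply_mutations(s, "273S", map), "malformed")
  expect_error(apply_mutations(s, "S1P", map), "expected-residue")
})

test_that("construct design interleaves ancestor and donor and logs changes", {
  # full alignment: columns 3-5 are a stripped loop provided by the donor
  full <- aa_alignment(c(donor = "MAKKSLV", other = "MA---LV"))
  mask <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE)
  anc <- "MGIV"  # residues for retained columns 1,2,6,7
  map <- build_reference_map(full, "donor")

  expect_error(design_construct("MG", full, "donor", mask), "retained columns")

  built <- design_construct(anc, full, "donor", mask)
  expect_equal(as.character(built), "MGKKSIV")
  expect_equal(attr(built, "log")$grafts$start_col, 3)
  expect_equal(attr(built, "log")$grafts$end_col, 5)

  # K -> H substitutions on the donor-derived loop (positions 3 and 4 in donor numbering)
  mut <- design_construct(anc, full, "donor", mask,
                          mutations = c("K3H", "K4H"), reference_map = map)
  expect_equal(as.character(mut), "MGHHSIV")
  expect_equal(nrow(attr(mut, "log")$mutations), 2)

  expect_error(design_construct(anc, full, "donor", mask,
                                mutations = "S3P", reference_map = map),
               "expected-residue")
  expect_error(design_construct(anc, full, "other", mask), "gap inside a graft")

  # no grafts, no mutations: identity on the ancestor
  all_mask <- rep(TRUE, 7)
  same <- design_construct("MAKKSLV", full, "donor", all_mask)
  expect_equal(as.character(same), "MAKKSLV")
})
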