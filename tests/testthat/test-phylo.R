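test_that("p and Poisson distances follow their closed forms", {
  # 10 ungapped columns, 1 mismatch between a and b
  msa <- msa_from_strings(c("a", "b", "c"),
                          c("AAAAAAAAAA", "AAAAAAAAAW", "WWWWWAAAAA"))
  d <- distance_matrix(msa, "p")
  expect_equal(d["a", "b"], 0.1)
  dp <- distance_matrix(msa, "poisson")
  expect_equal(dp["a", "b"], -log(0.9))
  expect_equal(diag(dp), c(a = 0, b = 0, c = 0))

  # identical rows -> zero distance
  same <- msa_from_strings(c("a", "b", "c"), rep("ACDEF", 3))
  expect_true(all(distance_matrix(same, "p") == 0))

  # pairwise deletion: gapped columns excluded per pair
  gap <- msa_from_strings(c("a", "b", "c"), c("A-CD", "AWCD", "AWCC"))
  expect_equal(distance_matrix(gap, "p")["a", "b"], 0)

  # zero comparable columns is an error naming the pair
  bad <- msa_from_strings(c("a", "b", "c"), c("A--", "-W-", "AWC"))
  expect_error(distance_matrix(bad, "p"), "a / b")

  # saturation cap for the Poisson correction
  sat <- msa_from_strings(c("a", "b", "c"),
                          c(strrep("A", 20), strrep("W", 20),
                            strrep("A", 20)))
  ds <- distance_matrix(sat, "poisson")
  expect_equal(ds["a", "b"], -log(1 - 0.95))
  expect_equal(ds["b", "c"], -log(1 - 0.95))
  expect_equal(nrow(attr(ds, "saturated_pairs")), 2L)  # a/b and b/c saturate

  # symmetry on seeded random alignments
  set.seed(707)
  for (k in 1:5) {
    rows <- vapply(1:4, function(i) random_seq(30, c("A", "C", "D", "-")),
                   character(1))
    m <- msa_from_strings(paste0("t", 1:4), rows)
    dd <- tryCatch(distance_matrix(m, "p"), error = function(e) NULL)
    if (!is.null(dd)) {
      expect_identical(dd, t(dd))
      expect_true(all(diag(dd) == 0))
    }
  }
})

test_that("NJ recovers the known quartet with exact branch lengths", {
  taxa <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- nj_tree(d)
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_true(is_monophyletic(tr, c("C", "D")))
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[taxa, taxa] - d)), 0)

  # 3 taxa: unique topology, three-point closed-form lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- nj_tree(d3)
  len <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(unname(len[c("x", "y", "z")]), c(0, 2, 3))

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b")))))
})

test_that("NJ is exact on seeded random additive matrices", {
  set.seed(808)
  for (k in 1:20) {
    n <- sample(4:8, 1)
    truth <- random_additive_tree(n)
    d <- ape::cophenetic.phylo(truth)
    ord <- order(rownames(d))
    tr <- nj_tree(d[ord, ord])
    expect_equal(ape::dist.topo(ape::unroot(truth), tr), 0,
                 ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)] - d)),
              1e-9)
    # independent cross-check against ape's NJ topology
    expect_equal(ape::dist.topo(ape::nj(d), tr), 0, ignore_attr = TRUE)
  }
})

test_that("the NJ tree is invariant to taxon input order", {
  set.seed(909)
  truth <- random_additive_tree(6)
  d <- ape::cophenetic.phylo(truth)
  base <- nj_tree(d)
  for (k in 1:5) {
    perm <- sample(nrow(d))
    tr <- nj_tree(d[perm, perm])
    expect_equal(ape::dist.topo(base, tr), 0, ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are deterministic, bounded and signal-driven", {
  # two highly distinct clades with identical within-clade rows
  rows <- c(a1 = strrep("AC", 15), a2 = strrep("AC", 15),
            b1 = strrep("WY", 15), b2 = strrep("WY", 15),
            b3 = strrep("WY", 15))
  msa <- msa_from_strings(names(rows), unname(rows))
  tr <- bootstrap_support(msa, n_replicates = 25, seed = 3)
  sup <- attr(tr, "supports")
  expect_true(all(sup >= 0 & sup <= 1))
  expect_equal(clade_support(tr, c("a1", "a2")), 1.0)

  # single replicate -> support in {0, 1}
  tr1 <- bootstrap_support(msa, n_replicates = 1, seed = 3)
  expect_true(all(attr(tr1, "supports") %in% c(0, 1)))

  # same seed twice -> identical supports
  tr2 <- bootstrap_support(msa, n_replicates = 25, seed = 3)
  expect_identical(attr(tr, "supports"), attr(tr2, "supports"))
})

test_that("monophyly is a bipartition test on the unrooted tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D")))  # full leaf set
  expect_true(is_monophyletic(tr, "A"))
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown taxon")

  # outgroup-aware rooted variant
  tr5 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,O:3);")
  expect_true(is_monophyletic(tr5, c("A", "B"), outgroup = "O"))
  expect_false(is_monophyletic(tr5, c("B", "C"), outgroup = "O"))
})

test_that("newick output preserves lengths and support labels", {
  rows <- c(a1 = strrep("ACDE", 10), a2 = strrep("ACDE", 10),
            b1 = strrep("WYKR", 10), b2 = strrep("WYKR", 10))
  msa <- msa_from_strings(names(rows), unname(rows))
  tr <- bootstrap_support(msa, n_replicates = 10, seed = 1)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, names(rows))
  expect_equal(sort(back$edge.length), sort(tr$edge.length))
})
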