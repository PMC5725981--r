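# p-distances, neighbor joining against an additive-matrix oracle,
# bootstrap supports and clade purity.

test_that("p-distances follow the identity definition", {
  seqs <- c(a = "MKVLQWERTYMKVLQWERTY",
            b = "MKVLQWERTYMKVLQWERTY",
            c = "MKVAQWERTYMKVAQWERTY")  # 2 of 20 positions differ
  d <- pdistance_matrix(seqs)
  expect_equal(unname(d["a", "b"]), 0)
  expect_equal(unname(d["a", "c"]), 2 / 20)
  expect_true(isSymmetric(unname(d)))
  expect_equal(unname(diag(d)), rep(0, 3))
})

test_that("NJ reproduces an additive 4-taxon tree exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:1);")
  d <- ape::cophenetic.phylo(tr)
  got <- nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(got)), 0,
               ignore_attr = TRUE)
  # branch lengths recovered: path lengths must match the input distances
  expect_equal(ape::cophenetic.phylo(got)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  # and the split agrees with the four-point-condition oracle
  split <- oracle_quartet_split(d)
  expect_true(tree_has_split(got, split[[1]]))
})

test_that("NJ recovers random additive trees (4-8 taxa)", {
  set.seed(41)
  for (n in c(4, 4, 5, 5, 6, 7, 8)) {
    tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.2, 1))
    d <- ape::cophenetic.phylo(tr)
    got <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(got)), 0,
                 ignore_attr = TRUE)
    if (n == 4) {
      split <- oracle_quartet_split(d)
      expect_true(tree_has_split(got, split[[1]]))
    }
  }
})

test_that("NJ validates its input and clamps negative branch lengths", {
  bad <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(matrix(0, 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "at least 3")
  # a 3-taxon star has the closed-form solution of the three equations
  d3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  expect_equal(sort(t3$edge.length), sort(c(0, 2, 3)))
})

test_that("bootstrap supports separate well-defined clusters and are
           reproducible", {
  set.seed(43)
  base1 <- paste(sample(setfam:::aa_alphabet(), 120, replace = TRUE),
                 collapse = "")
  base2 <- paste(sample(setfam:::aa_alphabet(), 120, replace = TRUE),
                 collapse = "")
  seqs <- c(
    setNames(vapply(1:4, function(i) setfam:::mutate_seq(base1, 0.03), ""),
             paste0("x", 1:4)),
    setNames(vapply(1:4, function(i) setfam:::mutate_seq(base2, 0.03), ""),
             paste0("y", 1:4)))
  tr <- bootstrap_support(seqs, n_reps = 100, seed = 99)
  sup <- attr(tr, "support")
  # the x|y bipartition exists and is near-certain
  expect_true(tree_has_split(tr, paste0("x", 1:4)))
  expect_gte(max(sup, na.rm = TRUE), 95)

  tr2 <- bootstrap_support(seqs, n_reps = 100, seed = 99)
  expect_identical(attr(tr, "support"), attr(tr2, "support"))

  one <- bootstrap_support(seqs, n_reps = 1, seed = 7)
  expect_true(all(attr(one, "support") %in% c(0, 100, NA)))
})

test_that("clade purity is exact on pure trees and matches the edge-scan
           oracle elsewhere", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  lab <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  p <- class_purity(tr, lab)
  expect_equal(unname(p$per_family[c("A", "B")]), c(1, 1))

  # interleaved labels on a caterpillar tree
  cat_tr <- ape::read.tree(text = "(t1:1,(t2:1,(t3:1,(t4:1,t5:1):1):1):1);")
  lab2 <- c(t1 = "A", t2 = "B", t3 = "A", t4 = "B", t5 = "A")
  p2 <- class_purity(cat_tr, lab2)
  want <- oracle_purity(cat_tr, lab2)
  expect_equal(p2$per_family[names(want)], want)

  # single family is trivially pure
  p3 <- class_purity(tr, setNames(rep("Z", 4), names(lab)))
  expect_equal(unname(p3$per_family), 1)
})

test_that("simulated four-family SET domains cluster by family", {
  fs <- generate_family_sequences(seed = 42)
  seqs <- setNames(fs$sequence, fs$id)
  tr <- nj_tree(pdistance_matrix(seqs))
  cp <- class_purity(tr, setNames(fs$family, fs$id))
  expect_gte(cp$mean, 0.9)
})

test_that("PHYLIP distance matrices round-trip through disk", {
  d <- matrix(c(0, .1, .2, .1, 0, .3, .2, .3, 0), 3, 3,
              dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3")))
  f <- tempfile(fileext = ".phy")
  write_phylip_dist(d, f)
  expect_equal(read_phylip_dist(f), d, tolerance = 1e-6)
})
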