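test_that("Newick parsing handles branch-length defaults, errors and round-trips", {
  tr <- readNewick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(treeHeight(tr), 2)

  # branchless Newick gets unit lengths throughout
  tr1 <- readNewick("((A,B),C);")
  expect_true(all(tr1$edge.length == 1))

  expect_error(readNewick("((A:1,A:1):1,C:2);"), "duplicate tip")
  expect_error(readNewick("((A:1,B:1:1,C:2);"), "position")
  expect_error(readNewick("((A:1,B:1)):1,C:2);"), "position")
  expect_error(readNewick("(A:1,B:1)"), "position")

  # round trip preserves topology, labels and lengths
  for (seed in 1:5) {
    tr0 <- randUltraTree(8, seed)
    tr2 <- readNewick(writeNewick(tr0))
    expect_setequal(tr2$tip.label, tr0$tip.label)
    d0 <- ape::cophenetic.phylo(tr0)
    d2 <- ape::cophenetic.phylo(tr2)[rownames(d0), colnames(d0)]
    expect_equal(d2, d0, tolerance = 1e-9)
  }
})

test_that("node ages follow the tip-zero / root-maximal convention", {
  ages <- nodeAges(readNewick("((A:1,B:1):1,C:2);"))
  expect_equal(unname(ages[c("A", "B", "C")]), c(0, 0, 0))
  expect_equal(sort(unname(ages[4:5])), c(1, 2))

  star <- readNewick("(A:3,B:3,C:3);")
  expect_equal(max(nodeAges(star)), 3)

  expect_error(nodeAges(readNewick("((A:1,B:2):1,C:2);")), "ultrametric")
})

test_that("terminal-branch extension ultrametrizes and is idempotent", {
  tr <- readNewick("((A:1,B:2):1,C:2);")
  u <- forceUltrametricExtend(tr)
  expect_true(isUltrametric(u))
  expect_equal(treeHeight(u), 3)
  # A's terminal branch extended from 1 to 2
  aEdge <- which(u$edge[, 2] == match("A", u$tip.label))
  expect_equal(u$edge.length[aEdge], 2)
  expect_equal(forceUltrametricExtend(u), u)

  expect_equal(treeHeight(forceUltrametricExtend(readNewick("(A:1,B:5);"))), 5)

  # already-ultrametric tree unchanged
  tu <- readNewick("((A:1,B:1):1,C:2);")
  expect_equal(forceUltrametricExtend(tu), tu)

  # agrees with the reference implementation on random non-ultrametric trees
  skip_if_not_installed("phytools")
  set.seed(7)
  tr <- ape::rtree(12)
  mine <- forceUltrametricExtend(tr)
  ref <- suppressWarnings(phytools::force.ultrametric(tr, method = "extend",
                                                      message = FALSE))
  expect_equal(ape::cophenetic.phylo(mine), ape::cophenetic.phylo(ref),
               tolerance = 1e-9)
})

test_that("polytomy resolution preserves all pairwise tip distances", {
  tr <- readNewick("(A:1,B:1,C:1);")
  r <- resolvePolytomies(tr, seed = 3)
  expect_true(ape::is.binary(r))
  expect_equal(ape::cophenetic.phylo(r)[c("A", "B", "C"), c("A", "B", "C")],
               ape::cophenetic.phylo(tr), tolerance = 1e-12)

  # binary tree returned unchanged
  bt <- readNewick("((A:1,B:1):1,C:2);")
  expect_identical(resolvePolytomies(bt, seed = 1), bt)

  # 5-way polytomy: different seeds, identical cophenetic matrices
  p5 <- readNewick("(A:2,B:2,C:2,D:2,E:2);")
  lab <- p5$tip.label
  d0 <- ape::cophenetic.phylo(p5)[lab, lab]
  for (s in c(1, 99)) {
    rs <- resolvePolytomies(p5, seed = s)
    expect_true(ape::is.binary(rs))
    expect_equal(ape::cophenetic.phylo(rs)[lab, lab], d0, tolerance = 1e-12)
    expect_true(isUltrametric(rs))
  }
})

test_that("consensus keeps majority clades with per-clade mean edge lengths", {
  t1 <- readNewick("((A:1,B:1):1,C:2);")
  # identical copies reproduce the tree
  cons <- consensusWithEdges(list(t1, t1, t1))
  expect_equal(ape::cophenetic.phylo(cons)[t1$tip.label, t1$tip.label],
               ape::cophenetic.phylo(t1), tolerance = 1e-12)

  # 2:1 topology vote
  t2 <- readNewick("((A:1,C:1):1,B:2);")
  cons <- consensusWithEdges(list(t1, t1, t2))
  ab <- ape::getMRCA(cons, c("A", "B"))
  expect_false(ab == ape::Ntip(cons) + 1)  # A+B clade retained (not the root)
  expect_true(is.null(ape::getMRCA(cons, c("A", "C"))) ||
                ape::getMRCA(cons, c("A", "C")) == ape::Ntip(cons) + 1)

  # same topology, lengths 1 vs 3 -> mean 2
  ta <- readNewick("((A:1,B:1):1,C:1);")
  tb <- readNewick("((A:3,B:3):3,C:3);")
  cons <- consensusWithEdges(list(ta, tb))
  expect_true(all(abs(cons$edge.length - 2) < 1e-12))

  expect_error(consensusWithEdges(list(t1, readNewick("(A:1,D:1);"))),
               "tip sets")
})

test_that("taxonomy converts to a height-4 unit-branch rank tree", {
  tax <- data.frame(
    species = c("s1", "s2", "s3", "s4", "s5"),
    genus = c("g1", "g1", "g2", "g3", "g4"),
    subfamily = c("sf1", "sf1", "sf1", "sf2", "sf3"),
    family = c("f1", "f1", "f1", "f1", "f2"))
  tr <- taxonomyToTree(tax)
  expect_true(isUltrametric(tr))
  expect_equal(treeHeight(tr), 4)
  D <- ape::cophenetic.phylo(tr)
  expect_equal(D["s1", "s2"], 2)  # congeners
  expect_equal(D["s1", "s3"], 4)  # same subfamily
  expect_equal(D["s1", "s4"], 6)  # same family only
  expect_equal(D["s1", "s5"], 8)  # different families

  badTax <- tax
  badTax$subfamily[2] <- "sf9"    # genus g1 in two subfamilies
  expect_error(taxonomyToTree(badTax), "inconsistent")
})

test_that("pruning collapses paths and keeps full-tree depth as a stem", {
  tr <- readNewick("((A:1,B:1):1,C:2);")
  p <- pruneKeepDepth(tr, c("A", "C"))
  expect_setequal(p$tip.label, c("A", "C"))
  expect_equal(sort(p$edge.length), c(2, 2))
  expect_equal(treeHeight(p, includeRootEdge = TRUE), 2)

  expect_identical(pruneKeepDepth(tr, c("A", "B", "C")), tr)

  p1 <- pruneKeepDepth(tr, "A")
  expect_equal(ape::Ntip(p1), 1)
  expect_equal(treeHeight(p1, includeRootEdge = TRUE), 2)

  pab <- pruneKeepDepth(tr, c("A", "B"))
  expect_equal(pab$root.edge, 1)
  expect_equal(treeHeight(pab, includeRootEdge = TRUE), 2)

  expect_error(pruneKeepDepth(tr, c("A", "Z")), "unknown tip")
})
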