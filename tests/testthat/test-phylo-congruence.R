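test_that("Newick parsing recovers topology, lengths and support scale", {
  tr <- parseNewick("((A:1,B:2):3,C:4);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(tr$Nnode, 2)
  tr2 <- parseNewick("((A:1,B:2)950:3,C:4);")
  expect_equal(attr(tr2, "supportScale"), "permille")
  expect_true("950" %in% tr2$node.label)
  tr3 <- parseNewick("((A:1,B:2)0.95:3,C:4);")
  expect_equal(attr(tr3, "supportScale"), "fraction")
})

test_that("Newick syntax and label errors are reported with positions", {
  expect_error(parseNewick("((A:1,B:2):3,C:4;"), "unbalanced")
  expect_error(parseNewick("(A:1,B:2)):3;"), "position")
  expect_error(parseNewick("((A:1,A:2):3,C:4);"), "duplicate")
  expect_warning(parseNewick("((A,B),C);"), "branch lengths")
})

test_that("writer-then-parser is the identity on random trees", {
  set.seed(21)
  for (i in 1:100) {
    tr <- ape::rtree(sample(4:20, 1))
    back <- parseNewick(writeNewick(tr))
    expect_equal(writeNewick(back), writeNewick(tr))
  }
})

test_that("patristic distances are path sums", {
  tr <- parseNewick("((A:1,B:2):3,C:4);")
  expect_equal(patristicDistance(tr, "A", "C"), 8)
  expect_equal(patristicDistance(tr, "A", "B"), 3)
  expect_equal(patristicDistance(tr, "B", "B"), 0)
  expect_error(patristicDistance(tr, "A", "Z"), "unknown")
})

test_that("patristic matrix equals the all-pairs path-sum oracle", {
  set.seed(22)
  for (i in 1:50) {
    tr <- ape::rtree(sample(4:12, 1))
    D <- patristicMatrix(tr)
    O <- oraclePatristic(tr)
    expect_equal(D[rownames(O), colnames(O)], O, tolerance = 1e-10)
  }
})

test_that("patristic distance is a metric on the leaves", {
  set.seed(23)
  for (i in 1:10) {
    tr <- ape::rtree(8)
    D <- patristicMatrix(tr)
    expect_true(all(D >= 0))
    expect_equal(D, t(D))
    labs <- rownames(D)
    for (a in labs) for (b in labs) for (c in labs)
      expect_lte(D[a, b], D[a, c] + D[c, b] + 1e-10)
  }
})

test_that("collapse contracts exactly the weakly supported nodes", {
  tr <- parseNewick("(((A:1,B:1)650:1,C:1)900:1,(D:1,E:1)800:1);")
  out <- suppressWarnings(collapseLowSupport(tr, 700))
  expect_equal(out$Nnode, tr$Nnode - 1)
  expect_equal(sort(out$tip.label), sort(tr$tip.label))
  # node (A,B) is gone: A and B now attach with C in a polytomy
  expect_false("650" %in% out$node.label)
  expect_true(all(c("900", "800") %in% out$node.label))

  # all nodes at/above the threshold: unchanged; threshold 0: unchanged
  keep <- parseNewick("(((A:1,B:1)700:1,C:1)900:1,(D:1,E:1)800:1);")
  expect_equal(writeNewick(collapseLowSupport(keep, 700)),
               writeNewick(keep))
  expect_equal(writeNewick(collapseLowSupport(tr, 0)), writeNewick(tr))
  expect_error(collapseLowSupport(tr, 2000), "scale")
})

test_that("collapsing a zero-length edge preserves leaf distances", {
  tr <- parseNewick("(((A:1,B:2)650:0,C:3)900:1,(D:1,E:1)800:2);")
  before <- patristicMatrix(tr)
  out <- suppressWarnings(collapseLowSupport(tr, 700))
  after <- patristicMatrix(out)
  expect_equal(after[rownames(before), colnames(before)], before,
               tolerance = 1e-10)
  # redistribute=TRUE pushes the contracted length onto the child edges
  tr2 <- parseNewick("(((A:1,B:2)650:5,C:3)900:1,(D:1,E:1)800:2);")
  out2 <- collapseLowSupport(tr2, 700, redistribute = TRUE)
  expect_equal(patristicDistance(out2, "A", "B"), 1 + 2 + 2 * 5)
  expect_equal(patristicDistance(out2, "A", "C"), 1 + 5 + 3)
})

test_that("congruence: nearest neighbour versus best homology hit", {
  # transferred gene grafted adjacent to the donor leaf
  tr <- parseNewick("(((query:0.02,donor:0.02)950:0.3,rel1:0.3)900:0.2,(rec1:0.3,rec2:0.2)850:0.4);")
  cg <- congruenceCheck(tr, "query", "donor")
  expect_true(isCongruent(cg))
  expect_equal(cg@nearestLeaf, "donor")
  expect_false(cg@tied)
  expect_equal(cg@sisterLeaves, "donor")
  # wrong best hit: incongruent
  expect_false(isCongruent(congruenceCheck(tr, "query", "rec1")))
  # candidate restriction can exclude the donor
  cg2 <- congruenceCheck(tr, "query", "donor",
                         candidates = c("rel1", "rec1", "rec2"))
  expect_equal(cg2@nearestLeaf, "rel1")
  expect_error(congruenceCheck(tr, "query", "donor", candidates = "query"),
               "empty")
  expect_error(congruenceCheck(tr, "absent", "donor"), "not in tree")
})

test_that("ties on a star tree are flagged and broken lexicographically", {
  star <- parseNewick("(q:1,b:1,a:1,c:1);")
  cg <- congruenceCheck(star, "q", "a")
  expect_true(cg@tied)
  expect_equal(cg@nearestLeaf, "a")
  expect_true(isCongruent(cg))
})

test_that("nearest neighbour equals brute-force minimum and survives re-rooting", {
  set.seed(24)
  for (i in 1:50) {
    tr <- ape::rtree(sample(5:12, 1))
    q <- sample(tr$tip.label, 1)
    cg <- congruenceCheck(tr, q, tr$tip.label[1])
    D <- oraclePatristic(tr)
    d <- D[q, setdiff(colnames(D), q)]
    expect_equal(cg@nearestDistance, min(d), tolerance = 1e-10)
    expect_true(cg@nearestLeaf %in% names(d)[d <= min(d) + 1e-12])
    # re-rooting must not change the nearest neighbour
    other <- setdiff(tr$tip.label, q)[1]
    rerooted <- ape::root(tr, outgroup = other, resolve.root = TRUE)
    cg2 <- congruenceCheck(rerooted, q, tr$tip.label[1])
    expect_equal(cg2@nearestDistance, cg@nearestDistance, tolerance = 1e-10)
  }
})
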