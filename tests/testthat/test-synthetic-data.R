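test_that("generateGenome hits its G+C target and is deterministic", {
  g <- generateGenome(100000, 70, seed = 1)
  expect_equal(gcContent(g)$molPercent, 70, tolerance = 0.5 / 70)
  expect_true(abs(gcContent(g)$molPercent - 70) < 0.5)
  at <- generateGenome(500, 0, seed = 2)
  expect_true(all(strsplit(as.character(at), "")[[1]] %in% c("A", "T")))
  expect_equal(as.character(generateGenome(1000, 40, seed = 3)),
               as.character(generateGenome(1000, 40, seed = 3)))
  expect_false(as.character(generateGenome(1000, 40, seed = 3)) ==
                 as.character(generateGenome(1000, 40, seed = 4)))
})

test_that("the identity-to-E map is monotone and spans the needed regimes", {
  ids <- seq(20, 100, by = 5)
  ev <- modelEvalue(ids, 1200)
  expect_true(all(diff(ev) < 0))
  expect_lt(modelEvalue(100, 1200), 1e-180)
  expect_lt(modelEvalue(85, 1200), 1e-200)
  e30 <- modelEvalue(30, 1200)
  expect_gt(e30, 1e-100)
  expect_lt(e30, 1e-50)
})

test_that("scenario validity constraints are enforced", {
  expect_error(transferScenario(geneLength = 1000), "multiple of 3")
  expect_error(transferScenario(geneLength = 6000, genomeLength = 30000),
               "genomeLength/10")
  expect_error(transferScenario(recipientGC = 150), "0, 100")
  expect_error(transferScenario(treeLeaves = 3), "at least 4")
})

test_that("a transfer scenario produces the expected compositional contrast", {
  ds <- simulateTransfer(transferScenario(seed = 101))
  tr <- truthLabels(ds)
  genome <- ds@genomes[["recipient_genome"]]
  gene <- Biostrings::subseq(genome, tr$focalGeneStart, tr$focalGeneEnd)
  expect_equal(gcContent(gene)$molPercent, 71, tolerance = 2 / 71)
  expect_true(abs(gcContent(gene)$molPercent - 71) < 2)
  expect_true(abs(gcContent(genome)$molPercent - 33) < 1)
  # the donor-orthologue hit crushes the recipient paralogue
  hom <- ds@homology
  expect_true(hom$evalue[hom$subject_group == "donor"] <
                hom$evalue[hom$subject_group == "recipient"])
  expect_gt(alienIndex(hom$evalue[hom$subject_group == "recipient"],
                       hom$evalue[hom$subject_group == "donor"]), 30)
  expect_true(hom$pident[hom$subject_group == "donor"] >= 80)
})

test_that("a null scenario yields a negative alien index", {
  ds <- simulateTransfer(transferScenario(seed = 102, transfer = FALSE))
  hom <- ds@homology
  expect_lte(alienIndex(hom$evalue[hom$subject_group == "recipient"],
                        hom$evalue[hom$subject_group == "donor"]), 0)
})

test_that("the embedded motif is recovered at the recorded offset", {
  ds <- simulateTransfer(transferScenario(seed = 103, motifEmbedded = TRUE))
  tr <- truthLabels(ds)
  donorProt <- as.character(ds@proteins[["donor_PAP"]])
  hits <- scanMotif(donorProt, PAP_SIGNATURE_CONSENSUS)
  expect_true(tr$motifStartAA %in% hits$start)
})

test_that("datasets are pure functions of the scenario", {
  a <- simulateTransfer(transferScenario(seed = 104))
  b <- simulateTransfer(transferScenario(seed = 104))
  expect_identical(as.character(a@genomes), as.character(b@genomes))
  expect_identical(a@homology, b@homology)
  expect_identical(writeNewick(a@tree), writeNewick(b@tree))
  expect_identical(a@truth, b@truth)
  c <- simulateTransfer(transferScenario(seed = 105))
  expect_false(identical(as.character(a@genomes[[1]]),
                         as.character(c@genomes[[1]])))
})

test_that("simulated trees place the query next to the truth neighbour", {
  sc <- transferScenario(seed = 106)
  tr <- makeTree(sc)
  expect_true(isCongruent(congruenceCheck(tr, "query_PAP", "donor_PAP")))
  expect_equal(attr(tr, "supportScale"), "permille")
  sup <- as.numeric(tr$node.label[tr$node.label != ""])
  expect_true(all(sup >= 700 & sup <= 1000))
  # collapse at 700 leaves the cherry intact
  collapsed <- collapseLowSupport(tr, 700)
  expect_true(isCongruent(congruenceCheck(collapsed, "query_PAP",
                                          "donor_PAP")))
  # null tree: query nests in the recipient clade
  trNull <- makeTree(transferScenario(seed = 106, transfer = FALSE))
  cg <- congruenceCheck(trNull, "query_PAP", "donor_PAP")
  expect_false(isCongruent(cg))
  expect_equal(cg@nearestLeaf, "recipient_TNT")
  expect_identical(writeNewick(makeTree(sc)), writeNewick(makeTree(sc)))
})

test_that("mobile elements land inside and outside the flank as configured", {
  ds <- simulateTransfer(transferScenario(seed = 107, mgeWithin = 3,
                                          mgeOutside = 2))
  feats <- ds@features
  focal <- feats[S4Vectors::mcols(feats)$ID == "focal_gene"]
  mges <- feats[!is.na(S4Vectors::mcols(feats)$type) &
                  S4Vectors::mcols(feats)$type == "mobile_element"]
  expect_length(mges, 5)
  rep <- proximityReport(focal, mges, flank = 5000)
  expect_equal(nrow(rep), 3)
})
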