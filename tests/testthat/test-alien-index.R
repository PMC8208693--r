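test_that("alienIndex reproduces the documented worked values", {
  expect_equal(round(alienIndex(1e-36, 0)), 378)
  expect_equal(alienIndex(1e-36, 0), log(1e-36 + 1e-200) - log(1e-200))
  expect_equal(alienIndex(2.5e-10, 2.5e-10), 0)
  # missing recipient hit is substituted by E = 1: the maximum regime
  expect_equal(round(alienIndex(NA, 0), 1), 460.5)
  expect_equal(alienIndex(NA, 0), log(1 + 1e-200) - log(1e-200))
  # negative control: strongly negative index
  expect_equal(round(alienIndex(0, 6e-161), 1), -91.6)
  expect_equal(round(alienIndex(9e-19, 0)), 419)
  expect_error(alienIndex(-1, 0), "non-negative")
})

test_that("alienIndex is antisymmetric, monotone and bounded", {
  evals <- c(0, 1e-300, 1e-200, 6e-161, 1e-50, 1e-10, 0.01, 1)
  for (a in evals) for (b in evals) {
    expect_equal(alienIndex(a, b), -alienIndex(b, a))
  }
  # non-increasing in donor E, non-decreasing in recipient E
  sorted <- sort(evals)
  ai_d <- alienIndex(1e-20, sorted)
  expect_true(all(diff(ai_d) <= 0))
  ai_r <- alienIndex(sorted, 1e-20)
  expect_true(all(diff(ai_r) >= 0))
  # bound for recipient E <= 1
  bound <- log(1 + 1e-200) - log(1e-200)
  grid <- expand.grid(r = sorted, d = sorted)
  aig <- alienIndex(grid$r, grid$d)
  expect_true(all(aig <= bound + 1e-12 & aig >= -bound - 1e-12))
})

test_that("classification follows the category definitions", {
  expect_equal(classifyAlienIndex(400, 98.4, identityRule = FALSE),
               "very_likely_hgt")
  expect_equal(classifyAlienIndex(-91.6, 50), "no_hgt_signal")
  expect_equal(classifyAlienIndex(10, 50, identityRule = TRUE),
               "possible_hgt")
  expect_equal(classifyAlienIndex(50, 80, identityRule = TRUE),
               "likely_contamination")
  expect_equal(classifyAlienIndex(50, 50, identityRule = TRUE),
               "very_likely_hgt")
  # boundaries: AI exactly 30 is only "possible", exactly 0 is no signal
  expect_equal(classifyAlienIndex(30, 10), "possible_hgt")
  expect_equal(classifyAlienIndex(0, 10), "no_hgt_signal")
  # without the identity rule, identity never demotes a call
  expect_equal(classifyAlienIndex(400, 98.4), "very_likely_hgt")
})

test_that("bestHits picks minimal E value with documented tie-breaks", {
  hits <- data.frame(
    qseqid = "q",
    sseqid = c("d1", "d2", "r1", "t1", "t2", "t3"),
    pident = c(90, 95, 30, 50, 60, 60),
    length = 100L, mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
    sstart = 1L, send = 100L,
    evalue = c(0, 1e-50, 1e-20, 1e-5, 1e-5, 1e-5),
    bitscore = c(900, 500, 100, 50, 80, 80),
    subject_group = c("donor", "donor", "recipient", "other", "other",
                      "other"))
  best <- bestHits(hits)
  expect_equal(best$donor$sseqid, "d1")
  expect_equal(best$recipient$sseqid, "r1")
  # ties at equal E value resolved by bit score, then identity, then id
  tie <- hits[4:6, ]
  tie$subject_group <- "donor"
  expect_equal(bestHits(tie)$donor$sseqid, "t2")
  tie$bitscore <- 80
  tie$pident <- c(60, 60, 70)
  expect_equal(bestHits(tie)$donor$sseqid, "t3")
  tie$pident <- 60
  expect_equal(bestHits(tie)$donor$sseqid, "t1")
  # self-matches can be excluded; groups can be assigned from taxa sets
  best2 <- bestHits(hits[, setdiff(names(hits), "subject_group")],
                    donorSubjects = c("d1", "d2"),
                    recipientSubjects = "r1", excludeSubjects = "d1")
  expect_equal(best2$donor$sseqid, "d2")
})

test_that("an empty recipient group yields the maximum-regime index", {
  hits <- data.frame(
    qseqid = "q", sseqid = "d1", pident = 98.4, length = 465L,
    mismatch = 7L, gapopen = 0L, qstart = 1L, qend = 465L, sstart = 1L,
    send = 465L, evalue = 0, bitscore = 900,
    subject_group = "donor")
  res <- evaluateAlienIndex(hits)
  expect_equal(round(ai(res), 1), 460.5)
  expect_equal(res@recipientEvalue, 1)
  expect_equal(category(res), "very_likely_hgt")
})

test_that("evaluateAlienIndex composes selection, index and category", {
  hits <- rbind(
    data.frame(qseqid = "q", sseqid = "donor_PAP", pident = 98.4,
               length = 465L, mismatch = 7L, gapopen = 0L, qstart = 1L,
               qend = 465L, sstart = 1L, send = 465L, evalue = 0,
               bitscore = 900, subject_group = "donor"),
    data.frame(qseqid = "q", sseqid = "recipient_TNT", pident = 34.1,
               length = 120L, mismatch = 79L, gapopen = 2L, qstart = 1L,
               qend = 120L, sstart = 1L, send = 120L, evalue = 1e-26,
               bitscore = 120, subject_group = "recipient"))
  res <- evaluateAlienIndex(hits)
  expect_equal(res@aiRounded, 401)
  expect_equal(category(res), "very_likely_hgt")
  expect_s4_class(res, "AlienIndexResult")
})
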