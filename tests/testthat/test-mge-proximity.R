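gr <- function(seq, s, e, strand = "+", id = NULL) {
  g <- GenomicRanges::GRanges(seq, IRanges::IRanges(s, e), strand = strand)
  if (!is.null(id)) S4Vectors::mcols(g)$element_id <- id
  g
}

test_that("flank windows follow the strand and clip at contig bounds", {
  w <- flankWindows(gr("c", 10000, 11000, "+"), 5000, contigLength = 1e6)
  expect_equal(GenomicRanges::start(w$upstream), 5000)
  expect_equal(GenomicRanges::end(w$upstream), 9999)
  expect_equal(GenomicRanges::start(w$downstream), 11001)
  expect_equal(GenomicRanges::end(w$downstream), 16000)
  # minus strand: sides swap relative to coordinates
  wm <- flankWindows(gr("c", 10000, 11000, "-"), 5000, contigLength = 1e6)
  expect_equal(GenomicRanges::start(wm$upstream), 11001)
  expect_equal(GenomicRanges::end(wm$downstream), 9999)
  # gene at contig start: upstream window is empty
  w1 <- flankWindows(gr("c", 1, 900, "+"), 5000, contigLength = 1e6)
  expect_length(w1$upstream, 0)
  # clipping near the origin
  w2 <- flankWindows(gr("c", 3000, 4000, "+"), 5000, contigLength = 1e6)
  expect_equal(GenomicRanges::start(w2$upstream), 1)
  expect_error(flankWindows(gr("c", 10, 20), -1, 100), "non-negative")
})

test_that("gene-element distances use the terminal-base convention", {
  gene <- gr("c", 1000, 2000, "+", id = "gene1")
  r <- mgeDistance(gene, gr("c", 2301, 2330, id = "m1"))
  expect_equal(r$side, "downstream")
  expect_equal(r$distance, 301)
  expect_true(r$within_flank)
  # abutting element is at distance 1 under the difference convention
  expect_equal(mgeDistance(gene, gr("c", 2001, 2100))$distance, 1)
  expect_equal(mgeDistance(gene, gr("c", 500, 999))$distance, 1)
  expect_equal(mgeDistance(gene, gr("c", 400, 699))$side, "upstream")
  ov <- mgeDistance(gene, gr("c", 1500, 2500))
  expect_equal(ov$distance, 0)
  expect_true(ov$overlap)
  expect_error(mgeDistance(gene, gr("other", 10, 20)), "different")
})

test_that("minus-strand distances mirror the plus-strand case", {
  L <- 100000
  gene <- gr("c", 1000, 2000, "+")
  mge <- gr("c", 2301, 2330)
  fwd <- mgeDistance(gene, mge)
  # reverse-complement all coordinates
  flip <- function(g) {
    s <- L - GenomicRanges::end(g) + 1
    e <- L - GenomicRanges::start(g) + 1
    st <- as.character(GenomicRanges::strand(g))
    gr("c", s, e, strand = if (st == "+") "-" else "+")
  }
  rev <- mgeDistance(flip(gene), flip(mge))
  expect_equal(rev$distance, fwd$distance)
  expect_equal(rev$side, fwd$side)
})

test_that("distances are translation invariant", {
  set.seed(31)
  for (i in 1:25) {
    s <- sample(5000:9000, 1); w <- sample(100:2000, 1)
    ms <- sample(1000:20000, 1); mw <- sample(20:300, 1)
    gene <- gr("c", s, s + w, sample(c("+", "-"), 1))
    mge <- gr("c", ms, ms + mw)
    base <- mgeDistance(gene, mge)
    off <- sample(1:5000, 1)
    shifted <- mgeDistance(GenomicRanges::shift(gene, off),
                           GenomicRanges::shift(mge, off))
    expect_equal(shifted$distance, base$distance)
    expect_equal(shifted$side, base$side)
  }
})

test_that("proximityReport filters at the flank and annotates fold ratios", {
  gene <- gr("c", 10000, 11000, "+", id = "pcnB")
  mges <- c(gr("c", 11301, 11330, id = "m_near"),
            gr("c", 15800, 15830, id = "m_mid"),
            gr("c", 18000, 18040, id = "m_far"))
  S4Vectors::mcols(mges)$gc <- c(86.4, 60, 70)
  S4Vectors::mcols(mges)$element_class <- "plasmid"
  rep5 <- proximityReport(gene, mges, flank = 5000, genomeGC = 30.4)
  expect_equal(nrow(rep5), 2)
  expect_equal(rep5$element_id, c("m_near", "m_mid"))
  expect_equal(rep5$distance, c(301, 4800))
  expect_equal(rep5$fold_ratio[1], 2.8)
  expect_true(attr(rep5, "anyWithinFlank"))
  # widening the flank never removes rows
  rep7 <- proximityReport(gene, mges, flank = 7001, genomeGC = 30.4)
  expect_true(all(rep5$element_id %in% rep7$element_id))
  expect_equal(nrow(rep7), 3)
  # no elements at all
  rep0 <- proximityReport(gene, mges[0], flank = 5000)
  expect_equal(nrow(rep0), 0)
  expect_false(attr(rep0, "anyWithinFlank"))
})

test_that("MGE hit tables round-trip through the TSV reader", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(element_id = c("plasmid:21669", "prophage:172094"),
                   element_class = c("plasmid", "prophage"),
                   host = c("Ralstonia solanacearum", "Desulfovibrio"),
                   evalue = c(1e-3, 2e-3), pident = c(96, 96),
                   gc = c(74.1, 63.0), seq_id = "c",
                   start = c(4301, 1358), end = c(4327, 1384))
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- readMgeHits(f)
  expect_length(g, 2)
  expect_equal(S4Vectors::mcols(g)$element_id, df$element_id)
  expect_equal(GenomicRanges::start(g), df$start)
  writeLines("element_id\tstart\tend", f)
  expect_error(readMgeHits(f), "seq_id")
})
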