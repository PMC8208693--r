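# Independent oracles used by the unit and property tests. These re-derive
# the expected results by the most transparent route available (explicit
# loops, all-pairs shortest paths, per-character tallies) and share no code
# with the implementation paths they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# position-by-position window matcher, written directly against the class
# semantics: explicit set / wildcard / hydrophobic
oracleScan <- function(seq, pattern, maxMismatches = 0L) {
  chars <- strsplit(seq, "")[[1]]
  k <- patternLength(pattern)
  hyd <- pattern@hydrophobic
  hits <- list()
  if (length(chars) < k) return(data.frame(start = integer(0),
                                           mismatches = integer(0)))
  for (s in seq_len(length(chars) - k + 1L)) {
    mm <- 0L
    for (j in seq_len(k)) {
      cl <- pattern@classes[[j]]
      ch <- chars[s + j - 1L]
      ok <- switch(cl$type,
                   any = TRUE,
                   hydrophobic = ch %in% hyd,
                   set = ch %in% cl$residues)
      if (!ok) mm <- mm + 1L
    }
    if (mm <= maxMismatches)
      hits[[length(hits) + 1L]] <- data.frame(start = s, mismatches = mm)
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(0), mismatches = integer(0))
}

oracleBestMismatches <- function(seq, pattern) {
  all <- oracleScan(seq, pattern, maxMismatches = patternLength(pattern))
  min(all$mismatches)
}

# all-pairs path-sum distances between leaves via Floyd-Warshall on the
# tree's node graph
oraclePatristic <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  D <- matrix(Inf, nnode, nnode)
  diag(D) <- 0
  for (r in seq_len(nrow(tree$edge))) {
    a <- tree$edge[r, 1]; b <- tree$edge[r, 2]
    D[a, b] <- D[b, a] <- tree$edge.length[r]
  }
  for (k in seq_len(nnode))
    for (i in seq_len(nnode)) {
      relax <- D[i, k] + D[k, ]
      better <- relax < D[i, ]
      D[i, better] <- relax[better]
    }
  out <- D[seq_len(ntip), seq_len(ntip)]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# per-character G+C tally with its own weight table
oracleGC <- function(seq) {
  w <- c(A = 0, C = 1, G = 1, T = 0, U = 0, R = 0.5, Y = 0.5, S = 1,
         W = 0, K = 0.5, M = 0.5, B = 2/3, D = 1/3, H = 1/3, V = 2/3,
         N = 0.5)
  chars <- strsplit(toupper(seq), "")[[1]]
  100 * sum(w[chars]) / length(chars)
}

randomAASeq <- function(n) paste(sample(AA20, n, replace = TRUE),
                                 collapse = "")

randomNtSeq <- function(n) paste(sample(c("A", "C", "G", "T", "R", "N",
                                          "S", "W"),
                                        n, replace = TRUE,
                                        prob = c(rep(0.22, 4),
                                                 rep(0.03, 4))),
                                 collapse = "")

# random pattern mixing explicit sets, wildcards and hydrophobic positions
randomPattern <- function(k = 6L) {
  parts <- vapply(seq_len(k), function(i) {
    kind <- sample(c("set", "single", "any", "hyd"), 1,
                   prob = c(0.4, 0.3, 0.2, 0.1))
    switch(kind,
           set = paste0("[", paste(sample(AA20, sample(2:4, 1)),
                                   collapse = ""), "]"),
           single = sample(AA20, 1),
           any = "x",
           hyd = "h")
  }, character(1))
  paste(parts, collapse = "")
}

randomSupportTree <- function(nLeaves) {
  tr <- ape::rtree(nLeaves)
  tr$node.label <- c("", sample(0:1000, tr$Nnode - 1L, replace = TRUE))
  tr
}
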