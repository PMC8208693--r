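# Tree handling for the congruence criterion: the best homology hit for a
# horizontally acquired gene should also be its nearest neighbour in the
# gene phylogeny (a best BLAST hit alone need not be the nearest
# phylogenetic neighbour). Trees are consumed as Newick via ape; the
# support-threshold collapse implements the consensus convention of
# showing only nodes at or above the declared bootstrap fraction.

normalizeLabel <- function(x) trimws(x)

# attach the declared support scale: per-mille when any value exceeds 100
# (e.g. of-1000 bootstrap scores), percent when any exceeds 1, else fraction
declareSupportScale <- function(tree) {
  sup <- suppressWarnings(as.numeric(tree$node.label))
  scale <- if (!length(sup) || all(is.na(sup))) NA_character_
  else if (max(sup, na.rm = TRUE) > 100) "permille"
  else if (max(sup, na.rm = TRUE) > 1) "percent"
  else "fraction"
  attr(tree, "supportScale") <- scale
  tree
}

finishTree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treating every edge as length 1")
    tree$edge.length <- rep(1, nrow(tree$edge))
    attr(tree, "lengthsMissing") <- TRUE
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length(s)")
  declareSupportScale(tree)
}

checkNewickSyntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("unbalanced ')' at position %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("unbalanced '(': %d unclosed at end of input", depth))
  invisible(TRUE)
}

#' Parse a Newick string into a phylo tree
#'
#' Branch lengths and internal-node support labels are optional; a tree
#' without branch lengths gets unit lengths with a warning. The support
#' scale is auto-declared from the label range (values above 100 imply a
#' per-mille scale such as of-1000 bootstrap scores) and stored as
#' \code{attr(tree, "supportScale")}.
#'
#' @param text a Newick string.
#' @return an \code{ape::phylo}. Unbalanced parentheses or duplicate leaf
#'   labels raise an error with the offending position or labels.
#' @export
parseNewick <- function(text) {
  checkNewickSyntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse Newick input")
  finishTree(tree)
}

#' Read a Newick tree file
#'
#' @param file path to a Newick file (first tree is used).
#' @return see [parseNewick()].
#' @export
readNewick <- function(file) {
  parseNewick(paste(readLines(file), collapse = ""))
}

#' Serialize a phylo tree to Newick
#'
#' @param tree an \code{ape::phylo}.
#' @param file optional output path; when \code{NULL} the Newick string is
#'   returned.
#' @return the Newick string (invisibly when writing to a file).
#' @export
writeNewick <- function(tree, file = NULL) {
  if (is.null(file))
    return(ape::write.tree(tree))
  cat(ape::write.tree(tree), "\n", sep = "", file = file)
  invisible(ape::write.tree(tree))
}

#' Patristic distance matrix over the leaves of a tree
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @return symmetric matrix of path-length sums between all leaf pairs.
#' @export
patristicMatrix <- function(tree) {
  ape::cophenetic.phylo(tree)
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths along the unique path connecting the two leaves.
#'
#' @param tree an \code{ape::phylo}.
#' @param leafA,leafB leaf labels.
#' @return non-negative numeric. Unknown labels raise an error.
#' @examples
#' tr <- parseNewick("((A:1,B:2):3,C:4);")
#' patristicDistance(tr, "A", "C")  # 8
#' @export
patristicDistance <- function(tree, leafA, leafB) {
  labs <- tree$tip.label
  missing <- setdiff(c(leafA, leafB), labs)
  if (length(missing))
    stop("unknown leaf label(s): ", paste(missing, collapse = ", "))
  if (leafA == leafB) return(0)
  D <- patristicMatrix(tree)
  unname(D[leafA, leafB])
}

isBadNode <- function(node, supports, ntip, root, threshold) {
  node > ntip && node != root &&
    !is.na(supports[node - ntip]) && supports[node - ntip] < threshold
}

#' Collapse weakly supported internal nodes into polytomies
#'
#' Every internal (non-root) edge whose child node carries a support value
#' below \code{threshold} is contracted: the child's children re-attach to
#' its parent. By default the contracted edge's length is discarded (the
#' consensus-tree convention operates on topology only), which biases
#' post-collapse leaf distances; set \code{redistribute = TRUE} to add the
#' contracted length to each re-attached child edge instead. Leaves are
#' never removed.
#'
#' @param tree an \code{ape::phylo} with support values as node labels.
#' @param threshold support threshold on the tree's declared scale (e.g.
#'   700 on a per-mille scale). A threshold outside the declared scale's
#'   range raises an error.
#' @param redistribute add each contracted edge's length to its child
#'   edges (default \code{FALSE}, with a warning when edges are
#'   contracted).
#' @return the collapsed \code{ape::phylo}.
#' @export
collapseLowSupport <- function(tree, threshold, redistribute = FALSE) {
  scale <- attr(tree, "supportScale")
  if (is.null(scale)) {
    tree <- declareSupportScale(tree)
    scale <- attr(tree, "supportScale")
  }
  if (is.na(scale))
    stop("tree has no numeric support values")
  top <- switch(scale, permille = 1000, percent = 100, fraction = 1)
  if (threshold < 0 || threshold > top)
    stop(sprintf("threshold %g outside the declared %s scale [0, %g]",
                 threshold, scale, top))
  supports <- suppressWarnings(as.numeric(tree$node.label))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  edges <- tree$edge
  lens <- tree$edge.length
  labelOf <- function(node) {
    l <- tree$node.label[node - ntip]
    if (is.null(l) || is.na(l)) "" else l
  }
  contracted <- FALSE
  partsOf <- function(node, extra) {
    rows <- which(edges[, 1] == node)
    unlist(lapply(rows, function(r) {
      child <- edges[r, 2]
      l <- lens[r] + extra
      if (isBadNode(child, supports, ntip, root, threshold)) {
        contracted <<- TRUE
        partsOf(child, if (redistribute) l else 0)
      } else {
        paste0(serialize(child), ":", format(l, digits = 15))
      }
    }))
  }
  serialize <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    paste0("(", paste(partsOf(node, 0), collapse = ","), ")", labelOf(node))
  }
  newick <- paste0(serialize(root), ";")
  if (contracted && !redistribute)
    warning("contracted edge lengths discarded; post-collapse patristic distances are topology-biased")
  out <- ape::read.tree(text = newick)
  attr(out, "supportScale") <- scale
  out
}

# all leaf labels descending from a node
descendantTips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  out <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    out <- c(out, tree$tip.label[kids[kids <= ntip]])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

#' Is the best homology hit also the nearest tree neighbour?
#'
#' Finds the leaf with minimal patristic distance to the query (over an
#' optional candidate set, e.g. to exclude the query's own paralogues) and
#' compares it with the best homology-search subject. Exact distance ties
#' are flagged and broken lexicographically. The leaves of the query's
#' sister clade are also reported, so "closest neighbour" can be read
#' either as patristic proximity or as sisterhood.
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @param queryLeaf leaf label of the query gene.
#' @param blastBestSubject leaf label of the best homology hit.
#' @param candidates optional leaf labels allowed as nearest neighbour.
#' @return a [CongruenceResult-class]. An empty candidate set after
#'   exclusions raises an error.
#' @export
congruenceCheck <- function(tree, queryLeaf, blastBestSubject,
                            candidates = NULL) {
  labs <- tree$tip.label
  queryLeaf <- normalizeLabel(queryLeaf)
  blastBestSubject <- normalizeLabel(blastBestSubject)
  if (!queryLeaf %in% labs)
    stop("query leaf '", queryLeaf, "' not in tree")
  cands <- if (is.null(candidates)) labs else
    intersect(normalizeLabel(candidates), labs)
  cands <- setdiff(cands, queryLeaf)
  if (length(cands) == 0L)
    stop("candidate set is empty after exclusions")
  D <- patristicMatrix(tree)
  d <- D[queryLeaf, cands]
  m <- min(d)
  tiedSet <- sort(names(d)[d == m])
  nearest <- tiedSet[1]
  # sister clade: leaves under the other children of the query's parent
  ntip <- length(labs)
  tipNo <- match(queryLeaf, labs)
  parent <- tree$edge[tree$edge[, 2] == tipNo, 1]
  sibs <- setdiff(tree$edge[tree$edge[, 1] == parent, 2], tipNo)
  sisterLeaves <- sort(unique(unlist(lapply(sibs, descendantTips,
                                            tree = tree))))
  new("CongruenceResult", queryLeaf = queryLeaf, nearestLeaf = nearest,
      nearestDistance = unname(m), blastBestSubject = blastBestSubject,
      congruent = identical(nearest, blastBestSubject),
      tied = length(tiedSet) > 1L, sisterLeaves = sisterLeaves)
}
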