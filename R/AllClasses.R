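# Central S4 classes and their accessor generics. Result objects are
# deliberately small value classes; bulk data travel in the standard
# Bioconductor containers (XStringSet, GRanges, DataFrame/data.frame,
# ape's phylo).

#' @name hgtEvidence-generics
#' @title Accessor generics
#' @description Small accessor generics shared by the result classes.
#' @param x an object.
#' @return The slot value; see the class documentation.
NULL

#' @rdname hgtEvidence-generics
#' @export
setGeneric("ai", function(x) standardGeneric("ai"))

#' @rdname hgtEvidence-generics
#' @export
setGeneric("category", function(x) standardGeneric("category"))

#' @rdname hgtEvidence-generics
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname hgtEvidence-generics
#' @export
setGeneric("isCongruent", function(x) standardGeneric("isCongruent"))

#' @rdname hgtEvidence-generics
#' @export
setGeneric("patternLength", function(x) standardGeneric("patternLength"))

#' @rdname hgtEvidence-generics
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' ConsensusPattern: a parsed degenerate protein motif
#'
#' One residue class per motif position, parsed from a PROSITE-like string
#' such as \code{"[LIV][LIV]G[RK][RK]Fx-[LIV]h[HQL][LIV]"}. Bracketed groups
#' are explicit residue sets, bare letters are singleton sets, \code{x} is a
#' wildcard, \code{h} matches the configured hydrophobic set, and hyphens are
#' cosmetic separators.
#'
#' @slot classes list with one element per position; each element is a list
#'   with fields \code{type} (\code{"set"}, \code{"any"} or
#'   \code{"hydrophobic"}) and \code{residues} (character vector, for
#'   \code{"set"}).
#' @slot sourceText the original pattern string.
#' @slot hydrophobic residues matched by the \code{h} class.
#' @seealso [parsePattern()], [scanMotif()]
#' @export
setClass("ConsensusPattern",
  representation(classes = "list", sourceText = "character",
                 hydrophobic = "character"))

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

setValidity("ConsensusPattern", function(object) {
  msgs <- character()
  if (length(object@classes) < 1L)
    msgs <- c(msgs, "pattern must have at least one position")
  for (i in seq_along(object@classes)) {
    cl <- object@classes[[i]]
    if (!is.list(cl) || !cl$type %in% c("set", "any", "hydrophobic"))
      msgs <- c(msgs, sprintf("position %d has an invalid class type", i))
    else if (cl$type == "set" &&
             (length(cl$residues) == 0L ||
              !all(cl$residues %in% AA_STANDARD)))
      msgs <- c(msgs, sprintf(
        "position %d: explicit set must be a non-empty subset of the 20 standard residues", i))
  }
  if (!all(object@hydrophobic %in% AA_STANDARD))
    msgs <- c(msgs, "hydrophobic set must use standard residues")
  if (length(msgs)) msgs else TRUE
})

#' @rdname hgtEvidence-generics
#' @export
setMethod("patternLength", "ConsensusPattern",
          function(x) length(x@classes))

setMethod("show", "ConsensusPattern", function(object) {
  cat("ConsensusPattern of length", length(object@classes), "\n")
  cat("  source:", object@sourceText, "\n")
  cat("  hydrophobic set:", paste(object@hydrophobic, collapse = ""), "\n")
})

#' AlienIndexResult: alien index value and HGT category for one query
#'
#' @slot ai alien index in natural-log units, full precision.
#' @slot aiRounded \code{ai} rounded to the nearest integer (the reporting
#'   convention for tables).
#' @slot donorEvalue,recipientEvalue the E values actually used, after
#'   substituting 1 for a missing hit.
#' @slot donorIdentity percent identity of the best donor hit (NA if absent).
#' @slot epsilon the pseudocount added to both E values (default 1e-200).
#' @slot category one of \code{"very_likely_hgt"}, \code{"possible_hgt"},
#'   \code{"likely_contamination"}, \code{"no_hgt_signal"}.
#' @seealso [alienIndex()], [classifyAlienIndex()], [evaluateAlienIndex()]
#' @export
setClass("AlienIndexResult",
  representation(ai = "numeric", aiRounded = "numeric",
                 donorEvalue = "numeric", recipientEvalue = "numeric",
                 donorIdentity = "numeric", epsilon = "numeric",
                 category = "character"))

AI_CATEGORIES <- c("very_likely_hgt", "possible_hgt",
                   "likely_contamination", "no_hgt_signal")

setValidity("AlienIndexResult", function(object) {
  if (!object@category %in% AI_CATEGORIES)
    return("unknown category")
  if (object@donorEvalue < 0 || object@recipientEvalue < 0)
    return("E values must be non-negative")
  TRUE
})

#' @rdname hgtEvidence-generics
#' @export
setMethod("ai", "AlienIndexResult", function(x) x@ai)

#' @rdname hgtEvidence-generics
#' @export
setMethod("category", "AlienIndexResult", function(x) x@category)

setMethod("show", "AlienIndexResult", function(object) {
  cat(sprintf("AlienIndexResult: AI = %.2f (rounded %d), category = %s\n",
              object@ai, as.integer(object@aiRounded), object@category))
  cat(sprintf("  donor E = %g, recipient E = %g, donor identity = %s%%\n",
              object@donorEvalue, object@recipientEvalue,
              ifelse(is.na(object@donorIdentity), "NA",
                     format(object@donorIdentity))))
})

#' GCAffinity: does a gene's G+C composition side with donor or host?
#'
#' @slot geneGC,hostGenomeGC,donorGeneGC mol\% G+C values compared.
#' @slot deltaHost,deltaDonor absolute differences |gene - host| and
#'   |gene - donor|.
#' @slot verdict \code{"donor_consistent"} iff deltaDonor < deltaHost,
#'   \code{"host_consistent"} iff deltaHost < deltaDonor, else \code{"tie"}.
#' @seealso [gcAffinity()]
#' @export
setClass("GCAffinity",
  representation(geneGC = "numeric", hostGenomeGC = "numeric",
                 donorGeneGC = "numeric", deltaHost = "numeric",
                 deltaDonor = "numeric", verdict = "character"))

setValidity("GCAffinity", function(object) {
  if (!object@verdict %in% c("donor_consistent", "host_consistent", "tie"))
    return("unknown verdict")
  TRUE
})

#' @rdname hgtEvidence-generics
#' @export
setMethod("verdict", "GCAffinity", function(x) x@verdict)

setMethod("show", "GCAffinity", function(object) {
  cat(sprintf(
    "GCAffinity: gene %.1f vs host %.1f (d=%.1f) / donor %.1f (d=%.1f) -> %s\n",
    object@geneGC, object@hostGenomeGC, object@deltaHost,
    object@donorGeneGC, object@deltaDonor, object@verdict))
})

#' CongruenceResult: nearest tree neighbour vs best homology hit
#'
#' @slot queryLeaf leaf label of the query gene.
#' @slot nearestLeaf leaf with minimal patristic distance to the query
#'   (ties broken lexicographically).
#' @slot nearestDistance that patristic distance.
#' @slot blastBestSubject leaf label of the best homology hit.
#' @slot congruent TRUE iff nearestLeaf equals blastBestSubject.
#' @slot tied TRUE when several candidates attained the minimal distance.
#' @slot sisterLeaves leaves of the query's sister clade, so sisterhood can
#'   be checked as an alternative reading of "closest neighbour".
#' @seealso [congruenceCheck()]
#' @export
setClass("CongruenceResult",
  representation(queryLeaf = "character", nearestLeaf = "character",
                 nearestDistance = "numeric", blastBestSubject = "character",
                 congruent = "logical", tied = "logical",
                 sisterLeaves = "character"))

#' @rdname hgtEvidence-generics
#' @export
setMethod("isCongruent", "CongruenceResult", function(x) x@congruent)

setMethod("show", "CongruenceResult", function(object) {
  cat(sprintf(
    "CongruenceResult: query %s, nearest %s (d=%.4g)%s, blast best %s -> %s\n",
    object@queryLeaf, object@nearestLeaf, object@nearestDistance,
    if (object@tied) " [tie]" else "", object@blastBestSubject,
    if (object@congruent) "congruent" else "incongruent"))
})

#' TransferScenario: parameters of one synthetic HGT scenario
#'
#' The parameter bundle that fully determines a synthetic dataset (the seed
#' included). Defaults emulate the compositional regime of a strongly
#' AT-biased recipient acquiring a gene from a GC-rich donor.
#'
#' @slot seed integer RNG seed; all outputs are pure functions of the slots.
#' @slot recipientGC,donorGC mol\% G+C targets for the two genomes.
#' @slot genomeLength,geneLength lengths in bp; geneLength is a multiple of
#'   3 and at most genomeLength/10.
#' @slot transfer truth label: was the focal gene horizontally acquired?
#' @slot motifEmbedded embed one perfect consensus-motif instantiation in
#'   the focal protein.
#' @slot evalueModel parameters (K, lambda, m, n, s0, s1) of the
#'   Karlin-Altschul-shaped identity-to-E-value map.
#' @slot treeLeaves total leaf count of the simulated gene tree (>= 4).
#' @slot mgeWithin,mgeOutside mobile elements placed inside / outside the
#'   5 kb flanks of the focal gene.
#' @slot donorIdentityRange,recipientIdentityRange percent-identity ranges
#'   from which the donor-orthologue and recipient-paralogue hits are drawn.
#' @seealso [transferScenario()], [simulateTransfer()]
#' @export
setClass("TransferScenario",
  representation(seed = "integer", recipientGC = "numeric",
                 donorGC = "numeric", genomeLength = "integer",
                 geneLength = "integer", transfer = "logical",
                 motifEmbedded = "logical", evalueModel = "list",
                 treeLeaves = "integer", mgeWithin = "integer",
                 mgeOutside = "integer", donorIdentityRange = "numeric",
                 recipientIdentityRange = "numeric"))

setValidity("TransferScenario", function(object) {
  msgs <- character()
  if (object@recipientGC < 0 || object@recipientGC > 100 ||
      object@donorGC < 0 || object@donorGC > 100)
    msgs <- c(msgs, "GC targets must lie in [0, 100]")
  if (object@geneLength %% 3L != 0L)
    msgs <- c(msgs, "geneLength must be a multiple of 3")
  if (object@geneLength > object@genomeLength / 10)
    msgs <- c(msgs, "geneLength must be at most genomeLength/10")
  if (object@treeLeaves < 4L)
    msgs <- c(msgs, "treeLeaves must be at least 4")
  needed <- c("K", "lambda", "m", "n", "s0", "s1")
  if (!all(needed %in% names(object@evalueModel)))
    msgs <- c(msgs, paste("evalueModel must name", paste(needed, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TransferScenario", function(object) {
  cat(sprintf(
    "TransferScenario(seed=%d): %s, recipient GC %.1f%%, donor GC %.1f%%\n",
    object@seed, if (object@transfer) "transfer" else "no transfer",
    object@recipientGC, object@donorGC))
  cat(sprintf("  genome %d bp, gene %d bp, %d tree leaves, MGEs %d in/%d out\n",
              object@genomeLength, object@geneLength, object@treeLeaves,
              object@mgeWithin, object@mgeOutside))
})

#' SyntheticDataset: one fully simulated HGT scenario with truth labels
#'
#' @slot genomes recipient and donor genomes (\code{DNAStringSet}).
#' @slot features focal gene, donor gene and MGE annotations
#'   (\code{GRanges}).
#' @slot proteins translated focal, donor and recipient proteins
#'   (\code{AAStringSet}).
#' @slot homology simulated tabular homology hits (12-column outfmt-6
#'   layout plus \code{qcovs} and \code{subject_group}).
#' @slot tree simulated gene tree (\code{ape::phylo}).
#' @slot truth list of expected verdicts (transfer flag, donor leaf,
#'   expected AI sign, GC verdict, congruence).
#' @slot scenario the generating [TransferScenario-class].
#' @seealso [simulateTransfer()], [writeSyntheticDataset()]
#' @export
setClass("SyntheticDataset",
  representation(genomes = "DNAStringSet", features = "GRanges",
                 proteins = "AAStringSet", homology = "data.frame",
                 tree = "ANY", truth = "list", scenario = "TransferScenario"))

setValidity("SyntheticDataset", function(object) {
  msgs <- character()
  gn <- names(object@genomes)
  if (!all(as.character(GenomicRanges::seqnames(object@features)) %in% gn))
    msgs <- c(msgs, "every feature seq_id must name a genome")
  if (!all(object@homology$qseqid %in% names(object@proteins)))
    msgs <- c(msgs, "every homology query must name a protein")
  if (length(msgs)) msgs else TRUE
})

#' @rdname hgtEvidence-generics
#' @export
setMethod("truthLabels", "SyntheticDataset", function(x) x@truth)

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:", length(object@genomes), "genomes,",
      length(object@features), "features,",
      nrow(object@homology), "homology hits,",
      length(object@tree$tip.label), "tree leaves\n")
  cat("  truth: transfer =", object@truth$transfer, "\n")
})
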