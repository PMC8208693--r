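# Orchestration: run the five evidence stages over a run configuration,
# aggregate one verdict per focal gene, and emit a TSV report with a JSON
# mirror. The aggregation rule is explicit and configurable: a gene is
# hgt_supported when the alien index category is very_likely_hgt AND the
# G+C verdict is donor_consistent OR the tree is congruent; no_support
# when the alien index shows no signal; ambiguous otherwise.

DEFAULT_THRESHOLDS <- list(ai_very_likely = 30, ai_possible = 0,
                           identity_rule = FALSE, collapse_support = 700,
                           flank = 5000)

emptyEvidenceRow <- function() {
  data.frame(gene_id = character(0), query = character(0),
             motif_start = integer(0), motif_window = character(0),
             motif_mismatches = integer(0), donor_best = character(0),
             donor_evalue = numeric(0), donor_identity = numeric(0),
             recipient_best = character(0), recipient_evalue = numeric(0),
             ai = numeric(0), ai_rounded = numeric(0),
             ai_category = character(0), gene_gc = numeric(0),
             host_genome_gc = numeric(0), donor_gene_gc = numeric(0),
             gc_verdict = character(0), nearest_leaf = character(0),
             congruent = logical(0), mge_within = integer(0),
             verdict = character(0), stringsAsFactors = FALSE)
}

aggregateVerdict <- function(category, gcVerdict, congruent) {
  if (identical(category, "no_hgt_signal")) return("no_support")
  gcOK <- identical(gcVerdict, "donor_consistent")
  trOK <- isTRUE(congruent)
  if (identical(category, "very_likely_hgt") && (gcOK || trOK))
    return("hgt_supported")
  "ambiguous"
}

categoryWithThresholds <- function(aiv, donorIdentity, thresholds) {
  veryLikely <- thresholds$ai_very_likely
  possible <- thresholds$ai_possible
  if (isTRUE(thresholds$identity_rule)) {
    if (aiv > possible && !is.na(donorIdentity) && donorIdentity >= 70)
      return("likely_contamination")
    if (aiv > veryLikely) return("very_likely_hgt")
    if (aiv > possible) return("possible_hgt")
    return("no_hgt_signal")
  }
  if (aiv > veryLikely) return("very_likely_hgt")
  if (aiv > possible) return("possible_hgt")
  "no_hgt_signal"
}

#' Run the evidence stages over in-memory inputs
#'
#' The computational core of [runPipeline()]: one evidence row per query
#' in the homology table. Optional stages are skipped when their input is
#' \code{NULL} and the corresponding fields are reported as \code{NA}.
#'
#' @param proteins \code{AAStringSet} of query proteins (motif stage).
#' @param homology homology hit data.frame with a \code{subject_group}
#'   column (or supply \code{donorTaxa}/\code{recipientTaxa}).
#' @param donorTaxa,recipientTaxa subject ids defining the two lineage
#'   groups when \code{subject_group} is absent.
#' @param features \code{GRanges} of gene features; a feature whose
#'   \code{protein_id} equals the query identifies the focal gene, one
#'   whose \code{protein_id} equals the best donor subject identifies the
#'   donor gene (G+C stage).
#' @param genomes \code{DNAStringSet} of genome sequences.
#' @param hostGenome,donorGenome names of the host and donor genome
#'   sequences in \code{genomes}.
#' @param tree \code{ape::phylo} gene tree, or \code{NULL} to skip the
#'   congruence stage.
#' @param mgeHits \code{GRanges} of mobile-element hits, or \code{NULL};
#'   by default mobile elements are taken from \code{features} (type
#'   \code{"mobile_element"}).
#' @param pattern motif pattern string or [ConsensusPattern-class].
#' @param thresholds list as in \code{DEFAULT_THRESHOLDS}.
#' @return data.frame with one row per query (see [writeReport()]).
#' @export
runEvidence <- function(proteins, homology, donorTaxa = NULL,
                        recipientTaxa = NULL, features = NULL,
                        genomes = NULL, hostGenome = NULL,
                        donorGenome = NULL, tree = NULL, mgeHits = NULL,
                        pattern = PAP_SIGNATURE_CONSENSUS,
                        thresholds = DEFAULT_THRESHOLDS) {
  thresholds <- utils::modifyList(DEFAULT_THRESHOLDS, thresholds)
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  queries <- unique(homology$qseqid)
  if (length(queries) == 0L) return(emptyEvidenceRow())
  if (is.null(mgeHits) && !is.null(features)) {
    sel <- !is.na(mcols(features)$type) &
      mcols(features)$type == "mobile_element"
    if (any(sel)) mgeHits <- features[sel]
  }
  collapsedTree <- tree
  if (!is.null(tree) && !is.na(attr(declareSupportScale(tree),
                                    "supportScale")))
    collapsedTree <- suppressWarnings(
      collapseLowSupport(tree, thresholds$collapse_support))
  rows <- lapply(queries, function(q)
    evidenceRowFor(q, proteins, homology, donorTaxa, recipientTaxa,
                   features, genomes, hostGenome, donorGenome,
                   collapsedTree, mgeHits, pattern, thresholds))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

evidenceRowFor <- function(q, proteins, homology, donorTaxa, recipientTaxa,
                           features, genomes, hostGenome, donorGenome,
                           tree, mgeHits, pattern, thresholds) {
  hits <- homology[homology$qseqid == q, , drop = FALSE]

  # motif stage
  motif <- list(start = NA_integer_, window = NA_character_,
                mismatches = NA_integer_)
  if (!is.null(proteins) && q %in% names(proteins)) {
    bw <- bestWindow(as.character(proteins[[q]]), pattern, sequenceId = q)
    motif <- list(start = bw$start, window = bw$window,
                  mismatches = bw$mismatches)
  }

  # alien index stage
  best <- bestHits(hits, donorTaxa, recipientTaxa, excludeSubjects = q)
  dE <- if (is.null(best$donor)) 1 else best$donor$evalue
  rE <- if (is.null(best$recipient)) 1 else best$recipient$evalue
  dId <- if (is.null(best$donor)) NA_real_ else best$donor$pident
  aiv <- alienIndex(rE, dE)
  cat <- categoryWithThresholds(aiv, dId, thresholds)

  # G+C stage
  geneGC <- hostGC <- donorGC <- NA_real_
  gcVerdict <- NA_character_
  if (!is.null(features) && !is.null(genomes)) {
    pid <- mcols(features)$protein_id
    focal <- features[!is.na(pid) & pid == q]
    donorFeat <- if (!is.null(best$donor))
      features[!is.na(pid) & pid == best$donor$sseqid] else features[0]
    if (length(focal) == 1L) {
      sq <- as.character(seqnames(focal))
      if (sq %in% names(genomes)) {
        geneGC <- gcContent(Biostrings::subseq(
          genomes[[sq]], start(focal), end(focal)))$molPercent
        host <- if (!is.null(hostGenome)) hostGenome else sq
        if (host %in% names(genomes))
          hostGC <- gcContent(genomes[[host]])$molPercent
      }
    }
    if (length(donorFeat) == 1L) {
      sq <- as.character(seqnames(donorFeat))
      if (sq %in% names(genomes))
        donorGC <- gcContent(Biostrings::subseq(
          genomes[[sq]], start(donorFeat), end(donorFeat)))$molPercent
    }
    if (!is.na(geneGC) && !is.na(hostGC) && !is.na(donorGC))
      gcVerdict <- verdict(gcAffinity(geneGC, hostGC, donorGC))
  }

  # congruence stage
  nearest <- NA_character_
  congruent <- NA
  if (!is.null(tree) && q %in% tree$tip.label && !is.null(best$donor) &&
      best$donor$sseqid %in% tree$tip.label) {
    cg <- congruenceCheck(tree, q, best$donor$sseqid)
    nearest <- cg@nearestLeaf
    congruent <- cg@congruent
  }

  # MGE stage
  mgeWithin <- NA_integer_
  if (!is.null(mgeHits) && !is.null(features)) {
    pid <- mcols(features)$protein_id
    focal <- features[!is.na(pid) & pid == q]
    if (length(focal) == 1L) {
      onSeq <- mgeHits[as.character(seqnames(mgeHits)) ==
                         as.character(seqnames(focal))]
      pr <- proximityReport(focal, onSeq, flank = thresholds$flank,
                            genomeGC = if (is.na(hostGC)) NULL else hostGC)
      mgeWithin <- nrow(pr)
    }
  }

  data.frame(
    gene_id = q, query = q,
    motif_start = motif$start, motif_window = motif$window,
    motif_mismatches = motif$mismatches,
    donor_best = if (is.null(best$donor)) NA_character_ else
      best$donor$sseqid,
    donor_evalue = dE, donor_identity = dId,
    recipient_best = if (is.null(best$recipient)) NA_character_ else
      best$recipient$sseqid,
    recipient_evalue = rE,
    ai = aiv, ai_rounded = round(aiv), ai_category = cat,
    gene_gc = geneGC, host_genome_gc = hostGC, donor_gene_gc = donorGC,
    gc_verdict = gcVerdict, nearest_leaf = nearest, congruent = congruent,
    mge_within = mgeWithin,
    verdict = aggregateVerdict(cat, gcVerdict, congruent),
    stringsAsFactors = FALSE)
}

#' Run the evidence stages on a synthetic dataset in memory
#'
#' @param dataset a [SyntheticDataset-class].
#' @param thresholds see [runEvidence()].
#' @return the evidence row data.frame.
#' @export
evaluateDataset <- function(dataset, thresholds = DEFAULT_THRESHOLDS) {
  stopifnot(is(dataset, "SyntheticDataset"))
  runEvidence(proteins = dataset@proteins, homology = dataset@homology,
              features = dataset@features, genomes = dataset@genomes,
              hostGenome = "recipient_genome",
              donorGenome = "donor_genome", tree = dataset@tree,
              thresholds = thresholds)
}

resolvePath <- function(path, baseDir) {
  if (is.null(path)) return(NULL)
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(baseDir, path)
}

#' Run the full pipeline from a configuration file
#'
#' The configuration (YAML, or an equivalent list) has sections
#' \code{inputs} (paths, resolved relative to the config file),
#' \code{thresholds}, \code{stages} (logical flags \code{motif},
#' \code{gc}, \code{tree}, \code{mge}) and \code{pattern}. Missing
#' optional stages are skipped and reported as \code{NA}; a missing
#' referenced file raises an error before any stage runs. The report
#' (\code{report.tsv} + \code{report.json}) is deterministic for fixed
#' inputs.
#'
#' @param config path to a YAML config, or a list with the same
#'   structure (then paths must be absolute or relative to \code{dir}).
#' @param outDir output directory for the report files.
#' @param dir base directory for relative paths when \code{config} is a
#'   list (default the working directory).
#' @return the evidence row data.frame, invisibly; report files are
#'   written to \code{outDir}.
#' @export
runPipeline <- function(config, outDir, dir = ".") {
  if (is.character(config)) {
    dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  inputs <- config$inputs
  stages <- utils::modifyList(list(motif = TRUE, gc = TRUE, tree = TRUE,
                                   mge = TRUE), as.list(config$stages))
  thresholds <- utils::modifyList(DEFAULT_THRESHOLDS,
                                  as.list(config$thresholds))
  pattern <- if (is.null(config$pattern)) PAP_SIGNATURE_CONSENSUS else
    config$pattern

  required <- c("homology", "donor_taxa", "recipient_taxa")
  optional <- c("proteins", "features", "genomes", "tree", "mge_hits")
  paths <- lapply(inputs[c(required, optional)], resolvePath, baseDir = dir)
  names(paths) <- c(required, optional)
  for (nm in required)
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]]))
      stop("required input '", nm, "' is missing or does not exist")
  for (nm in optional)
    if (!is.null(inputs[[nm]]) && !file.exists(paths[[nm]]))
      stop("referenced input file does not exist: ", paths[[nm]])

  homology <- readBlast6(paths$homology)
  donorTaxa <- readLines(paths$donor_taxa)
  recipientTaxa <- readLines(paths$recipient_taxa)
  proteins <- if (isTRUE(stages$motif) && !is.null(paths$proteins))
    readFasta(paths$proteins, "aa") else NULL
  features <- if (!is.null(paths$features)) readGff3(paths$features) else NULL
  genomes <- if (isTRUE(stages$gc) && !is.null(paths$genomes))
    readFasta(paths$genomes, "nt") else NULL
  tree <- if (isTRUE(stages$tree) && !is.null(paths$tree))
    readNewick(paths$tree) else NULL
  mgeHits <- if (isTRUE(stages$mge) && !is.null(paths$mge_hits))
    readMgeHits(paths$mge_hits) else NULL
  if (!isTRUE(stages$mge)) {
    # drop mobile elements carried inside the feature file as well
    if (!is.null(features))
      features <- features[is.na(mcols(features)$type) |
                             mcols(features)$type != "mobile_element"]
  }
  if (!is.null(genomes) && length(names(genomes)))
    names(genomes) <- sub("\\s.*", "", names(genomes))
  if (!is.null(proteins) && length(names(proteins)))
    names(proteins) <- sub("\\s.*", "", names(proteins))

  badSubjects <- setdiff(c(donorTaxa, recipientTaxa), homology$sseqid)
  rows <- runEvidence(proteins = proteins, homology = homology,
                      donorTaxa = donorTaxa, recipientTaxa = recipientTaxa,
                      features = features, genomes = genomes,
                      hostGenome = inputs$host_genome,
                      donorGenome = inputs$donor_genome,
                      tree = tree, mgeHits = mgeHits, pattern = pattern,
                      thresholds = thresholds)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeReport(rows, file.path(outDir, "report"))
  invisible(rows)
}

#' Summarise a run: counts per verdict and category, MGE-positive genes
#'
#' @param rows evidence rows from [runEvidence()] / [runPipeline()].
#' @return list with \code{n}, \code{verdicts} (named counts over the
#'   three verdict classes), \code{categories} (over the four alien-index
#'   categories) and \code{mgePositive} (genes with at least one mobile
#'   element within the flank).
#' @export
summarizeEvidence <- function(rows) {
  verdicts <- c(hgt_supported = 0L, ambiguous = 0L, no_support = 0L)
  categories <- setNames(integer(length(AI_CATEGORIES)), AI_CATEGORIES)
  if (nrow(rows)) {
    tv <- table(rows$verdict)
    verdicts[names(tv)] <- as.integer(tv)
    tc <- table(rows$ai_category)
    categories[names(tc)] <- as.integer(tc)
  }
  list(n = nrow(rows), verdicts = verdicts, categories = categories,
       mgePositive = sum(rows$mge_within >= 1L, na.rm = TRUE))
}
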