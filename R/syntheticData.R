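# Deterministic synthetic HGT scenarios: recipient and donor genomes with
# distinct G+C content, a focal gene whose composition matches the donor
# (when a transfer happened), a homology table in which the donor
# orthologue vastly outscores the best recipient-lineage hit, a gene tree
# whose nearest leaf to the query is the donor, and mobile elements placed
# inside and outside the 5 kb flanks. Every output is a pure function of
# the scenario, seed included.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# GC-leaning codon per residue, used when embedding a motif instantiation
MOTIF_CODONS <- c(L = "CTG", V = "GTG", G = "GGC", K = "AAG", R = "CGC",
                  F = "TTC", A = "GCC", H = "CAC", I = "ATC")
MOTIF_INSTANCE <- "LVGKRFRLAHI"

#' Construct a synthetic transfer scenario
#'
#' Defaults emulate an AT-rich recipient (33 mol\% G+C) acquiring a
#' 1200 bp gene from a GC-rich donor (71 mol\%), with the donor orthologue
#' 80-100\% identical to the query and the best recipient-lineage hit a
#' distant paralogue at 29-38\% identity.
#'
#' @param seed integer RNG seed.
#' @param recipientGC,donorGC genome G+C targets (mol\%).
#' @param genomeLength,geneLength lengths in bp; \code{geneLength} must be
#'   a multiple of 3 and at most \code{genomeLength/10}.
#' @param transfer truth label: simulate a horizontal acquisition?
#' @param motifEmbedded embed one perfect signature-motif instantiation in
#'   the focal protein.
#' @param evalueModel list(K, lambda, m, n, s0, s1) for the identity-to-E
#'   map, see [modelEvalue()].
#' @param treeLeaves total gene-tree leaves (>= 4).
#' @param mgeWithin,mgeOutside elements placed inside/outside the 5 kb
#'   flanks.
#' @param donorIdentityRange,recipientIdentityRange percent-identity
#'   ranges for the simulated hits.
#' @return a [TransferScenario-class].
#' @export
transferScenario <- function(seed = 1L, recipientGC = 33, donorGC = 71,
                             genomeLength = 100000L, geneLength = 1200L,
                             transfer = TRUE, motifEmbedded = TRUE,
                             evalueModel = list(K = 0.041, lambda = 0.267,
                                                m = 450, n = 450,
                                                s0 = 0, s1 = 2),
                             treeLeaves = 10L, mgeWithin = 2L,
                             mgeOutside = 1L,
                             donorIdentityRange = c(80, 100),
                             recipientIdentityRange = c(29, 38)) {
  new("TransferScenario", seed = as.integer(seed),
      recipientGC = recipientGC, donorGC = donorGC,
      genomeLength = as.integer(genomeLength),
      geneLength = as.integer(geneLength), transfer = transfer,
      motifEmbedded = motifEmbedded, evalueModel = evalueModel,
      treeLeaves = as.integer(treeLeaves), mgeWithin = as.integer(mgeWithin),
      mgeOutside = as.integer(mgeOutside),
      donorIdentityRange = donorIdentityRange,
      recipientIdentityRange = recipientIdentityRange)
}

#' Generate a random genome at a target G+C content
#'
#' Bases are drawn independently with P(G) + P(C) = gcTarget/100 split
#' evenly (likewise A/T).
#'
#' @param length genome length in bp (>= 1).
#' @param gcTarget mol\% G+C in [0, 100].
#' @param seed integer seed; the same seed gives an identical sequence.
#' @return a \code{DNAString}.
#' @export
generateGenome <- function(length, gcTarget, seed) {
  stopifnot(length >= 1, gcTarget >= 0, gcTarget <= 100)
  set.seed(seed)
  DNAString(paste(randomBases(length, gcTarget), collapse = ""))
}

randomBases <- function(n, gcTarget) {
  g <- gcTarget / 100
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2))
}

# replace in-frame stop codons (middle base -> C) so translation is clean
removeStops <- function(bases) {
  stopifnot(length(bases) %% 3L == 0L)
  codonStarts <- seq.int(1L, length(bases), by = 3L)
  for (s in codonStarts) {
    if (paste(bases[s:(s + 2L)], collapse = "") %in% STOP_CODONS)
      bases[s + 1L] <- "C"
  }
  bases
}

# random protein-coding gene (no internal stops) at a target G+C
randomGene <- function(geneLength, gcTarget) {
  removeStops(randomBases(geneLength, gcTarget))
}

# substitute bases to reach approximately the given percent identity;
# substitutions swap within the strong (G/C) and weak (A/T) classes so the
# copy keeps the donor's G+C composition, then stops are cleaned again
mutateToIdentity <- function(bases, identity) {
  nmut <- round((1 - identity / 100) * length(bases))
  if (nmut > 0L) {
    pos <- sample.int(length(bases), nmut)
    swap <- c(A = "T", T = "A", G = "C", C = "G")
    bases[pos] <- swap[bases[pos]]
  }
  removeStops(bases)
}

#' Map percent identity to a simulated E value
#'
#' A Karlin-Altschul-shaped map \code{E = K * m * n * exp(-lambda * S)}
#' with score \code{S = s0 + s1 * identity * geneLength / 100}. Only
#' monotonicity and range coverage matter: the alien index consumes E
#' values, not alignments. Under the defaults and a 1200 bp gene,
#' identity 100 gives E around 5e-275 (the "donor E value is 0" regime)
#' and identity 30 around 1.5e-80 (a clearly resolvable recipient
#' paralogue).
#'
#' @param identity percent identity in [0, 100].
#' @param geneLength gene length in bp.
#' @param model list with elements K, lambda, m, n, s0, s1.
#' @return simulated E value (may underflow to exact 0 for extreme
#'   scores, as search tools themselves report).
#' @export
modelEvalue <- function(identity, geneLength,
                        model = list(K = 0.041, lambda = 0.267,
                                     m = 450, n = 450, s0 = 0, s1 = 2)) {
  S <- model$s0 + model$s1 * identity * geneLength / 100
  model$K * model$m * model$n * exp(-model$lambda * S)
}

homologyRow <- function(query, subject, pident, evalue, alnLen, group) {
  data.frame(qseqid = query, sseqid = subject, pident = round(pident, 1),
             length = alnLen, mismatch = round((1 - pident / 100) * alnLen),
             gapopen = 0L, qstart = 1L, qend = alnLen, sstart = 1L,
             send = alnLen, evalue = evalue,
             bitscore = round(2 * alnLen * pident / 100, 1),
             qcovs = 100, subject_group = group, stringsAsFactors = FALSE)
}

#' Simulate a complete HGT scenario with truth labels
#'
#' Builds donor and recipient genomes at their G+C targets; when
#' \code{transfer} is true, inserts a donor-composition gene (replacing
#' recipient sequence, so genome length is unchanged) at a recorded locus
#' and optionally embeds one perfect consensus-motif instantiation in its
#' translation. Emits a homology table in which the donor orthologue is
#' 80-100\% identical with a correspondingly extreme E value while the
#' best recipient-lineage hit is a 29-38\% paralogue, a gene tree whose
#' nearest leaf to the query is the donor, and mobile elements inside and
#' outside the 5 kb flanks. Without a transfer the focal gene is native:
#' recipient-composition sequence, a near-identical recipient best hit and
#' a weak donor-group hit (so the alien index is strongly negative), and a
#' query leaf nested in the recipient clade.
#'
#' @param scenario a [TransferScenario-class].
#' @return a [SyntheticDataset-class].
#' @export
simulateTransfer <- function(scenario) {
  stopifnot(is(scenario, "TransferScenario"))
  validObject(scenario)
  set.seed(scenario@seed)
  L <- scenario@genomeLength
  gl <- scenario@geneLength
  model <- scenario@evalueModel

  recipientBases <- randomBases(L, scenario@recipientGC)
  donorBases <- randomBases(L, scenario@donorGC)

  donorGene <- randomGene(gl, scenario@donorGC)
  motifStartAA <- NA_integer_
  spliceMotif <- function(gene) {
    # splice a perfect 11-residue instantiation at a codon boundary
    nt <- unlist(strsplit(MOTIF_CODONS[strsplit(MOTIF_INSTANCE, "")[[1]]], ""))
    gene[(3L * (motifStartAA - 1L) + 1L):(3L * (motifStartAA - 1L) +
                                          length(nt))] <- nt
    gene
  }
  if (scenario@motifEmbedded) {
    motifStartAA <- 50L
    donorGene <- spliceMotif(donorGene)
  }
  donorLocus <- as.integer(floor(L / 2) - floor(gl / 2))
  donorBases[donorLocus:(donorLocus + gl - 1L)] <- donorGene

  recipientLocus <- as.integer(floor(L / 2) - floor(gl / 2))
  if (scenario@transfer) {
    donorIdentity <- runif(1, scenario@donorIdentityRange[1],
                           scenario@donorIdentityRange[2])
    focalGene <- mutateToIdentity(donorGene, donorIdentity)
    if (scenario@motifEmbedded)  # the signature is conserved in the copy
      focalGene <- spliceMotif(focalGene)
    recipientIdentity <- runif(1, scenario@recipientIdentityRange[1],
                               scenario@recipientIdentityRange[2])
  } else {
    focalGene <- randomGene(gl, scenario@recipientGC)
    # native gene: strong recipient-lineage hit, weak donor-group hit
    donorIdentity <- runif(1, scenario@recipientIdentityRange[1],
                           scenario@recipientIdentityRange[2])
    recipientIdentity <- runif(1, 90, 100)
  }
  recipientBases[recipientLocus:(recipientLocus + gl - 1L)] <- focalGene

  genomes <- DNAStringSet(c(
    recipient_genome = paste(recipientBases, collapse = ""),
    donor_genome = paste(donorBases, collapse = "")))

  focalDNA <- DNAString(paste(focalGene, collapse = ""))
  donorDNA <- DNAString(paste(donorGene, collapse = ""))
  recipientParalog <- DNAString(paste(randomGene(gl, scenario@recipientGC),
                                      collapse = ""))
  proteins <- AAStringSet(c(
    query_PAP = as.character(Biostrings::translate(focalDNA)),
    donor_PAP = as.character(Biostrings::translate(donorDNA)),
    recipient_TNT = as.character(Biostrings::translate(recipientParalog))))

  aaLen <- gl / 3L
  homology <- rbind(
    homologyRow("query_PAP", "donor_PAP", donorIdentity,
                modelEvalue(donorIdentity, gl, model), aaLen, "donor"),
    homologyRow("query_PAP", "recipient_TNT", recipientIdentity,
                modelEvalue(recipientIdentity, gl, model), aaLen,
                "recipient"))

  features <- makeFeatures(scenario, recipientLocus, donorLocus, L, gl)
  tree <- makeTree(scenario)

  aiExpected <- alienIndex(homology$evalue[2], homology$evalue[1])
  truth <- list(
    transfer = scenario@transfer,
    queryLeaf = "query_PAP", donorLeaf = "donor_PAP",
    recipientLeaf = "recipient_TNT",
    focalGeneStart = recipientLocus, focalGeneEnd = recipientLocus + gl - 1L,
    motifStartAA = motifStartAA,
    donorIdentity = donorIdentity, recipientIdentity = recipientIdentity,
    expectedAiPositive = scenario@transfer,
    expectedCategory = if (scenario@transfer) "very_likely_hgt"
                       else "no_hgt_signal",
    expectedGcVerdict = if (scenario@transfer) "donor_consistent"
                        else "host_consistent",
    expectedCongruent = scenario@transfer,
    mgeWithin = scenario@mgeWithin)
  stopifnot(isTRUE(aiExpected > 0) == scenario@transfer || aiExpected == 0)

  new("SyntheticDataset", genomes = genomes, features = features,
      proteins = proteins, homology = homology, tree = tree,
      truth = truth, scenario = scenario)
}

makeFeatures <- function(scenario, recipientLocus, donorLocus, L, gl) {
  flank <- 5000L
  geneEnd <- recipientLocus + gl - 1L
  feats <- GRanges(
    c("recipient_genome", "donor_genome"),
    IRanges(c(recipientLocus, donorLocus),
            c(geneEnd, donorLocus + gl - 1L)),
    strand = "+")
  mcols(feats)$type <- "gene"
  mcols(feats)$ID <- c("focal_gene", "donor_gene")
  mcols(feats)$protein_id <- c("query_PAP", "donor_PAP")
  mcols(feats)$element_class <- NA_character_
  mcols(feats)$host <- NA_character_
  mcols(feats)$gc <- NA_real_

  nIn <- scenario@mgeWithin
  nOut <- scenario@mgeOutside
  n <- nIn + nOut
  if (n > 0L) {
    dists <- c(if (nIn) sample(200:4500, nIn, replace = TRUE),
               if (nOut) sample((flank + 1500L):(flank + 5500L), nOut,
                                replace = TRUE))
    sides <- rep_len(c(1, -1), n)
    lens <- sample(20:220, n, replace = TRUE)
    starts <- ifelse(sides > 0, geneEnd + dists,
                     recipientLocus - dists - lens + 1L)
    starts <- pmax(1L, pmin(as.integer(starts), L - max(lens)))
    mge <- GRanges("recipient_genome",
                   IRanges(starts, width = lens), strand = "+")
    mcols(mge)$type <- "mobile_element"
    mcols(mge)$ID <- paste0("mge_", seq_len(n))
    mcols(mge)$protein_id <- NA_character_
    mcols(mge)$element_class <- sample(c("plasmid", "prophage", "virus"),
                                       n, replace = TRUE)
    mcols(mge)$host <- "synthetic_host"
    mcols(mge)$gc <- pmin(100, pmax(0, scenario@donorGC + runif(n, -5, 5)))
    suppressWarnings(feats <- c(feats, mge))
  }
  names(feats) <- mcols(feats)$ID
  feats
}

#' Simulate a gene tree for a scenario
#'
#' Builds a tree over a donor clade and a recipient clade. With
#' \code{transfer = TRUE} the query leaf is grafted as sister to the donor
#' leaf on a short branch, so the query's nearest patristic neighbour is
#' the donor; otherwise the query nests inside the recipient clade.
#' Internal supports are drawn in [700, 1000] (per-mille scale), so every
#' node survives a collapse at 700.
#'
#' @param scenario a [TransferScenario-class] (\code{treeLeaves >= 4}).
#' @return an \code{ape::phylo}; serialize with [writeNewick()]. The same
#'   seed yields a byte-identical Newick string.
#' @export
makeTree <- function(scenario) {
  stopifnot(is(scenario, "TransferScenario"))
  set.seed(scenario@seed + 1L)
  n <- scenario@treeLeaves
  nDonorExtra <- max(0L, (n - 3L) %/% 2L)
  nRecipExtra <- max(0L, n - 3L - nDonorExtra)
  elen <- function() round(runif(1, 0.1, 0.4), 4)
  sup <- function() sample(700:1000, 1)
  cherryLen <- function() round(runif(1, 0.01, 0.03), 4)

  nest <- function(core, leaves) {
    for (leaf in leaves)
      core <- sprintf("(%s:%s,%s:%s)%d", core, elen(), leaf, elen(), sup())
    core
  }
  if (scenario@transfer) {
    donorCore <- sprintf("(query_PAP:%s,donor_PAP:%s)%d",
                         cherryLen(), cherryLen(), sup())
    donorClade <- nest(donorCore,
                       if (nDonorExtra) paste0("donor_rel_", seq_len(nDonorExtra)))
    recipClade <- nest("recipient_TNT",
                       if (nRecipExtra) paste0("recipient_rel_", seq_len(nRecipExtra)))
  } else {
    recipCore <- sprintf("(query_PAP:%s,recipient_TNT:%s)%d",
                         cherryLen(), cherryLen(), sup())
    recipClade <- nest(recipCore,
                       if (nRecipExtra) paste0("recipient_rel_", seq_len(nRecipExtra)))
    donorClade <- nest("donor_PAP",
                       if (nDonorExtra) paste0("donor_rel_", seq_len(nDonorExtra)))
  }
  newick <- sprintf("(%s:%s,%s:%s);", donorClade, elen(), recipClade, elen())
  parseNewick(newick)
}

#' Write a synthetic dataset to disk as standard text formats
#'
#' Writes \code{genomes.fasta}, \code{proteins.fasta},
#' \code{features.gff3}, \code{homology.tsv} (outfmt 6 + qcovs),
#' \code{donor_taxa.txt}, \code{recipient_taxa.txt}, \code{tree.nwk},
#' \code{truth.json} and a ready-to-run \code{config.yaml} for
#' [runPipeline()].
#'
#' @param dataset a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return the config path, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "SyntheticDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeFasta(dataset@genomes, p("genomes.fasta"))
  writeFasta(dataset@proteins, p("proteins.fasta"))
  writeGff3(dataset@features, p("features.gff3"))
  hom <- dataset@homology
  writeBlast6(hom[setdiff(names(hom), "subject_group")], p("homology.tsv"))
  writeLines(unique(hom$sseqid[hom$subject_group == "donor"]),
             p("donor_taxa.txt"))
  writeLines(unique(hom$sseqid[hom$subject_group == "recipient"]),
             p("recipient_taxa.txt"))
  writeNewick(dataset@tree, p("tree.nwk"))
  jsonlite::write_json(dataset@truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  config <- list(
    inputs = list(proteins = "proteins.fasta", homology = "homology.tsv",
                  donor_taxa = "donor_taxa.txt",
                  recipient_taxa = "recipient_taxa.txt",
                  features = "features.gff3", genomes = "genomes.fasta",
                  tree = "tree.nwk",
                  host_genome = "recipient_genome",
                  donor_genome = "donor_genome"),
    thresholds = list(ai_very_likely = 30, ai_possible = 0,
                      identity_rule = FALSE, collapse_support = 700,
                      flank = 5000),
    stages = list(motif = TRUE, gc = TRUE, tree = TRUE, mge = TRUE),
    pattern = PAP_SIGNATURE_CONSENSUS)
  yaml::write_yaml(config, p("config.yaml"))
  invisible(p("config.yaml"))
}
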