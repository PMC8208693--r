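# Mobile-genetic-element proximity: plasmid/prophage/virus fragments found
# within fixed flanking windows of a focal gene are circumstantial evidence
# that the locus sits in DNA with a mobile history. Distances follow the
# terminal-base convention: from the gene's 3'-terminal base to the
# element's proximal base on that side (and mirrored on the 5' side),
# counted as the simple coordinate difference, so an abutting element is at
# distance 1 and an overlapping one at 0.

grOne <- function(x, what) {
  if (!is(x, "GRanges") || length(x) != 1L)
    stop(what, " must be a GRanges of length 1")
  x
}

featureId <- function(x, default) {
  m <- mcols(x)
  for (key in c("element_id", "ID", "Name", "gene_id"))
    if (!is.null(m[[key]]) && !is.na(m[[key]][1])) return(as.character(m[[key]][1]))
  nm <- names(x)
  if (!is.null(nm) && nzchar(nm[1])) nm[1] else default
}

#' Flanking windows of a gene
#'
#' Builds the upstream and downstream windows of width \code{flank}
#' adjacent to the gene, 1-based inclusive, clipped at the contig bounds.
#' Upstream/downstream follow the gene's strand (the 5' side is upstream),
#' so on the minus strand the windows swap sides relative to coordinates.
#'
#' @param gene a length-1 \code{GRanges}.
#' @param flank window width in bp (default 5000).
#' @param contigLength length of the contig holding the gene.
#' @return a list with \code{GRanges} elements \code{upstream} and
#'   \code{downstream}; a window fully clipped away is empty (length 0).
#' @export
flankWindows <- function(gene, flank = 5000L, contigLength) {
  gene <- grOne(gene, "gene")
  if (flank < 0) stop("flank must be non-negative")
  if (start(gene) < 1L || end(gene) > contigLength)
    stop("gene does not lie within the contig")
  sq <- as.character(seqnames(gene))
  left <- if (start(gene) > 1L)
    GRanges(sq, IRanges(max(1L, start(gene) - flank), start(gene) - 1L))
  else GRanges()
  right <- if (end(gene) < contigLength)
    GRanges(sq, IRanges(end(gene) + 1L, min(contigLength, end(gene) + flank)))
  else GRanges()
  if (as.character(strand(gene)) == "-")
    list(upstream = right, downstream = left)
  else
    list(upstream = left, downstream = right)
}

#' Distance from a gene to a mobile element
#'
#' For an element on the gene's 3' side the distance runs from the gene's
#' 3'-terminal base to the element's gene-proximal end; analogously on the
#' 5' side. Distance is the coordinate difference, so adjacency gives 1;
#' overlapping features get distance 0 and \code{overlap = TRUE}. Side
#' labels (upstream/downstream) follow the gene's strand.
#'
#' @param gene,mge length-1 \code{GRanges} on the same sequence.
#' @param flank flank width used for the \code{within_flank} flag
#'   (default 5000).
#' @return one-row data.frame with columns \code{gene_id},
#'   \code{element_id}, \code{side}, \code{distance}, \code{overlap},
#'   \code{within_flank}.
#' @export
mgeDistance <- function(gene, mge, flank = 5000L) {
  gene <- grOne(gene, "gene"); mge <- grOne(mge, "mge")
  if (as.character(seqnames(gene)) != as.character(seqnames(mge)))
    stop("gene and element lie on different sequences")
  minus <- as.character(strand(gene)) == "-"
  if (start(mge) > end(gene)) {            # element on the coordinate-right
    distance <- start(mge) - end(gene)
    side <- if (minus) "upstream" else "downstream"
    overlap <- FALSE
  } else if (end(mge) < start(gene)) {     # element on the coordinate-left
    distance <- start(gene) - end(mge)
    side <- if (minus) "downstream" else "upstream"
    overlap <- FALSE
  } else {
    distance <- 0L
    side <- NA_character_
    overlap <- TRUE
  }
  data.frame(gene_id = featureId(gene, "gene"),
             element_id = featureId(mge, "mge"),
             side = side, distance = as.integer(distance),
             overlap = overlap, within_flank = distance <= flank,
             stringsAsFactors = FALSE)
}

#' Mobile elements within the flanks of a gene, with G+C fold ratios
#'
#' Computes the distance of every element to the gene, keeps those within
#' the flank, sorts by distance and annotates each with the fold ratio of
#' its G+C content over the genome's.
#'
#' @param gene length-1 \code{GRanges}.
#' @param mges \code{GRanges} of elements on the same sequence; metadata
#'   columns \code{element_id}, \code{element_class}, \code{host},
#'   \code{gc}, \code{evalue}, \code{pident} are carried through when
#'   present.
#' @param flank flank width in bp (default 5000).
#' @param genomeGC genome mol\% G+C for the fold ratio (optional).
#' @return data.frame of within-flank elements sorted by distance, with a
#'   \code{fold_ratio} column when \code{genomeGC} is given; attribute
#'   \code{anyWithinFlank} carries the species-level summary flag.
#' @export
proximityReport <- function(gene, mges, flank = 5000L, genomeGC = NULL) {
  gene <- grOne(gene, "gene")
  rows <- lapply(seq_along(mges), function(i) {
    r <- mgeDistance(gene, mges[i], flank = flank)
    m <- mcols(mges[i])
    for (key in c("element_class", "host"))
      if (!is.null(m[[key]])) r[[key]] <- as.character(m[[key]][1])
    for (key in c("gc", "evalue", "pident"))  # GFF3 attributes arrive as text
      if (!is.null(m[[key]])) r[[key]] <- as.numeric(m[[key]][1])
    r
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), element_id = character(0),
               side = character(0), distance = integer(0),
               overlap = logical(0), within_flank = logical(0))
  out <- out[out$within_flank, , drop = FALSE]
  out <- out[order(out$distance, out$element_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(genomeGC) && nrow(out) && !is.null(out$gc))
    out$fold_ratio <- foldRatio(out$gc, genomeGC)
  attr(out, "anyWithinFlank") <- nrow(out) > 0L
  out
}

#' Read a tabular mobile-element hit file
#'
#' Tab-separated with header; required columns \code{element_id},
#' \code{seq_id}, \code{start}, \code{end}; recognised extras
#' \code{element_class}, \code{host}, \code{length}, \code{evalue},
#' \code{pident}, \code{gc}, \code{strand}.
#'
#' @param file path to the TSV.
#' @return a \code{GRanges} with the extras as metadata columns.
#' @export
readMgeHits <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("element_id", "seq_id", "start", "end")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("MGE hit table lacks column(s): ", paste(missing, collapse = ", "))
  strand <- if ("strand" %in% names(df)) df$strand else "+"
  gr <- GRanges(df$seq_id, IRanges(df$start, df$end), strand = strand)
  for (key in setdiff(names(df), c("seq_id", "start", "end", "strand")))
    mcols(gr)[[key]] <- df[[key]]
  gr
}
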