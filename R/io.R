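# Readers/writers for the standard formats the pipeline consumes: FASTA,
# BLAST tabular (outfmt 6), GFF3, and the pipeline's own TSV/JSON report.
# FASTA goes through Biostrings and GFF3 through rtracklayer; thin wrappers
# add the validation and normalisation the pipeline relies on (uppercasing,
# stop stripping, alphabet checks, row-numbered errors).

NT_IUPAC <- strsplit("ACGTURYSWKMBDHVN", "")[[1]]
AA_VALID <- c(AA_STANDARD, "X")

BLAST6_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                    "gapopen", "qstart", "qend", "sstart", "send",
                    "evalue", "bitscore")

#' Read a FASTA file into a DNAStringSet or AAStringSet
#'
#' Residues are uppercased, gap characters are rejected, and for protein
#' input trailing/internal \code{*} (stop) characters are stripped with a
#' warning. \code{U} in nucleotide input is converted to \code{T} so the
#' result fits the DNA alphabet. Characters outside the declared alphabet
#' (IUPAC nucleotide codes, or the 20 standard residues plus X) raise an
#' error naming the offending record and character.
#'
#' @param file path to a FASTA file (records may wrap lines).
#' @param alphabet \code{"nt"} or \code{"aa"}.
#' @return a named \code{DNAStringSet} (\code{alphabet = "nt"}) or
#'   \code{AAStringSet} (\code{alphabet = "aa"}); names hold the full header
#'   (id plus description). An empty file gives an empty set.
#' @export
readFasta <- function(file, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  raw <- Biostrings::readBStringSet(file)
  seqs <- toupper(as.character(raw))
  ids <- names(raw)
  if (length(seqs) == 0L)
    return(if (alphabet == "nt") DNAStringSet() else AAStringSet())
  if (any(grepl("[ \t]", seqs)))
    stop("sequence residues must not contain whitespace")
  if (alphabet == "aa" && any(grepl("\\*", seqs))) {
    warning("stripping '*' (stop) characters from protein sequences")
    seqs <- gsub("\\*", "", seqs)
  }
  valid <- if (alphabet == "nt") NT_IUPAC else AA_VALID
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(chars, valid)
    if (length(bad))
      stop(sprintf("record '%s' contains character(s) outside the %s alphabet: %s",
                   sub("\\s.*", "", ids[i]), alphabet,
                   paste(bad, collapse = ", ")))
  }
  if (alphabet == "nt") {
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
    out <- DNAStringSet(seqs)
  } else {
    out <- AAStringSet(seqs)
  }
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x a \code{DNAStringSet}, \code{AAStringSet} or named character
#'   vector.
#' @param file output path.
#' @param width line-wrap width.
#' @return \code{file}, invisibly.
#' @export
writeFasta <- function(x, file, width = 70L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, file, width = width)
  invisible(file)
}

#' Read BLAST tabular (outfmt 6) output
#'
#' Parses the standard 12-column layout (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore); extra named
#' columns such as \code{qcovs} may be declared through \code{columnSpec}.
#' Columns beyond the declared ones are ignored. E values of \code{"0.0"}
#' or \code{"0"} parse to exact zero, distinguishable from the smallest
#' positive double.
#'
#' @param file path to a tab-separated hit table without header.
#' @param columnSpec character vector of column names, default the standard
#'   12; must contain \code{evalue}.
#' @return a \code{data.frame} with one row per hit, rows in input order.
#'   Numeric fields are parsed; a wrong column count or a non-numeric E
#'   value raises an error giving the row number.
#' @export
readBlast6 <- function(file, columnSpec = BLAST6_COLUMNS) {
  stopifnot(is.character(columnSpec), "evalue" %in% columnSpec)
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(columnSpec)),
                                  columnSpec))
    return(coerceBlast6(out, columnSpec, integer(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  short <- which(nf < length(columnSpec))
  if (length(short))
    stop(sprintf("row %d has %d column(s); expected at least %d",
                 short[1], nf[short[1]], length(columnSpec)))
  mat <- t(vapply(parts, function(p) p[seq_along(columnSpec)],
                  character(length(columnSpec))))
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- columnSpec
  coerceBlast6(out, columnSpec, seq_along(lines))
}

coerceBlast6 <- function(df, columnSpec, rowIdx) {
  numeric_cols <- intersect(
    c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
      "sstart", "send", "evalue", "bitscore", "qcovs"), columnSpec)
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & nzchar(df[[cc]]))
    if (length(bad))
      stop(sprintf("row %d: non-numeric value '%s' in column %s",
                   rowIdx[bad[1]], df[[cc]][bad[1]], cc))
    df[[cc]] <- v
  }
  if (nrow(df) && any(df$evalue < 0))
    stop("negative E value in hit table")
  if ("pident" %in% names(df) && nrow(df) &&
      any(df$pident < 0 | df$pident > 100))
    stop("percent identity outside [0, 100]")
  df
}

#' Write a hit table in BLAST outfmt-6 layout
#'
#' @param hits data.frame as returned by [readBlast6()] (extra columns are
#'   written too).
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeBlast6 <- function(hits, file) {
  df <- hits
  if ("evalue" %in% names(df))
    df$evalue <- formatEvalue(df$evalue)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

# Serialize E values so exact zero survives a round trip and tiny exponents
# keep full precision.
formatEvalue <- function(e) {
  ifelse(e == 0, "0", format(e, digits = 15, scientific = TRUE, trim = TRUE))
}

#' Read genomic features from GFF3
#'
#' A thin validated wrapper around \code{rtracklayer::import}. Coordinates
#' stay 1-based inclusive. Strand \code{"."} (unstranded) is mapped to
#' \code{"+"} and flagged in the metadata column \code{strand_missing}.
#'
#' @param file path to a GFF3 file.
#' @return a \code{GRanges} whose \code{type} and attribute key-value pairs
#'   are metadata columns. Fewer than 9 columns, or start > end, raise an
#'   error giving the offending line.
#' @export
readGff3 <- function(file) {
  lines <- readLines(file)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop(sprintf("GFF3 line %d has %d column(s); 9 required", i, length(f)))
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e) || s > e)
      stop(sprintf("GFF3 line %d: invalid interval %s..%s", i, f[4], f[5]))
  }
  gr <- rtracklayer::import(file, format = "gff3")
  unstranded <- as.character(GenomicRanges::strand(gr)) == "*"
  if (any(unstranded)) {
    GenomicRanges::strand(gr)[unstranded] <- "+"
    mcols(gr)$strand_missing <- unstranded
  }
  gr
}

#' Write genomic features to GFF3
#'
#' @param gr a \code{GRanges} with a \code{type} metadata column (defaults
#'   to \code{"feature"} when absent); other metadata columns become GFF3
#'   attributes.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeGff3 <- function(gr, file) {
  if (is.null(mcols(gr)$type))
    mcols(gr)$type <- "feature"
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}

#' Write the pipeline report as TSV with a JSON mirror
#'
#' @param rows a data.frame of evidence rows (see [runEvidence()]).
#' @param prefix output path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json}.
#' @return the two paths, invisibly.
#' @export
writeReport <- function(rows, prefix) {
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  utils::write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(rows, json, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}
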