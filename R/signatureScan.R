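# Degenerate signature-motif parsing and window scanning. The poly(A)
# polymerase I consensus [LIV][LIV]G[RK][RK]Fx-[LIV]h[HQL][LIV] is the
# motivating pattern: 11 residue classes located in the beta-turn of the
# catalytic domain, diagnostic of bacterial PAPs as opposed to the
# CCA-adding tRNA nucleotidyltransferases.

#' Default hydrophobic residue set for the \code{h} pattern class
#'
#' The conventional aliphatic/aromatic set. Configurable in
#' [parsePattern()] and [scanMotif()].
#' @export
HYDROPHOBIC_DEFAULT <- c("A", "V", "L", "I", "M", "F", "W", "C")

#' The bacterial PAP I signature consensus pattern string
#'
#' Eleven positions: \code{[LIV][LIV]G[RK][RK]Fx-[LIV]h[HQL][LIV]}, where
#' \code{x} is any residue, \code{h} a hydrophobic residue and the hyphen a
#' cosmetic separator.
#' @export
PAP_SIGNATURE_CONSENSUS <- "[LIV][LIV]G[RK][RK]Fx-[LIV]h[HQL][LIV]"

#' Parse a PROSITE-like degenerate motif string
#'
#' Bracketed groups are explicit residue sets, bare capital letters are
#' singleton sets, \code{x} is a wildcard, \code{h} matches the hydrophobic
#' set, and hyphens are ignored as separators.
#'
#' @param text the pattern string.
#' @param hydrophobic residues matched by \code{h}.
#' @return a [ConsensusPattern-class]. Unbalanced brackets or characters
#'   outside \code{A-Z}, \code{x}, \code{h}, \code{[}, \code{]}, \code{-}
#'   raise a parse error reporting the offset.
#' @examples
#' p <- parsePattern(PAP_SIGNATURE_CONSENSUS)
#' patternLength(p)  # 11
#' @export
parsePattern <- function(text, hydrophobic = HYDROPHOBIC_DEFAULT) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  chars <- strsplit(text, "")[[1]]
  classes <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "-") {
      i <- i + 1L
    } else if (ch == "x") {
      classes[[length(classes) + 1L]] <- list(type = "any", residues = character(0))
      i <- i + 1L
    } else if (ch == "h") {
      classes[[length(classes) + 1L]] <- list(type = "hydrophobic",
                                              residues = character(0))
      i <- i + 1L
    } else if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (length(close) == 0L)
        stop(sprintf("unbalanced '[' at offset %d in pattern '%s'", i, text))
      close <- close[1]
      members <- chars[(i + 1L):(close - 1L)]
      if (length(members) == 0L || !all(members %in% LETTERS))
        stop(sprintf("invalid residue set at offset %d in pattern '%s'", i, text))
      if (!all(members %in% AA_STANDARD))
        stop(sprintf("non-standard residue in set at offset %d: %s",
                     i, paste(setdiff(members, AA_STANDARD), collapse = ",")))
      classes[[length(classes) + 1L]] <- list(type = "set", residues = members)
      i <- close + 1L
    } else if (ch == "]") {
      stop(sprintf("unbalanced ']' at offset %d in pattern '%s'", i, text))
    } else if (ch %in% LETTERS) {
      if (!ch %in% AA_STANDARD)
        stop(sprintf("non-standard residue '%s' at offset %d", ch, i))
      classes[[length(classes) + 1L]] <- list(type = "set", residues = ch)
      i <- i + 1L
    } else {
      stop(sprintf("invalid character '%s' at offset %d in pattern '%s'",
                   ch, i, text))
    }
  }
  new("ConsensusPattern", classes = classes, sourceText = text,
      hydrophobic = hydrophobic)
}

# residues matched at one pattern position
positionResidues <- function(pattern, i) {
  cl <- pattern@classes[[i]]
  switch(cl$type,
         any = AA_STANDARD,
         hydrophobic = pattern@hydrophobic,
         set = cl$residues)
}

# mismatch counts for every window of seq (character scalar) vs pattern
windowMismatches <- function(seqChars, pattern) {
  k <- length(pattern@classes)
  n <- length(seqChars)
  nw <- n - k + 1L
  if (nw < 1L) return(integer(0))
  mism <- integer(nw)
  for (j in seq_len(k)) {
    ok <- seqChars[j:(j + nw - 1L)] %in% positionResidues(pattern, j)
    mism <- mism + !ok
  }
  mism
}

#' Scan a protein sequence for windows matching a degenerate motif
#'
#' Slides the pattern along the sequence and returns every window whose
#' count of class-violating positions is at most \code{maxMismatches}, in
#' ascending start order. Overlapping hits are all reported.
#'
#' @param x an \code{AAString}/\code{AAStringSet} element or a character
#'   scalar protein sequence.
#' @param pattern a [ConsensusPattern-class] or a pattern string (parsed
#'   with the default hydrophobic set).
#' @param maxMismatches tolerated violations per window (default 0).
#' @param sequenceId id used in the result (defaults to the name of
#'   \code{x} or \code{"seq"}).
#' @return a \code{data.frame} with columns \code{sequence_id},
#'   \code{start} (1-based), \code{window}, \code{mismatches}. A sequence
#'   shorter than the pattern gives zero rows.
#' @examples
#' scanMotif("LVGKRFRLAHIRF", PAP_SIGNATURE_CONSENSUS)
#' @export
scanMotif <- function(x, pattern, maxMismatches = 0L, sequenceId = NULL) {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  stopifnot(is(pattern, "ConsensusPattern"), maxMismatches >= 0L)
  seq <- as.character(x)[1]
  if (is.null(sequenceId))
    sequenceId <- if (!is.null(names(x)) && nzchar(names(x)[1]))
      names(x)[1] else "seq"
  chars <- strsplit(toupper(seq), "")[[1]]
  mism <- windowMismatches(chars, pattern)
  keep <- which(mism <= maxMismatches)
  k <- length(pattern@classes)
  data.frame(
    sequence_id = rep(sequenceId, length(keep)),
    start = keep,
    window = vapply(keep, function(s) paste(chars[s:(s + k - 1L)],
                                            collapse = ""), character(1)),
    mismatches = mism[keep],
    stringsAsFactors = FALSE)
}

#' Best-matching window of a sequence against a pattern
#'
#' Returns the single window with the minimal number of class violations
#' (ties broken by smallest start), regardless of any tolerance. Useful for
#' reporting near-matches of the consensus.
#'
#' @inheritParams scanMotif
#' @return a one-row \code{data.frame} as in [scanMotif()]. A sequence
#'   shorter than the pattern raises an error.
#' @export
bestWindow <- function(x, pattern, sequenceId = NULL) {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  seq <- as.character(x)[1]
  if (is.null(sequenceId))
    sequenceId <- if (!is.null(names(x)) && nzchar(names(x)[1]))
      names(x)[1] else "seq"
  chars <- strsplit(toupper(seq), "")[[1]]
  k <- length(pattern@classes)
  if (length(chars) < k)
    stop(sprintf("sequence length %d is shorter than the pattern (%d)",
                 length(chars), k))
  mism <- windowMismatches(chars, pattern)
  s <- which.min(mism)
  data.frame(sequence_id = sequenceId, start = s,
             window = paste(chars[s:(s + k - 1L)], collapse = ""),
             mismatches = mism[s], stringsAsFactors = FALSE)
}

#' Scan every sequence of a protein set for a motif
#'
#' @param seqs an \code{AAStringSet} (or named character vector).
#' @inheritParams scanMotif
#' @return row-bound [scanMotif()] results for all sequences.
#' @export
scanMotifSet <- function(seqs, pattern, maxMismatches = 0L) {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  res <- lapply(seq_along(seqs), function(i)
    scanMotif(as.character(seqs[[i]]), pattern,
              maxMismatches = maxMismatches, sequenceId = ids[i]))
  do.call(rbind, res)
}
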