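# G+C content and compositional affinity. A gene whose mol% G+C sides with
# a distant donor rather than with its host genome is a classic
# composition-based indicator of horizontal acquisition; amelioration
# erodes the signal over time, so it is corroborating rather than decisive
# evidence.

# expected G+C contribution of each IUPAC nucleotide code
GC_WEIGHTS <- c(A = 0, C = 1, G = 1, T = 0, U = 0,
                R = 0.5, Y = 0.5, S = 1, W = 0, K = 0.5, M = 0.5,
                B = 2 / 3, D = 1 / 3, H = 1 / 3, V = 2 / 3, N = 0.5)

#' G+C content of a nucleotide sequence
#'
#' G, C and S contribute 1 to the G+C count; A, T, U and W contribute 0;
#' the remaining IUPAC ambiguity codes contribute their expected G+C
#' fraction (R = Y = K = M = N = 0.5, B = V = 2/3, D = H = 1/3). The
#' denominator is the full sequence length, so with plain ACGT input this
#' reduces to the simple count.
#'
#' @param x a \code{DNAString}, a single-element \code{DNAStringSet}, or a
#'   character scalar of IUPAC nucleotide codes.
#' @return a list with fields \code{length}, \code{gcCount} (possibly
#'   fractional) and \code{molPercent}. Empty or non-IUPAC input raises an
#'   error.
#' @examples
#' gcContent("ATGC")$molPercent    # 50
#' gcContent("GGCCSS")$molPercent  # 100
#' @export
gcContent <- function(x) {
  if (is(x, "DNAStringSet")) x <- x[[1]]
  if (is(x, "DNAString")) {
    freq <- Biostrings::alphabetFrequency(x)
    freq <- freq[names(freq) %in% names(GC_WEIGHTS)]
    n <- sum(freq)
    if (n == 0L) stop("empty sequence: mol% G+C is undefined")
    gc <- sum(freq * GC_WEIGHTS[names(freq)])
  } else {
    chars <- strsplit(toupper(as.character(x)[1]), "")[[1]]
    if (length(chars) == 0L) stop("empty sequence: mol% G+C is undefined")
    bad <- setdiff(unique(chars), names(GC_WEIGHTS))
    if (length(bad))
      stop("non-IUPAC nucleotide character(s): ", paste(bad, collapse = ", "))
    n <- length(chars)
    gc <- sum(GC_WEIGHTS[chars])
  }
  list(length = n, gcCount = unname(gc), molPercent = unname(100 * gc / n))
}

#' mol\% G+C of every sequence in a set
#'
#' @param seqs a \code{DNAStringSet} or character vector.
#' @return named numeric vector of mol\% values.
#' @export
gcPercent <- function(seqs) {
  if (is.character(seqs)) seqs <- DNAStringSet(toupper(seqs))
  vapply(seq_along(seqs),
         function(i) gcContent(seqs[[i]])$molPercent, numeric(1)) |>
    setNames(names(seqs))
}

#' Does a gene's G+C composition side with the donor or the host?
#'
#' Compares the absolute differences |gene - host genome| and |gene -
#' donor gene|; the smaller difference wins, an exact tie is reported as
#' such.
#'
#' @param geneGC,hostGenomeGC,donorGeneGC mol\% values in [0, 100].
#' @return a [GCAffinity-class].
#' @examples
#' verdict(gcAffinity(71.3, 32.7, 71.3))  # donor_consistent
#' @export
gcAffinity <- function(geneGC, hostGenomeGC, donorGeneGC) {
  vals <- c(geneGC, hostGenomeGC, donorGeneGC)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100))
    stop("mol% values must lie in [0, 100]")
  dh <- abs(geneGC - hostGenomeGC)
  dd <- abs(geneGC - donorGeneGC)
  v <- if (dd < dh) "donor_consistent" else if (dh < dd) "host_consistent" else "tie"
  new("GCAffinity", geneGC = geneGC, hostGenomeGC = hostGenomeGC,
      donorGeneGC = donorGeneGC, deltaHost = dh, deltaDonor = dd,
      verdict = v)
}

#' Fold ratio of two G+C contents
#'
#' The ratio mge/genome used to express how much more GC-rich a mobile
#' element is than the genome hosting it.
#'
#' @param mgeGC,genomeGC mol\% values; \code{genomeGC} must be positive.
#' @param digits decimals for the reported ratio (default 1, the table
#'   convention).
#' @return the rounded ratio.
#' @examples
#' foldRatio(86.4, 30.4)  # 2.8
#' foldRatio(69.9, 32.7)  # 2.1
#' @export
foldRatio <- function(mgeGC, genomeGC, digits = 1L) {
  if (any(genomeGC <= 0)) stop("genome mol% G+C must be positive")
  round(mgeGC / genomeGC, digits)
}

#' Sliding-window G+C profile
#'
#' Windows start at 1-based positions 1, 1+step, 1+2*step, ...; a final
#' partial window (shorter than \code{window}) is included and flagged.
#'
#' @param x sequence as accepted by [gcContent()].
#' @param window window width in bases (at most the sequence length).
#' @param step step in bases (>= 1).
#' @return data.frame with columns \code{start}, \code{end},
#'   \code{length}, \code{gcCount}, \code{molPercent}, \code{partial}.
#' @export
slidingWindowGC <- function(x, window, step = window) {
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  seq <- toupper(as.character(x)[1])
  n <- nchar(seq)
  if (window > n) stop("window exceeds sequence length")
  starts <- seq.int(1L, n, by = step)
  # drop starts that begin past the end of the last full-or-partial window
  starts <- starts[starts <= n]
  rows <- lapply(starts, function(s) {
    e <- min(s + window - 1L, n)
    st <- gcContent(substr(seq, s, e))
    data.frame(start = s, end = e, length = st$length, gcCount = st$gcCount,
               molPercent = st$molPercent, partial = (e - s + 1L) < window)
  })
  do.call(rbind, rows)
}
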