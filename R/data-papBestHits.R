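#' Curated best-hit E values for 15 putative PAP acquisitions
#'
#' The donor and recipient best-hit E values, percent identities and
#' coverages for the 15 bacterial species in which a poly(A) polymerase I
#' gene is inferred to have been horizontally acquired from a beta- or
#' gamma-proteobacterium, together with the alien index reported for each.
#' In every row the donor best hit has E value 0 (identity 80-100\%),
#' while the best recipient-lineage hit is the distant tRNA
#' nucleotidyltransferase paralogue.
#'
#' Recomputing the alien index from the E-value pairs reproduces the
#' reported integer for 13 of the 15 rows; the Mesorhizobium and
#' Campylobacter rows differ from the formula by 3 and 1 respectively
#' (the package follows the formula and does not reconcile those cells).
#'
#' @return data.frame with columns \code{species}, \code{donor_species},
#'   \code{donor_evalue}, \code{donor_identity}, \code{donor_coverage},
#'   \code{recipient_species}, \code{recipient_evalue},
#'   \code{recipient_identity}, \code{recipient_coverage},
#'   \code{reported_ai}.
#' @examples
#' tab <- papBestHits()
#' round(alienIndex(tab$recipient_evalue, tab$donor_evalue))
#' @export
papBestHits <- function() {
  utils::read.table(
    system.file("extdata", "pap_best_hits.tsv", package = "hgtEvidence",
                mustWork = TRUE),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE, quote = "")
}
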