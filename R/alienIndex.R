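# The alien index: AI = ln(best recipient E value + 1e-200) -
# ln(best donor E value + 1e-200). Large positive values mean the query is
# far closer to the candidate donor lineage than to its own, the signature
# of a horizontally acquired gene. The pseudocount caps the statistic at
# ln(1) - ln(1e-200) = 460.517... when the recipient hit is absent (E
# treated as 1) and the donor E value is 0.

AI_EPSILON <- 1e-200

#' Compute the alien index from two best-hit E values
#'
#' \code{AI = ln(recipientEvalue + epsilon) - ln(donorEvalue + epsilon)}.
#' A missing hit (\code{NA}) is substituted by E = 1 before the formula,
#' which makes the maximum attainable value \code{ln(1) - ln(1e-200) =
#' 460.517...} (reported as 460.5 to one decimal).
#'
#' @param recipientEvalue best E value against the recipient lineage
#'   (non-negative; \code{NA} = no hit).
#' @param donorEvalue best E value against the candidate donor lineage
#'   (non-negative; \code{NA} = no hit).
#' @param epsilon pseudocount added to both E values (default
#'   \code{1e-200}).
#' @return the alien index in natural-log units, full precision.
#'   Vectorised over the two E-value arguments.
#' @examples
#' alienIndex(1e-36, 0)          # 377.62..., rounds to 378
#' round(alienIndex(NA, 0), 1)   # 460.5, the maximum
#' round(alienIndex(0, 6e-161), 1)  # -91.6
#' @export
alienIndex <- function(recipientEvalue, donorEvalue, epsilon = AI_EPSILON) {
  recipientEvalue[is.na(recipientEvalue)] <- 1
  donorEvalue[is.na(donorEvalue)] <- 1
  if (any(recipientEvalue < 0) || any(donorEvalue < 0))
    stop("E values must be non-negative")
  log(recipientEvalue + epsilon) - log(donorEvalue + epsilon)
}

#' Classify an alien index value into an HGT category
#'
#' With the identity rule disabled (the prokaryote-to-prokaryote mode):
#' AI > 30 is \code{very_likely_hgt}, 0 < AI <= 30 is \code{possible_hgt},
#' AI <= 0 is \code{no_hgt_signal}. With the rule enabled the three
#' contamination-aware categories apply: \code{very_likely_hgt} needs
#' AI > 30 and donor identity < 70\%; \code{possible_hgt} needs AI > 0 and
#' identity < 70\%; AI > 0 with identity >= 70\% is
#' \code{likely_contamination}. The identity stipulation targets
#' prokaryote-to-eukaryote transfers, where a near-identical donor hit more
#' plausibly reflects contamination than ancient transfer.
#'
#' @param ai alien index value(s).
#' @param donorIdentity percent identity to the best donor hit.
#' @param identityRule enable the 70\%-identity contamination rule
#'   (default \code{FALSE}).
#' @return character vector of categories.
#' @export
classifyAlienIndex <- function(ai, donorIdentity = NA_real_,
                               identityRule = FALSE) {
  stopifnot(all(is.finite(ai)))
  n <- max(length(ai), length(donorIdentity))
  ai <- rep_len(ai, n)
  donorIdentity <- rep_len(donorIdentity, n)
  out <- rep("no_hgt_signal", n)
  if (!identityRule) {
    out[ai > 0 & ai <= 30] <- "possible_hgt"
    out[ai > 30] <- "very_likely_hgt"
  } else {
    if (any(is.na(donorIdentity) & ai > 0))
      stop("identityRule = TRUE requires donorIdentity for positive AI")
    out[ai > 0 & ai <= 30 & donorIdentity < 70] <- "possible_hgt"
    out[ai > 30 & donorIdentity < 70] <- "very_likely_hgt"
    out[ai > 0 & donorIdentity >= 70] <- "likely_contamination"
  }
  out
}

#' Select the best donor and recipient hits from a homology table
#'
#' Within each subject group the hit with the minimal E value wins; ties
#' are broken by larger bit score, then larger percent identity, then
#' lexicographic subject id. Subjects listed in \code{excludeSubjects}
#' (e.g. self-matches) are dropped first. An empty group yields an absent
#' best hit, which downstream is treated as E = 1.
#'
#' @param hits data.frame as from [readBlast6()], with a
#'   \code{subject_group} column, or one assigned here via
#'   \code{donorSubjects}/\code{recipientSubjects}.
#' @param donorSubjects,recipientSubjects subject ids (or values of
#'   \code{groupColumn}) defining the two groups, used when
#'   \code{subject_group} is absent.
#' @param excludeSubjects subject ids removed before selection.
#' @return a list with elements \code{donor} and \code{recipient}, each a
#'   one-row data.frame or \code{NULL} when the group is empty.
#' @export
bestHits <- function(hits, donorSubjects = NULL, recipientSubjects = NULL,
                     excludeSubjects = character(0)) {
  if (nrow(hits) && length(excludeSubjects))
    hits <- hits[!hits$sseqid %in% excludeSubjects, , drop = FALSE]
  if (is.null(hits$subject_group)) {
    if (is.null(donorSubjects) || is.null(recipientSubjects))
      stop("either a subject_group column or donor/recipient subject sets are required")
    hits$subject_group <- "other"
    hits$subject_group[hits$sseqid %in% donorSubjects] <- "donor"
    hits$subject_group[hits$sseqid %in% recipientSubjects] <- "recipient"
  }
  pick <- function(group) {
    g <- hits[hits$subject_group == group, , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    ord <- order(g$evalue, -g$bitscore, -g$pident, g$sseqid)
    g[ord[1], , drop = FALSE]
  }
  list(donor = pick("donor"), recipient = pick("recipient"))
}

#' Alien index and category for one query from a homology table
#'
#' Combines [bestHits()], [alienIndex()] and [classifyAlienIndex()].
#'
#' @inheritParams bestHits
#' @param identityRule see [classifyAlienIndex()].
#' @param epsilon pseudocount, see [alienIndex()].
#' @return an [AlienIndexResult-class].
#' @export
evaluateAlienIndex <- function(hits, donorSubjects = NULL,
                               recipientSubjects = NULL,
                               excludeSubjects = character(0),
                               identityRule = FALSE, epsilon = AI_EPSILON) {
  best <- bestHits(hits, donorSubjects, recipientSubjects, excludeSubjects)
  dE <- if (is.null(best$donor)) 1 else best$donor$evalue
  rE <- if (is.null(best$recipient)) 1 else best$recipient$evalue
  dId <- if (is.null(best$donor)) NA_real_ else best$donor$pident
  aiv <- alienIndex(rE, dE, epsilon)
  new("AlienIndexResult", ai = aiv, aiRounded = round(aiv),
      donorEvalue = dE, recipientEvalue = rE, donorIdentity = dId,
      epsilon = epsilon,
      category = classifyAlienIndex(aiv, dId, identityRule))
}
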