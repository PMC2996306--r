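#' Declare a one-directional best hit
#'
#' For one query's hit list (per-target best HSP scores), the top target is
#' declared the best hit when it is the only hit, or when the ratio of the
#' second-best score to the best score is strictly below
#' \code{ratioCutoff}. Two targets tied at the top score give a ratio of
#' 1 and therefore no declaration.
#'
#' @param hits hit table for a single query (layout of
#'   [readTabularHits()]).
#' @param ratioCutoff second-to-best score ratio below which the top hit is
#'   unambiguous.
#' @return the declared target id, or \code{NA_character_}.
#' @examples
#' h <- data.frame(queryId = "c", targetId = c("x", "y"),
#'                 rawScore = c(100, 60), evalue = 0)
#' declareBestHit(h)  # "x" (0.6 < 0.7)
#' @export
declareBestHit <- function(hits, ratioCutoff = 0.7) {
  if (nrow(hits) == 0L) return(NA_character_)
  # best single HSP per target
  ho <- hits[order(-hits$rawScore, hits$targetId), , drop = FALSE]
  ho <- ho[!duplicated(ho$targetId), , drop = FALSE]
  if (nrow(ho) == 1L) return(ho$targetId[1])
  if (ho$rawScore[2] / ho$rawScore[1] < ratioCutoff) ho$targetId[1]
  else NA_character_
}

#' Reciprocal best-hit 1:1 orthologue assignment
#'
#' Pairs a contig and a reference peptide when each is the other's declared
#' best hit. Peptides shorter than \code{minPepAa} are removed before any
#' declaration (short sequences produce unreliable local-search
#' statistics). The returned pair set is a partial bijection: no contig or
#' peptide appears twice.
#'
#' @param fwdHits hit table of the forward search (contig queries against
#'   peptide targets, translated query).
#' @param revHits hit table of the reverse search (peptide queries against
#'   contig targets).
#' @param peptides named character vector or [Biostrings::AAStringSet] of
#'   the reference peptides (used for the length filter and coverage).
#' @param minPepAa minimum peptide length in amino acids.
#' @param ratioCutoff passed to [declareBestHit()].
#' @return data.frame with columns \code{contigId}, \code{peptideId},
#'   \code{fwdScore}, \code{revScore}, \code{identity} (fraction, from the
#'   forward best HSP) and \code{coverage} (fraction of the peptide length
#'   covered by the forward HSP), ordered by \code{contigId}.
#' @export
reciprocalBestHits <- function(fwdHits, revHits, peptides, minPepAa = 50L,
                               ratioCutoff = 0.7) {
  pepLen <- nchar(as.character(peptides))
  names(pepLen) <- names(peptides)
  okPep <- names(pepLen)[pepLen >= minPepAa]
  fwd <- fwdHits[fwdHits$targetId %in% okPep, , drop = FALSE]
  rev <- revHits[revHits$queryId %in% okPep, , drop = FALSE]
  fwdBest <- vapply(unique(fwd$queryId), function(q)
    declareBestHit(fwd[fwd$queryId == q, , drop = FALSE], ratioCutoff),
    character(1))
  revBest <- vapply(unique(rev$queryId), function(q)
    declareBestHit(rev[rev$queryId == q, , drop = FALSE], ratioCutoff),
    character(1))
  pairs <- list()
  for (ctg in sort(names(fwdBest))) {
    pep <- fwdBest[[ctg]]
    if (is.na(pep)) next
    back <- revBest[pep]
    if (is.na(back) || back != ctg) next
    fh <- fwd[fwd$queryId == ctg & fwd$targetId == pep, , drop = FALSE]
    fh <- fh[which.max(fh$rawScore), , drop = FALSE]
    rh <- rev[rev$queryId == pep & rev$targetId == ctg, , drop = FALSE]
    pairs[[ctg]] <- data.frame(
      contigId = ctg, peptideId = pep,
      fwdScore = fh$rawScore, revScore = max(rh$rawScore),
      identity = fh$pctIdentity / 100,
      coverage = (fh$tEnd - fh$tStart + 1) / pepLen[[pep]],
      stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0L)
    return(data.frame(contigId = character(0), peptideId = character(0),
                      fwdScore = numeric(0), revScore = numeric(0),
                      identity = numeric(0), coverage = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

#' One-step orthologue search
#'
#' Runs the forward (translated contig vs peptide) and reverse (peptide vs
#' translated contig) searches with [localSearch()] and applies
#' [reciprocalBestHits()].
#'
#' @param contigs named character vector or [ContigSet-class].
#' @param peptides named character vector or [Biostrings::AAStringSet].
#' @param maxEvalue e-value cutoff for both searches.
#' @inheritParams reciprocalBestHits
#' @return see [reciprocalBestHits()].
#' @export
findOrthologs <- function(contigs, peptides, minPepAa = 50L,
                          ratioCutoff = 0.7, maxEvalue = 1e-6) {
  ctg <- setNames(as.character(contigs), names(contigs))
  pep <- setNames(as.character(peptides), names(peptides))
  pep <- pep[nchar(pep) >= minPepAa]
  fwd <- localSearchAll(ctg, pep, mode = "x", maxEvalue = maxEvalue)
  rev <- localSearchAll(pep, ctg, mode = "tx", maxEvalue = maxEvalue)
  reciprocalBestHits(fwd, rev, pep, minPepAa, ratioCutoff)
}
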