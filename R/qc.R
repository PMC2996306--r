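#' Per-read quality filter
#'
#' A read fails when more than \code{maxNFrac} of its bases are 'N' or when
#' more than \code{maxLowQFrac} of its bases have Phred quality below
#' \code{minQ}. Both boundaries are strict ("more than"): a 100-bp read with
#' exactly 33 Ns is kept. Fractions are computed over the full read length,
#' Ns included.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param maxNFrac maximum tolerated fraction of N bases (strict).
#' @param maxLowQFrac maximum tolerated fraction of bases with quality below
#'   \code{minQ} (strict).
#' @param minQ Phred score below which a base counts as low-quality;
#'   the default of 20 corresponds to a 1% expected error rate.
#' @return logical vector, \code{TRUE} for reads to keep.
#' @seealso [polyAFilter()], [filterReads()]
#' @export
qualityFilter <- function(reads, maxNFrac = 0.33, maxLowQFrac = 0.34,
                          minQ = 20) {
  if (length(reads) == 0L) return(logical(0))
  w <- Biostrings::width(reads)
  nFrac <- as.vector(Biostrings::letterFrequency(reads, "N")) / w
  quals <- readQuals(reads)
  lowFrac <- sum(quals < minQ) / w
  !(nFrac > maxNFrac | lowFrac > maxLowQFrac)
}

#' Poly-A read filter
#'
#' Flags reads suspected of being dominated by a poly-adenine tail: a read
#' is dropped when strictly more than \code{maxAFrac} of its bases are
#' adenine. Only A is counted; reads that are reverse-complement poly-T are
#' not touched unless \code{alsoT = TRUE}.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param maxAFrac maximum tolerated adenine fraction (strict).
#' @param alsoT also apply the rule to thymine (off by default).
#' @return logical vector, \code{TRUE} for reads to keep.
#' @export
polyAFilter <- function(reads, maxAFrac = 0.33, alsoT = FALSE) {
  if (length(reads) == 0L) return(logical(0))
  w <- Biostrings::width(reads)
  keep <- !(as.vector(Biostrings::letterFrequency(reads, "A")) / w > maxAFrac)
  if (alsoT)
    keep <- keep &
      !(as.vector(Biostrings::letterFrequency(reads, "T")) / w > maxAFrac)
  keep
}

#' Trim reads to a fixed length
#'
#' Keeps the first \code{keepLen} bases (and qualities) of each read;
#' reads already at or below \code{keepLen} are returned unchanged. Used to
#' cut the error-prone tail cycles off longer lanes before mapping (e.g.
#' trimming 87-cycle reads to 75 bp).
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param keepLen positive integer, length to keep.
#' @return the trimmed read set.
#' @export
trimTail <- function(reads, keepLen) {
  stopifnotScalarInt(keepLen, "keepLen", min = 1L)
  if (length(reads) == 0L) return(reads)
  end <- pmin(Biostrings::width(reads), as.integer(keepLen))
  Biostrings::subseq(reads, start = 1L, end = end)
}

#' Apply the full pre-assembly read QC
#'
#' Runs the quality filter and the poly-A filter (dropped reads are counted
#' once: a read failing both is tallied under the quality filter) and then
#' optionally trims survivors to a fixed length. Mates are filtered
#' independently; with \code{dropPairs = TRUE} both mates are dropped
#' whenever either fails.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet] (read 1, or all
#'   reads when unpaired).
#' @param mates optional second [Biostrings::QualityScaledDNAStringSet] of
#'   the same length (read 2).
#' @param trimTo optional integer; survivors longer than this are trimmed.
#' @param dropPairs drop both mates when either fails a filter.
#' @inheritParams qualityFilter
#' @inheritParams polyAFilter
#' @return a list with elements \code{reads} (filtered/trimmed read 1),
#'   \code{mates} (same for read 2, or NULL) and \code{report}
#'   (a [QCReport-class] over all input reads).
#' @examples
#' r <- makeReadsForExample()
#' res <- filterReads(r)
#' res$report
#' @export
filterReads <- function(reads, mates = NULL, maxNFrac = 0.33,
                        maxLowQFrac = 0.34, minQ = 20, maxAFrac = 0.33,
                        trimTo = NULL, dropPairs = FALSE) {
  paired <- !is.null(mates)
  if (paired && length(mates) != length(reads))
    stop("'reads' and 'mates' must have equal length", call. = FALSE)
  all1 <- qualityFilter(reads, maxNFrac, maxLowQFrac, minQ)
  allA1 <- polyAFilter(reads, maxAFrac)
  if (paired) {
    all2 <- qualityFilter(mates, maxNFrac, maxLowQFrac, minQ)
    allA2 <- polyAFilter(mates, maxAFrac)
  } else {
    all2 <- allA2 <- logical(0)
  }
  qcPass <- c(all1, all2)
  aPass <- c(allA1, allA2)
  keep1 <- all1 & allA1
  keep2 <- if (paired) all2 & allA2 else NULL
  if (paired && dropPairs) {
    both <- keep1 & keep2
    keep1 <- keep2 <- both
  }
  out1 <- reads[keep1]
  out2 <- if (paired) mates[keep2] else NULL
  nTrimmed <- 0L
  if (!is.null(trimTo)) {
    nTrimmed <- sum(Biostrings::width(out1) > trimTo) +
      if (paired) sum(Biostrings::width(out2) > trimTo) else 0L
    out1 <- trimTail(out1, trimTo)
    if (paired) out2 <- trimTail(out2, trimTo)
  }
  nInput <- length(qcPass)
  nRemQ <- sum(!qcPass)
  nRemA <- sum(qcPass & !aPass)
  report <- new("QCReport", nInput = nInput, nRemovedQuality = nRemQ,
                nRemovedPolyA = nRemA, nTrimmed = as.integer(nTrimmed),
                nPassed = nInput - nRemQ - nRemA)
  list(reads = out1, mates = out2, report = report)
}

#' Tiny example read set
#'
#' Six 20-bp reads exercising each QC outcome; used in documentation
#' examples.
#'
#' @return a [Biostrings::QualityScaledDNAStringSet].
#' @export
makeReadsForExample <- function() {
  makeReads(
    c(ok = "ACGTACGTACGTACGTACGT",
      polyA = "AAAAAAAAAAAAAAAAAAAA",
      manyN = strrep("N", 20),
      lowq = "ACGTACGTACGTACGTACGT",
      ok2 = "TTGGCCAATTGGCCAATTGG",
      ok3 = "GATCGATCGATCGATCGATC"),
    quals = c(strrep("I", 20), strrep("I", 20), strrep("I", 20),
              strrep("#", 20), strrep("I", 20), strrep("I", 20)))
}
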