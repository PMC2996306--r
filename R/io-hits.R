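#' Read a 12-column tabular local-alignment hit file
#'
#' Parses the ubiquitous 12-column tab-separated local-alignment format
#' (query id, target id, percent identity, alignment length, mismatches,
#' gap opens, query start/end, target start/end, e-value, score). Target
#' coordinates given in reverse order (start > end, the minus-strand
#' convention) are normalised to start <= end and the original orientation
#' is retained in the \code{tStrand} column.
#'
#' @param path path to the hit file; an empty file yields a 0-row table.
#' @return a data.frame with columns \code{queryId}, \code{targetId},
#'   \code{pctIdentity}, \code{alnLen}, \code{mismatches}, \code{gapOpens},
#'   \code{qStart}, \code{qEnd}, \code{tStart}, \code{tEnd} (1-based,
#'   inclusive, start <= end), \code{evalue}, \code{rawScore},
#'   \code{tStrand} (\code{"+"}/\code{"-"}) and \code{frame} (query reading
#'   frame for translated searches, 0 for untranslated input).
#' @seealso [writeTabularHits()], [localSearch()]
#' @export
readTabularHits <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(emptyHits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop("hit file line ", which(nf < 12L)[1],
         ": expected 12 tab-separated columns, found ", min(nf), call. = FALSE)
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  hits <- data.frame(
    queryId = m[, 1], targetId = m[, 2],
    pctIdentity = as.numeric(m[, 3]), alnLen = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gapOpens = as.integer(m[, 6]),
    qStart = as.integer(m[, 7]), qEnd = as.integer(m[, 8]),
    tStart = as.integer(m[, 9]), tEnd = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), rawScore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  if (any(hits$qStart > hits$qEnd))
    stop("hit file: query coordinates must satisfy start <= end",
         call. = FALSE)
  if (any(is.na(hits$evalue)) || any(hits$evalue < 0))
    stop("hit file: e-values must be numeric and >= 0", call. = FALSE)
  rev <- hits$tStart > hits$tEnd
  hits$tStrand <- ifelse(rev, "-", "+")
  tmp <- hits$tStart[rev]
  hits$tStart[rev] <- hits$tEnd[rev]
  hits$tEnd[rev] <- tmp
  hits$frame <- 0L
  hits
}

# internal: 0-row hit table with the canonical column layout
emptyHits <- function() {
  data.frame(queryId = character(0), targetId = character(0),
             pctIdentity = numeric(0), alnLen = integer(0),
             mismatches = integer(0), gapOpens = integer(0),
             qStart = integer(0), qEnd = integer(0),
             tStart = integer(0), tEnd = integer(0),
             evalue = numeric(0), rawScore = numeric(0),
             tStrand = character(0), frame = integer(0),
             stringsAsFactors = FALSE)
}

#' Write hits in the 12-column tabular format
#'
#' Inverse of [readTabularHits()]: minus-strand hits are written with
#' reversed target coordinates, as produced by standard local-search tools.
#'
#' @param hits a hit table as returned by [readTabularHits()] or
#'   [localSearch()].
#' @param path output path.
#' @export
writeTabularHits <- function(hits, path) {
  ts <- ifelse(hits$tStrand == "-", hits$tEnd, hits$tStart)
  te <- ifelse(hits$tStrand == "-", hits$tStart, hits$tEnd)
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.4g",
                   hits$queryId, hits$targetId, hits$pctIdentity,
                   hits$alnLen, hits$mismatches, hits$gapOpens,
                   hits$qStart, hits$qEnd, ts, te,
                   hits$evalue, hits$rawScore)
  writeLines(lines, path)
  invisible(path)
}
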