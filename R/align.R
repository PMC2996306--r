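#' Scoring schemes for pairwise alignment and local search
#'
#' \code{nucScheme()} is the package's nucleotide scale: match +5,
#' mismatch -4, gap open -10, gap extend -1 (the first gapped position costs
#' the opening penalty, each further position the extension penalty). Under
#' this scale a perfect alignment of length L scores 5L, which keeps the
#' absolute-score acceptance rule used in EST clustering (score > 50 + 3L)
#' satisfiable for perfect matches longer than 25 nt. \code{protScheme()}
#' uses BLOSUM62 with gap -11/-1. Both carry Karlin-Altschul constants for
#' e-value computation in [localSearch()]; these are stock approximations
#' (nucleotide lambda = 1.28, K = 0.46; protein lambda = 0.267, K = 0.041)
#' and downstream decisions rely only on e-value ordering and thresholding,
#' never on absolute e-values.
#'
#' @return a list with elements \code{type}, \code{matrix}, \code{gapOpen},
#'   \code{gapExtend}, \code{kaLambda}, \code{kaK}, \code{wordSize}.
#' @export
nucScheme <- function() {
  list(type = "nucleotide",
       matrix = Biostrings::nucleotideSubstitutionMatrix(
         match = 5, mismatch = -4, baseOnly = FALSE),
       gapOpen = -10, gapExtend = -1,
       kaLambda = 1.28, kaK = 0.46, wordSize = 11L)
}

#' @rdname nucScheme
#' @export
protScheme <- function() {
  list(type = "protein", matrix = "BLOSUM62",
       gapOpen = -11, gapExtend = -1,
       kaLambda = 0.267, kaK = 0.041, wordSize = 3L)
}

# internal: Biostrings gap parameters for a scheme (Biostrings charges
# gapOpening + L * gapExtension for a length-L gap, our convention charges
# |gapOpen| for the first position and |gapExtend| for each further one)
.bsGap <- function(scheme) {
  list(opening = abs(scheme$gapOpen) - abs(scheme$gapExtend),
       extension = abs(scheme$gapExtend))
}

# internal: guess alphabet of a character sequence
.alphabetOf <- function(s) {
  if (grepl("^[ACGTNacgtn]*$", s)) "nucleotide" else "protein"
}

#' Pairwise alignment result
#'
#' Container for one pairwise alignment: the two gapped strings, the raw
#' alignment score, the percent-identity-like normalised score over non-gap
#' columns (0-100), and the fraction of alignment columns that differ
#' (gap columns counting as differences).
#'
#' @slot aId,bId sequence identifiers.
#' @slot alignedA,alignedB gapped strings of equal length.
#' @slot rawScore optimal alignment score under the scheme used.
#' @slot normScore 100 x (identical non-gap columns / non-gap columns).
#' @slot pDiff fraction of all alignment columns that are not identities.
#' @export
setClass("PairwiseAln",
  representation(aId = "character", bId = "character",
                 alignedA = "character", alignedB = "character",
                 rawScore = "numeric", normScore = "numeric",
                 pDiff = "numeric"))

setValidity("PairwiseAln", function(object) {
  if (nchar(object@alignedA) != nchar(object@alignedB))
    return("aligned strings must have equal length")
  if (object@pDiff < 0 || object@pDiff > 1) return("pDiff must be in [0,1]")
  TRUE
})

setMethod("show", "PairwiseAln", function(object) {
  cat("PairwiseAln ", object@aId, " vs ", object@bId,
      ": score ", object@rawScore,
      ", normScore ", round(object@normScore, 1),
      ", pDiff ", round(object@pDiff, 4), "\n", sep = "")
})

# internal: alignment statistics from two gapped strings
.alnStats <- function(va, vb) {
  a <- strsplit(va, "", fixed = TRUE)[[1]]
  b <- strsplit(vb, "", fixed = TRUE)[[1]]
  nonGap <- a != "-" & b != "-"
  ident <- nonGap & a == b
  list(ncol = length(a), nIdent = sum(ident), nNonGap = sum(nonGap),
       pDiff = if (length(a)) 1 - sum(ident) / length(a) else 0,
       normScore = if (sum(nonGap)) 100 * sum(ident) / sum(nonGap) else 0)
}

#' Global pairwise alignment
#'
#' Optimal Needleman-Wunsch alignment with affine gaps (end gaps
#' penalised), via the [Biostrings::pairwiseAlignment] dynamic-programming
#' engine, wrapped to the package's scoring convention and summary
#' statistics. \code{type = "overlap"} gives an ends-free alignment, used
#' when testing whether two contigs overlap.
#'
#' @param a,b sequences: named character scalars, or XString objects; both
#'   must be of the same alphabet (nucleotide or protein).
#' @param scheme a scoring scheme ([nucScheme()] or [protScheme()]);
#'   defaults to the scheme matching the alphabet.
#' @param type \code{"global"} or \code{"overlap"}.
#' @return a [PairwiseAln-class].
#' @examples
#' globalAlign(c(x = "ACGT"), c(y = "ACGA"))  # score 3*5 - 4 = 11
#' @export
globalAlign <- function(a, b, scheme = NULL, type = c("global", "overlap")) {
  type <- match.arg(type)
  aId <- if (!is.null(names(a))) names(a)[1] else "a"
  bId <- if (!is.null(names(b))) names(b)[1] else "b"
  sa <- toupper(as.character(a)[1]); sb <- toupper(as.character(b)[1])
  alphA <- .alphabetOf(sa); alphB <- .alphabetOf(sb)
  if (nzchar(sa) && nzchar(sb) && alphA != alphB)
    stop("cannot align sequences of different alphabets (", alphA,
         " vs ", alphB, ")", call. = FALSE)
  if (is.null(scheme))
    scheme <- if (alphA == "nucleotide" && alphB == "nucleotide")
      nucScheme() else protScheme()
  if (!nzchar(sa) || !nzchar(sb)) {         # forced all-gap alignment
    len <- max(nchar(sa), nchar(sb))
    score <- if (len == 0L) 0
             else scheme$gapOpen + (len - 1) * scheme$gapExtend
    va <- if (nzchar(sa)) sa else strrep("-", len)
    vb <- if (nzchar(sb)) sb else strrep("-", len)
    st <- .alnStats(va, vb)
    return(new("PairwiseAln", aId = aId, bId = bId, alignedA = va,
               alignedB = vb, rawScore = score, normScore = st$normScore,
               pDiff = st$pDiff))
  }
  gp <- .bsGap(scheme)
  xa <- if (scheme$type == "nucleotide") Biostrings::DNAString(sa)
        else Biostrings::AAString(sa)
  xb <- if (scheme$type == "nucleotide") Biostrings::DNAString(sb)
        else Biostrings::AAString(sb)
  pa <- Biostrings::pairwiseAlignment(
    xa, xb, type = type, substitutionMatrix = scheme$matrix,
    gapOpening = gp$opening, gapExtension = gp$extension)
  va <- as.character(Biostrings::alignedPattern(pa))
  vb <- as.character(Biostrings::alignedSubject(pa))
  st <- .alnStats(va, vb)
  new("PairwiseAln", aId = aId, bId = bId, alignedA = va, alignedB = vb,
      rawScore = Biostrings::score(pa), normScore = st$normScore,
      pDiff = st$pDiff)
}

#' Six-frame translation
#'
#' Translates a nucleotide sequence in frames +1, +2, +3 (forward strand)
#' and -1, -2, -3 (reverse complement), using the standard genetic code.
#' Stops are rendered \code{*}; codons containing N (or otherwise outside
#' the code table) translate to \code{X}; trailing partial codons are
#' dropped.
#'
#' @param seq a nucleotide sequence (character scalar or
#'   [Biostrings::DNAString]).
#' @return named character vector of 6 protein strings
#'   (\code{F1,F2,F3,R1,R2,R3}).
#' @examples
#' sixFrameTranslate("ATGAAATAA")[["F1"]]  # "MK*"
#' @export
sixFrameTranslate <- function(seq) {
  s <- toupper(as.character(seq)[1])
  code <- Biostrings::GENETIC_CODE
  tr1 <- function(x, f) {
    n <- nchar(x)
    ncod <- (n - f + 1L) %/% 3L
    if (ncod <= 0L) return("")
    starts <- f + 3L * (seq_len(ncod) - 1L)
    aa <- code[substring(x, starts, starts + 2L)]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
  rc <- if (nzchar(s)) .rc1(s) else s
  c(F1 = tr1(s, 1L), F2 = tr1(s, 2L), F3 = tr1(s, 3L),
    R1 = tr1(rc, 1L), R2 = tr1(rc, 2L), R3 = tr1(rc, 3L))
}

# internal: w-mer set of a string
.wmers <- function(s, w) {
  n <- nchar(s)
  if (n < w) return(character(0))
  unique(substring(s, 1:(n - w + 1L), w:n))
}

# internal: Karlin-Altschul e-value
.evalue <- function(score, m, n, scheme) {
  scheme$kaK * m * n * exp(-scheme$kaLambda * score)
}

# internal: one seeded local alignment between two same-alphabet strings;
# NULL when no shared word or e-value above cutoff
.localHsp <- function(qs, ts, scheme, m, n, maxEvalue) {
  w <- scheme$wordSize
  qw <- .wmers(qs, w)
  if (length(qw) == 0L || !any(qw %in% .wmers(ts, w))) return(NULL)
  gp <- .bsGap(scheme)
  mk <- if (scheme$type == "nucleotide") Biostrings::DNAString
        else Biostrings::AAString
  pa <- Biostrings::pairwiseAlignment(
    mk(qs), mk(ts), type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = gp$opening, gapExtension = gp$extension)
  s <- Biostrings::score(pa)
  ev <- .evalue(s, m, n, scheme)
  if (ev > maxEvalue) return(NULL)
  va <- as.character(Biostrings::alignedPattern(pa))
  vb <- as.character(Biostrings::alignedSubject(pa))
  st <- .alnStats(va, vb)
  gapOpens <- sum(rle(strsplit(va, "")[[1]] == "-")$values) +
    sum(rle(strsplit(vb, "")[[1]] == "-")$values)
  list(score = s, evalue = ev,
       qStart = Biostrings::start(Biostrings::pattern(pa)),
       qEnd = Biostrings::end(Biostrings::pattern(pa)),
       tStart = Biostrings::start(Biostrings::subject(pa)),
       tEnd = Biostrings::end(Biostrings::subject(pa)),
       alnLen = st$ncol, nIdent = st$nIdent,
       mismatches = st$nNonGap - st$nIdent, gapOpens = gapOpens)
}

# internal: map aa coords on a translated frame back to nucleotide coords
# on the forward strand of the untranslated sequence of length n
.aa2nt <- function(aaStart, aaEnd, frame, n) {
  f <- abs(frame)
  s <- f + 3L * (aaStart - 1L)
  e <- f + 3L * aaEnd - 1L
  if (frame > 0L) c(s, e) else c(n - e + 1L, n - s + 1L)
}

#' Seeded local similarity search
#'
#' A seed-and-extend local search over a set of targets: a query/target
#' pair is examined only when the two share an exact word (11 nt in
#' nucleotide space, 3 aa in protein space), in which case the optimal
#' local (Smith-Waterman) alignment is computed and converted to an
#' e-value via the Karlin-Altschul formula E = K m n exp(-lambda S).
#' Hits with E above \code{maxEvalue} are discarded; survivors are
#' returned sorted by decreasing raw score.
#'
#' Modes: \code{"n2n"} searches a nucleotide query (both strands) against
#' nucleotide targets; \code{"x"} searches the six-frame translation of a
#' nucleotide query against protein targets; \code{"tx"} searches a protein
#' or translated query against the six-frame translations of nucleotide
#' targets. HSP coordinates are always reported on the original (forward
#' strand, untranslated) sequences, with \code{frame} recording the query
#' reading frame for translated queries and \code{tStrand} the target
#' strand.
#'
#' @param query one named sequence (character scalar with a name, or a
#'   named length-1 character vector).
#' @param targets named character vector or XStringSet of target sequences.
#' @param mode search mode, see Details.
#' @param scheme optional scoring scheme; defaults to [nucScheme()] for
#'   \code{"n2n"} and [protScheme()] otherwise.
#' @param maxEvalue e-value cutoff; the package-wide default of 1e-6 is the
#'   uniform significance threshold used across all homology evidence.
#' @return a hit table in the layout of [readTabularHits()].
#' @export
localSearch <- function(query, targets, mode = c("n2n", "x", "tx"),
                        scheme = NULL, maxEvalue = 1e-6) {
  mode <- match.arg(mode)
  qId <- if (!is.null(names(query))) names(query)[1] else "query"
  qs <- toupper(as.character(query)[1])
  tIds <- names(targets)
  if (is.null(tIds)) tIds <- sprintf("t%d", seq_along(targets))
  tSeqs <- toupper(as.character(targets))
  if (is.null(scheme))
    scheme <- if (mode == "n2n") nucScheme() else protScheme()
  dbLen <- sum(nchar(tSeqs))
  rows <- list()
  addRow <- function(h, tId, qCoords, tCoords, tStrand, frame) {
    rows[[length(rows) + 1L]] <<- data.frame(
      queryId = qId, targetId = tId,
      pctIdentity = 100 * h$nIdent / h$alnLen, alnLen = h$alnLen,
      mismatches = h$mismatches, gapOpens = h$gapOpens,
      qStart = qCoords[1], qEnd = qCoords[2],
      tStart = tCoords[1], tEnd = tCoords[2],
      evalue = h$evalue, rawScore = h$score,
      tStrand = tStrand, frame = frame, stringsAsFactors = FALSE)
  }
  if (mode == "n2n") {
    m <- nchar(qs)
    for (i in seq_along(tSeqs)) {
      for (strand in c("+", "-")) {
        ts <- if (strand == "+") tSeqs[i] else .rc1(tSeqs[i])
        h <- .localHsp(qs, ts, scheme, m, dbLen, maxEvalue)
        if (is.null(h)) next
        tn <- nchar(tSeqs[i])
        tc <- if (strand == "+") c(h$tStart, h$tEnd)
              else c(tn - h$tEnd + 1L, tn - h$tStart + 1L)
        addRow(h, tIds[i], c(h$qStart, h$qEnd), tc, strand, 0L)
      }
    }
  } else if (mode == "x") {
    frames <- sixFrameTranslate(qs)
    frameNo <- c(1L, 2L, 3L, -1L, -2L, -3L)
    for (fi in seq_along(frames)) {
      fseq <- frames[[fi]]
      if (!nzchar(fseq)) next
      m <- nchar(fseq)
      for (i in seq_along(tSeqs)) {
        h <- .localHsp(fseq, tSeqs[i], scheme, m, dbLen, maxEvalue)
        if (is.null(h)) next
        qc <- .aa2nt(h$qStart, h$qEnd, frameNo[fi], nchar(qs))
        addRow(h, tIds[i], qc, c(h$tStart, h$tEnd), "+", frameNo[fi])
      }
    }
  } else {  # tx: protein (or pre-translated) query vs translated targets
    m <- nchar(qs)
    frameNo <- c(1L, 2L, 3L, -1L, -2L, -3L)
    for (i in seq_along(tSeqs)) {
      tframes <- sixFrameTranslate(tSeqs[i])
      for (fi in seq_along(tframes)) {
        fseq <- tframes[[fi]]
        if (!nzchar(fseq)) next
        h <- .localHsp(qs, fseq, scheme, m, dbLen, maxEvalue)
        if (is.null(h)) next
        tc <- .aa2nt(h$tStart, h$tEnd, frameNo[fi], nchar(tSeqs[i]))
        addRow(h, tIds[i], c(h$qStart, h$qEnd), tc,
               if (frameNo[fi] > 0) "+" else "-", 0L)
      }
    }
  }
  if (length(rows) == 0L) return(emptyHits())
  out <- do.call(rbind, rows)
  out[order(-out$rawScore, out$targetId), , drop = FALSE]
}

#' Search many queries against a target set
#'
#' Convenience wrapper running [localSearch()] per query and binding the
#' hit tables.
#'
#' @param queries named character vector or XStringSet.
#' @inheritParams localSearch
#' @return a combined hit table.
#' @export
localSearchAll <- function(queries, targets, mode = c("n2n", "x", "tx"),
                           scheme = NULL, maxEvalue = 1e-6) {
  mode <- match.arg(mode)
  qIds <- names(queries)
  if (is.null(qIds)) qIds <- sprintf("q%d", seq_along(queries))
  qSeqs <- as.character(queries)
  res <- lapply(seq_along(qSeqs), function(i)
    localSearch(setNames(qSeqs[i], qIds[i]), targets, mode, scheme,
                maxEvalue))
  do.call(rbind, c(res, list(emptyHits())))
}
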