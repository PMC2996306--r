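# ORF extraction and evidence-based contig selection.
#
# Two ORF types are distinguished, mirroring the two getorf-style
# definitions: type A is a translated region flanked by a Methionine and a
# stop codon; type B is a translated region merely free of stop codons
# (and may lack both start and stop at contig edges). Codons containing N
# translate to 'X' and never count as stops; runs of >= 10 Ns (scaffold
# gaps) split a contig into independently scanned segments.

# internal: segments of a contig between long N runs; list of (offset0, seq)
.nSegments <- function(seq, minRun = 10L) {
  m <- gregexpr(sprintf("N{%d,}", minRun), seq)[[1]]
  if (m[1] == -1L) return(list(list(offset = 0L, seq = seq)))
  starts <- as.integer(m); lens <- attr(m, "match.length")
  bounds <- c(1L, as.vector(rbind(starts, starts + lens)), nchar(seq) + 1L)
  segs <- list()
  for (i in seq(1L, length(bounds) - 1L, by = 2L)) {
    s <- bounds[i]; e <- bounds[i + 1L] - 1L
    if (e >= s) segs[[length(segs) + 1L]] <-
        list(offset = s - 1L, seq = substr(seq, s, e))
  }
  segs
}

# internal: an "ORF row"; coordinates are 0-based half-open on the contig
# forward strand and exclude the stop codon
.orfRow <- function(contigId, frame, start, end, orfType, protein) {
  data.frame(contigId = contigId, frame = frame, start = start, end = end,
             aaLen = nchar(protein), orfType = orfType, protein = protein,
             stringsAsFactors = FALSE)
}

#' Extract the best type A and type B ORFs of a contig
#'
#' Scans all six reading frames. The best ORF of each type is the longest;
#' ties are broken by frame order +1, +2, +3, -1, -2, -3, then by leftmost
#' position within the frame.
#'
#' @param contig a named character scalar (or length-1
#'   [Biostrings::DNAStringSet]).
#' @return list with elements \code{typeA} (one-row data.frame or NULL when
#'   no Met-to-stop ORF exists in any frame) and \code{typeB} (one-row
#'   data.frame); columns \code{contigId}, \code{frame}, \code{start},
#'   \code{end} (0-based half-open, forward strand, stop codon excluded),
#'   \code{aaLen}, \code{orfType}, \code{protein}.
#' @examples
#' extractOrfs(c(x = "ATGAAATAA"))$typeA$protein  # "MK"
#' @export
extractOrfs <- function(contig) {
  id <- if (!is.null(names(contig))) names(contig)[1] else "contig"
  seq <- toupper(as.character(contig)[1])
  n <- nchar(seq)
  bestA <- NULL; bestB <- NULL
  frameOrder <- c(1L, 2L, 3L, -1L, -2L, -3L)
  for (seg in .nSegments(seq)) {
    segLen <- nchar(seg$seq)
    frames <- sixFrameTranslate(seg$seq)
    for (fi in seq_along(frameOrder)) {
      frame <- frameOrder[fi]
      prot <- frames[[fi]]
      if (!nzchar(prot)) next
      # nt coords (0-based, within oriented segment) of aa range [i, j]
      toContig <- function(aaFrom, aaTo) {
        f <- abs(frame)
        s <- (f - 1L) + 3L * (aaFrom - 1L)
        e <- (f - 1L) + 3L * aaTo
        if (frame > 0L) c(seg$offset + s, seg$offset + e)
        else c(seg$offset + segLen - e, seg$offset + segLen - s)
      }
      # stop-free chunks with their aa offsets
      stops <- c(0L, which(strsplit(prot, "", fixed = TRUE)[[1]] == "*"),
                 nchar(prot) + 1L)
      for (ci in seq_len(length(stops) - 1L)) {
        from <- stops[ci] + 1L; to <- stops[ci + 1L] - 1L
        if (to < from) next
        chunk <- substr(prot, from, to)
        hasStop <- stops[ci + 1L] <= nchar(prot)
        # type B: the whole stop-free stretch
        if (is.null(bestB) || nchar(chunk) > bestB$aaLen) {
          cc <- toContig(from, to)
          bestB <- .orfRow(id, frame, cc[1], cc[2], "B", chunk)
        }
        # type A: first Met of the chunk up to a real stop
        if (hasStop) {
          mPos <- regexpr("M", chunk, fixed = TRUE)[1]
          if (mPos > 0L) {
            aProt <- substring(chunk, mPos)
            if (is.null(bestA) || nchar(aProt) > bestA$aaLen) {
              cc <- toContig(from + mPos - 1L, to)
              bestA <- .orfRow(id, frame, cc[1], cc[2], "A", aProt)
            }
          }
        }
      }
    }
  }
  if (is.null(bestB)) bestB <- .orfRow(id, 1L, 0L, 0L, "B", "")
  list(typeA = bestA, typeB = bestB)
}

#' Choose between the best type A and type B ORFs
#'
#' Keeps the ORF with a start codon (type A) unless there is none, or
#' unless the type B ORF both extends upstream of the type A ORF and
#' reaches the contig's 5' boundary in its frame - the signature of a true
#' start codon truncated off the contig.
#'
#' @param a best type A ORF (one-row data.frame) or NULL.
#' @param b best type B ORF (one-row data.frame).
#' @param contigLen contig length in nt (needed to assess the 5' boundary
#'   on minus-strand ORFs).
#' @return the selected one-row ORF data.frame.
#' @export
selectOrf <- function(a, b, contigLen) {
  if (is.null(a)) return(b)
  fivePrime <- function(orf) {
    if (orf$frame > 0L) orf$start else contigLen - orf$end
  }
  bAtBoundary <- fivePrime(b) == abs(b$frame) - 1L
  if (bAtBoundary && fivePrime(b) < fivePrime(a)) b else a
}

#' Selected ORFs for a contig set
#'
#' Runs [extractOrfs()] and [selectOrf()] over every contig.
#'
#' @param contigs a [ContigSet-class] or named character vector.
#' @return data.frame of selected ORFs, one row per contig.
#' @export
selectedOrfs <- function(contigs) {
  seqs <- as.character(contigs)
  ids <- names(contigs)
  rows <- lapply(seq_along(seqs), function(i) {
    orfs <- extractOrfs(setNames(seqs[i], ids[i]))
    selectOrf(orfs$typeA, orfs$typeB, nchar(seqs[i]))
  })
  do.call(rbind, rows)
}

#' Minimum-ORF-length partition
#'
#' Discards contigs whose selected ORF is shorter than \code{minAa} amino
#' acids (strictly: a 49-aa ORF is discarded, a 50-aa ORF kept).
#'
#' @param orfs data.frame from [selectedOrfs()].
#' @param minAa minimum ORF length in amino acids.
#' @return list with character vectors \code{kept} and \code{discarded}
#'   (contig ids; a partition of the input).
#' @export
orfLengthFilter <- function(orfs, minAa = 50L) {
  keep <- orfs$aaLen >= minAa
  list(kept = orfs$contigId[keep], discarded = orfs$contigId[!keep])
}

.evidenceVocab <- c("agam_pep", "aaeg_pep", "cqui_pep", "dmel_pep",
                    "agam_genome", "cdd", "smart", "pfam", "kog", "go")
.proteomeTags <- c("agam_pep", "aaeg_pep", "cqui_pep", "dmel_pep")

#' Build a per-contig evidence table from tagged hit files
#'
#' Each hit table contributes its tag to every query contig with at least
#' one hit at or below \code{maxEvalue}.
#'
#' @param hitsBySource named list of hit tables (layout of
#'   [readTabularHits()]); names must come from the controlled vocabulary
#'   \code{agam_pep, aaeg_pep, cqui_pep, dmel_pep, agam_genome, cdd, smart,
#'   pfam, kog, go}.
#' @param maxEvalue significance cutoff, uniform across sources.
#' @return named list: contig id -> character vector of evidence tags.
#' @export
buildEvidenceTable <- function(hitsBySource, maxEvalue = 1e-6) {
  tags <- names(hitsBySource)
  bad <- setdiff(tags, .evidenceVocab)
  if (length(bad))
    stop("unknown evidence tags: ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.evidenceVocab, collapse = ", "),
         call. = FALSE)
  ev <- list()
  for (tag in tags) {
    h <- hitsBySource[[tag]]
    ids <- unique(h$queryId[h$evalue <= maxEvalue])
    for (id in ids) ev[[id]] <- union(ev[[id]], tag)
  }
  ev
}

#' Final contig selection
#'
#' A contig enters the final set when its selected ORF is at least
#' \code{minAa} amino acids long AND it carries at least one evidence tag
#' (a significant match to some proteome or domain database). Also tallies
#' per-source membership and the "core" count of contigs matched in all
#' four proteomes.
#'
#' @param contigs a [ContigSet-class] or named character vector.
#' @param orfs data.frame from [selectedOrfs()].
#' @param evidence named list from [buildEvidenceTable()].
#' @param minAa minimum ORF length.
#' @return list with \code{final} (subset of \code{contigs}),
#'   \code{orfs} (ORF rows of the final contigs), \code{perSource} (named
#'   integer counts) and \code{coreCount} (contigs with all four proteome
#'   tags).
#' @export
selectFinal <- function(contigs, orfs, evidence, minAa = 50L) {
  part <- orfLengthFilter(orfs, minAa)
  withEv <- names(evidence)[lengths(evidence) >= 1L]
  finalIds <- intersect(part$kept, withEv)
  finalIds <- finalIds[finalIds %in% names(contigs)]
  perSource <- vapply(.evidenceVocab, function(tag)
    sum(vapply(finalIds, function(id) tag %in% evidence[[id]], logical(1))),
    integer(1))
  coreCount <- sum(vapply(finalIds, function(id)
    all(.proteomeTags %in% evidence[[id]]), logical(1)))
  list(final = contigs[finalIds],
       orfs = orfs[orfs$contigId %in% finalIds, , drop = FALSE],
       perSource = perSource, coreCount = coreCount)
}

#' N50 of a set of contig lengths
#'
#' The largest length L such that contigs of length >= L together contain
#' at least half of the total assembled bases.
#'
#' @param lengths positive numeric vector of contig lengths.
#' @return the N50 (one of the input lengths).
#' @examples
#' n50(c(4, 3, 3, 2, 2, 2))  # 3
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("'lengths' must be non-empty", call. = FALSE)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}
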