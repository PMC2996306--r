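#' Collapse an EST set to unique sequences
#'
#' Removes exact duplicates and any sequence fully contained in a longer
#' sequence, case-insensitively and on either strand. When two sequences
#' contain each other (equal length duplicates) the lexicographically first
#' id is kept.
#'
#' @param ests named character vector or [Biostrings::DNAStringSet].
#' @return named character vector of surviving sequences, input order
#'   preserved.
#' @export
dedupeEsts <- function(ests) {
  ids <- names(ests)
  if (is.null(ids)) ids <- sprintf("est%d", seq_along(ests))
  seqs <- toupper(as.character(ests))
  ord <- order(-nchar(seqs), ids)
  kept <- character(0); keptIds <- character(0)
  for (i in ord) {
    s <- seqs[i]; rc <- .rc1(s)
    contained <- any(vapply(kept, function(kk)
      grepl(s, kk, fixed = TRUE) || grepl(rc, kk, fixed = TRUE),
      logical(1)))
    if (!contained) { kept <- c(kept, s); keptIds <- c(keptIds, ids[i]) }
  }
  keepMask <- ids %in% keptIds
  setNames(seqs[keepMask], ids[keepMask])
}

#' EST-contig alignment-score prefilter
#'
#' A contig-EST match is credible only when its global alignment score is
#' strictly greater than 50 plus 3 times the length of the shorter of the
#' two sequences. Under the package's nucleotide scale (match +5) a perfect
#' alignment scores 5 per position, so perfect matches longer than 25 nt
#' always pass.
#'
#' @param contig,est sequences (character scalars), used for their lengths.
#' @param aln the contig-EST alignment: a [PairwiseAln-class], or any list
#'   with a \code{score} element. The package aligns contigs to ESTs
#'   ends-free (a contig legitimately extending past the EST edge is not
#'   penalised), so the score reflects the aligned overlap: with match +5
#'   the rule effectively demands a clean overlap covering more than
#'   (50 + 3 L)/5 positions of the shorter sequence.
#' @return \code{TRUE} to keep the match.
#' @export
estPrefilter <- function(contig, est, aln) {
  minLen <- min(nchar(as.character(contig)), nchar(as.character(est)))
  score <- if (is(aln, "PairwiseAln")) aln@rawScore else aln$score
  score > 50 + 3 * minLen
}

#' Within-group normalised-score filter
#'
#' Divides each member's score by the maximum score in the group; members
#' with a normalised score strictly below \code{cutoff} are discarded. The
#' best member (normalised score 1) always survives.
#'
#' @param rawScores numeric vector of scores (one target group).
#' @param cutoff normalised-score cutoff (default 0.7).
#' @return logical vector of survivors.
#' @examples
#' normScoreFilter(c(200, 140, 90))  # TRUE TRUE FALSE
#' @export
normScoreFilter <- function(rawScores, cutoff = 0.7) {
  if (length(rawScores) == 0L) return(logical(0))
  rawScores / max(rawScores) >= cutoff
}

# internal: orient a contig to the target strand given hit strand/frame
.orientSeq <- function(seq, strandOrFrame) {
  minus <- (is.character(strandOrFrame) && strandOrFrame == "-") ||
    (is.numeric(strandOrFrame) && strandOrFrame < 0)
  if (minus) .rc1(seq) else seq
}

# internal: ends-free (overlap) alignment of two same-alphabet strings,
# with coordinates of the aligned cores; end gaps are free, matching the
# clustering use case where a contig legitimately extends past its target
.overlapAln <- function(s1, s2, scheme = nucScheme()) {
  gp <- .bsGap(scheme)
  mk <- if (scheme$type == "nucleotide") Biostrings::DNAString
        else Biostrings::AAString
  pa <- Biostrings::pairwiseAlignment(
    mk(s1), mk(s2), type = "overlap", substitutionMatrix = scheme$matrix,
    gapOpening = gp$opening, gapExtension = gp$extension)
  va <- as.character(Biostrings::alignedPattern(pa))
  vb <- as.character(Biostrings::alignedSubject(pa))
  st <- .alnStats(va, vb)
  list(score = Biostrings::score(pa), normScore = st$normScore,
       pStart = Biostrings::start(Biostrings::pattern(pa)),
       pEnd = Biostrings::end(Biostrings::pattern(pa)),
       sStart = Biostrings::start(Biostrings::subject(pa)),
       sEnd = Biostrings::end(Biostrings::subject(pa)),
       alignedA = va, alignedB = vb)
}

# internal: lengths of contig sequence extending past the target's edges,
# from an overlap alignment (contig = pattern, target = subject)
.overhangs <- function(oa, contigLen, targetLen) {
  c(left = max(0L, (oa$pStart - 1L) - (oa$sStart - 1L)),
    right = max(0L, (contigLen - oa$pEnd) - (targetLen - oa$sEnd)))
}

# internal: empty join-record table
emptyJoins <- function() {
  data.frame(newId = character(0), rule = character(0),
             nGapLen = integer(0), parts = character(0),
             stringsAsFactors = FALSE)
}

#' EST-based target clustering (contig joining around conspecific ESTs)
#'
#' Groups contigs around the EST each one matches, filters matches, and
#' extends each EST with contig sequence overhanging its edges.
#' Per EST group the steps are: (1) discard contig-EST matches whose global
#' alignment fails [estPrefilter()]; (2) discard contigs whose local-search
#' score, normalised by the group maximum, is below 0.7; (3) when more than
#' one contig remains, renormalise the EST-contig global alignment scores
#' within the group and again discard below 0.7; (4) join: the output
#' sequence is (longest left overhang among survivors) + EST + (longest
#' right overhang), and all surviving contigs are consumed. Groups whose
#' surviving contigs match the EST on both strands with equal best scores
#' are left unjoined and logged. Contigs consumed by a join do not proceed
#' to peptide clustering; all other contigs pass through with provenance
#' \code{"unchanged"}.
#'
#' @param contigs a [ContigSet-class] or named character vector.
#' @param ests named character vector or [Biostrings::DNAStringSet] of
#'   conspecific ESTs; deduplicated internally with [dedupeEsts()].
#' @param hits optional pre-computed contig-vs-EST hit table (layout of
#'   [readTabularHits()]); computed with [localSearch()] in nucleotide mode
#'   when NULL.
#' @param cutoff normalised-score cutoff for both filters.
#' @param maxEvalue e-value cutoff for the built-in search.
#' @return a list with \code{contigs} (a [ContigSet-class]: joined products
#'   plus untouched contigs), \code{joins} (join-record table: \code{newId},
#'   \code{rule}, \code{nGapLen}, \code{parts}) and \code{consumed}
#'   (ids of contigs absorbed into joins).
#' @export
estCluster <- function(contigs, ests, hits = NULL, cutoff = 0.7,
                       maxEvalue = 1e-6) {
  ctgSeqs <- toupper(as.character(contigs))
  ctgIds <- names(contigs)
  if (is.null(ctgIds)) stop("contigs must be named", call. = FALSE)
  names(ctgSeqs) <- ctgIds
  estSeqs <- dedupeEsts(ests)
  if (is.null(hits))
    hits <- localSearchAll(ctgSeqs, estSeqs, mode = "n2n",
                           maxEvalue = maxEvalue)
  hits <- hits[hits$evalue <= maxEvalue & hits$targetId %in% names(estSeqs), ,
               drop = FALSE]
  joined <- character(0)
  joins <- list()
  consumed <- character(0)
  for (estId in unique(hits$targetId)) {
    gh <- hits[hits$targetId == estId, , drop = FALSE]
    # best HSP per contig, remembering its orientation
    best <- gh[order(-gh$rawScore), , drop = FALSE]
    ambig <- vapply(unique(best$queryId), function(q) {
      qs <- best[best$queryId == q, , drop = FALSE]
      top <- qs$rawScore == max(qs$rawScore)
      length(unique(qs$tStrand[top])) > 1L
    }, logical(1))
    best <- best[!duplicated(best$queryId), , drop = FALSE]
    est <- estSeqs[[estId]]
    # step 1: ends-free alignment absolute-score prefilter
    alns <- list()
    oriented <- list()
    pass <- logical(nrow(best))
    for (j in seq_len(nrow(best))) {
      cid <- best$queryId[j]
      oriented[[cid]] <- .orientSeq(ctgSeqs[[cid]], best$tStrand[j])
      alns[[cid]] <- .overlapAln(oriented[[cid]], est)
      pass[j] <- estPrefilter(oriented[[cid]], est, alns[[cid]])
    }
    best <- best[pass, , drop = FALSE]
    if (nrow(best) == 0L) next
    # step 2: normalised local-search score filter
    best <- best[normScoreFilter(best$rawScore, cutoff), , drop = FALSE]
    # step 3: renormalised pairwise-alignment score filter (groups > 1)
    if (nrow(best) > 1L) {
      gaScores <- vapply(best$queryId, function(cid) alns[[cid]]$score,
                         numeric(1))
      best <- best[normScoreFilter(gaScores, cutoff), , drop = FALSE]
    }
    if (nrow(best) == 0L) next
    if (any(ambig[best$queryId])) {
      tfLog("estCluster: group ", estId,
            " has a contig matching on both strands; left unjoined")
      next
    }
    # step 4: join overhangs to the EST
    left <- ""; right <- ""
    for (j in seq_len(nrow(best))) {
      cid <- best$queryId[j]
      oa <- alns[[cid]]
      ov <- .overhangs(oa, nchar(oriented[[cid]]), nchar(est))
      if (ov["left"] > nchar(left))
        left <- substr(oriented[[cid]], 1L, ov["left"])
      if (ov["right"] > nchar(right))
        right <- substring(oriented[[cid]],
                           nchar(oriented[[cid]]) - ov["right"] + 1L)
    }
    newId <- paste0("estj_", estId)
    joined[newId] <- paste0(left, est, right)
    joins[[newId]] <- data.frame(
      newId = newId, rule = "est_extend", nGapLen = 0L,
      parts = paste(c(estId, best$queryId), collapse = ","),
      stringsAsFactors = FALSE)
    consumed <- c(consumed, best$queryId)
  }
  untouched <- setdiff(ctgIds, consumed)
  outSeqs <- c(joined, ctgSeqs[untouched])
  out <- ContigSet(outSeqs,
                   provenance = c(rep("est_joined", length(joined)),
                                  rep("unchanged", length(untouched))),
                   sourceIds = c(vapply(joins, function(j) j$parts,
                                        character(1)),
                                 untouched))
  list(contigs = out,
       joins = if (length(joins)) do.call(rbind, joins) else emptyJoins(),
       consumed = unique(consumed))
}

# internal: merge two overlapping oriented sequences using an ends-free
# alignment; disagreeing columns take the base of the higher-scoring contig
# (ties: first by id, logged)
.mergeOverlap <- function(s1, s2, id1, id2, score1, score2) {
  oa <- .overlapAln(s1, s2)
  a <- strsplit(oa$alignedA, "", fixed = TRUE)[[1]]
  b <- strsplit(oa$alignedB, "", fixed = TRUE)[[1]]
  firstWins <- score1 > score2 || (score1 == score2 && id1 <= id2)
  if (score1 == score2)
    tfLog("mergeOverlap: equal scores for ", id1, " and ", id2,
          "; taking bases from ", if (firstWins) id1 else id2)
  cons <- ifelse(a == "-", b, ifelse(b == "-", a,
                 ifelse(a == b, a, if (firstWins) a else b)))
  core <- paste(cons, collapse = "")
  # stitch the unaligned ends back on (ends-free alignment clips them)
  leftTail <- if (oa$pStart - 1L >= oa$sStart - 1L)
    substr(s1, 1L, oa$pStart - 1L) else substr(s2, 1L, oa$sStart - 1L)
  r1 <- nchar(s1) - oa$pEnd; r2 <- nchar(s2) - oa$sEnd
  rightTail <- if (r1 >= r2) substring(s1, oa$pEnd + 1L)
               else substring(s2, oa$sEnd + 1L)
  list(seq = paste0(leftTail, core, rightTail), normScore = oa$normScore)
}

# internal: N-run length from peptide HSP coordinates: 3 nt per missing
# residue between the two HSPs; floor of 1 N when they abut or overlap
.nGapFromHsps <- function(tEnd1, tStart2) {
  max(1L, 3L * (tStart2 - tEnd1 - 1L))
}

#' Peptide-based target clustering
#'
#' The analogue of [estCluster()] against a heterospecific predicted
#' peptide set, applied to the contigs not consumed by EST clustering.
#' Contigs are matched to peptides by translated search, assigned to their
#' best-matching peptide, and filtered within each peptide group by
#' normalised score (cutoff 0.7). Groups of exactly two surviving contigs
#' are merged when their ends-free alignment has a normalised score
#' strictly greater than 90; when their peptide HSPs do not overlap they
#' are instead scaffolded with a run of Ns, 3 per missing residue between
#' the HSPs (minimum 1). In groups of three or more, all pairs are globally
#' aligned, pairs scoring strictly above 80 are marked joinable, and
#' transitively connected contigs are merged in peptide-coordinate order.
#' Groups whose surviving contigs translate on inconsistent strands are
#' logged and left unjoined.
#'
#' @param contigs a [ContigSet-class] or named character vector (the
#'   contigs left unjoined by EST clustering).
#' @param peptides named character vector or [Biostrings::AAStringSet] of
#'   predicted peptides.
#' @param hits optional contig-vs-peptide translated hit table; computed
#'   with [localSearch()] mode \code{"x"} when NULL.
#' @param cutoff normalised local-search score cutoff.
#' @param pairScoreMin minimum pairwise normalised alignment score for
#'   joining within groups of 3+ (strictly greater).
#' @param overlapScoreMin minimum ends-free normalised alignment score for
#'   merging a 2-contig group (strictly greater).
#' @param maxEvalue e-value cutoff for the built-in search.
#' @return same shape as [estCluster()]: \code{contigs}, \code{joins},
#'   \code{consumed}.
#' @export
peptideCluster <- function(contigs, peptides, hits = NULL, cutoff = 0.7,
                           pairScoreMin = 80, overlapScoreMin = 90,
                           maxEvalue = 1e-6) {
  ctgSeqs <- toupper(as.character(contigs))
  ctgIds <- names(contigs)
  if (is.null(ctgIds)) stop("contigs must be named", call. = FALSE)
  names(ctgSeqs) <- ctgIds
  pepSeqs <- toupper(as.character(peptides))
  names(pepSeqs) <- names(peptides)
  if (is.null(hits))
    hits <- localSearchAll(ctgSeqs, pepSeqs, mode = "x",
                           maxEvalue = maxEvalue)
  hits <- hits[hits$evalue <= maxEvalue, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(list(contigs = ContigSet(ctgSeqs, provenance = "unchanged"),
                joins = emptyJoins(), consumed = character(0)))
  }
  # each contig belongs to the group of its best-scoring peptide
  ho <- hits[order(hits$queryId, -hits$rawScore, hits$targetId), ,
             drop = FALSE]
  bestPerContig <- ho[!duplicated(ho$queryId), , drop = FALSE]
  joined <- character(0); prov <- character(0)
  joins <- list(); consumed <- character(0)
  for (pepId in unique(bestPerContig$targetId)) {
    g <- bestPerContig[bestPerContig$targetId == pepId, , drop = FALSE]
    g <- g[normScoreFilter(g$rawScore, cutoff), , drop = FALSE]
    if (nrow(g) < 2L) next
    g <- g[order(g$tStart, g$queryId), , drop = FALSE]
    oriented <- setNames(
      vapply(seq_len(nrow(g)), function(j)
        .orientSeq(ctgSeqs[[g$queryId[j]]], g$frame[j]), character(1)),
      g$queryId)
    if (nrow(g) == 2L) {
      overlapHsp <- g$tStart[2] <= g$tEnd[1]
      if (overlapHsp) {
        mg <- .mergeOverlap(oriented[[1]], oriented[[2]],
                            g$queryId[1], g$queryId[2],
                            g$rawScore[1], g$rawScore[2])
        if (mg$normScore > overlapScoreMin) {
          newId <- paste0("pepj_", pepId)
          joined[newId] <- mg$seq
          prov[newId] <- "peptide_joined"
          joins[[newId]] <- data.frame(
            newId = newId, rule = "pep_overlap_merge", nGapLen = 0L,
            parts = paste(g$queryId, collapse = ","),
            stringsAsFactors = FALSE)
          consumed <- c(consumed, g$queryId)
        }
      } else {
        nGap <- .nGapFromHsps(g$tEnd[1], g$tStart[2])
        newId <- paste0("pepj_", pepId)
        joined[newId] <- paste0(oriented[[1]], strrep("N", nGap),
                                oriented[[2]])
        prov[newId] <- "n_scaffolded"
        joins[[newId]] <- data.frame(
          newId = newId, rule = "pep_n_scaffold", nGapLen = nGap,
          parts = paste(g$queryId, collapse = ","),
          stringsAsFactors = FALSE)
        consumed <- c(consumed, g$queryId)
      }
    } else {
      n <- nrow(g)
      parent <- seq_len(n)
      findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      pairScore <- matrix(NA_real_, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        aln <- globalAlign(setNames(oriented[[i]], g$queryId[i]),
                           setNames(oriented[[j]], g$queryId[j]))
        pairScore[i, j] <- aln@normScore
        if (aln@normScore > pairScoreMin) {
          ri <- findRoot(i); rj <- findRoot(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
      roots <- vapply(seq_len(n), findRoot, integer(1))
      for (r in unique(roots)) {
        members <- which(roots == r)
        if (length(members) < 2L) next
        cur <- oriented[[members[1]]]
        curScore <- g$rawScore[members[1]]
        curId <- g$queryId[members[1]]
        for (mIdx in members[-1L]) {
          mg <- .mergeOverlap(cur, oriented[[mIdx]], curId,
                              g$queryId[mIdx], curScore, g$rawScore[mIdx])
          cur <- mg$seq
          curScore <- max(curScore, g$rawScore[mIdx])
        }
        newId <- paste0("pepj_", pepId, "_", r)
        joined[newId] <- cur
        prov[newId] <- "peptide_joined"
        joins[[newId]] <- data.frame(
          newId = newId, rule = "pep_overlap_merge", nGapLen = 0L,
          parts = paste(g$queryId[members], collapse = ","),
          stringsAsFactors = FALSE)
        consumed <- c(consumed, g$queryId[members])
      }
    }
  }
  untouched <- setdiff(ctgIds, consumed)
  outSeqs <- c(joined, ctgSeqs[untouched])
  out <- ContigSet(outSeqs,
                   provenance = c(unname(prov),
                                  rep("unchanged", length(untouched))),
                   sourceIds = c(vapply(joins, function(j) j$parts,
                                        character(1)),
                                 untouched))
  list(contigs = out,
       joins = if (length(joins)) do.call(rbind, joins) else emptyJoins(),
       consumed = unique(consumed))
}
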