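# Synthetic-data generators with full ground truth.
#
# Every input the pipeline consumes can be generated here: coding
# transcripts and their proteins, diverged orthologous peptide sets,
# transcript fragments (clustering ground truth), paired reads with
# sequencing errors and planted biallelic sites, pileups (either
# aggregated from reads or simulated directly per site), expression
# counts, and block-structured category annotations. All generators are
# pure functions of their arguments including the seed.

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")
.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

#' Simulate a coding transcriptome
#'
#' Random CDS transcripts: ATG, interior codons drawn uniformly from the
#' 61 sense codons, and one stop codon; lengths are multiples of 3 drawn
#' uniformly from \code{lenRange}. Base composition is therefore
#' near-uniform (excluding the AT-rich stop codons raises expected GC to
#' 94/183, about 0.514). Proteins are the frame +1 translations without
#' the stop.
#'
#' @param n number of transcripts.
#' @param lenRange nucleotide length range (values rounded to multiples
#'   of 3).
#' @param seed RNG seed.
#' @return list with named character vectors \code{transcripts}
#'   (\code{tx0001}, ...) and \code{proteins} (same names).
#' @export
simTranscriptome <- function(n = 20L, lenRange = c(300L, 1500L), seed = 1L) {
  set.seed(seed)
  sense <- setdiff(apply(expand.grid(.BASES, .BASES, .BASES), 1, paste,
                         collapse = ""), .STOPS)
  lens <- 3L * sample(seq(ceiling(lenRange[1] / 3), floor(lenRange[2] / 3)),
                      n, replace = TRUE)
  tx <- vapply(lens, function(L) {
    m <- L / 3L
    paste0("ATG", paste(sample(sense, m - 2L, replace = TRUE),
                        collapse = ""), sample(.STOPS, 1L))
  }, character(1))
  names(tx) <- sprintf("tx%04d", seq_len(n))
  prots <- vapply(tx, function(s) {
    p <- sixFrameTranslate(s)[["F1"]]
    sub("\\*$", "", p)
  }, character(1))
  list(transcripts = tx, proteins = prots)
}

#' Simulate a diverged orthologous peptide set
#'
#' Substitutes each residue independently with probability \code{d} (per
#' family when \code{d} is a named vector parallel to \code{proteins}) to
#' a uniformly chosen different residue, emulating the proteome of a
#' related species; the true 1:1 pairing is returned as ground truth.
#'
#' @param proteins named character vector of reference proteins.
#' @param d substitution probability per site, scalar or per-protein
#'   vector in [0, 0.5].
#' @param seed RNG seed.
#' @return list with \code{peptides} (named \code{ref_<id>}) and
#'   \code{truth} (data.frame \code{contigFamily}, \code{peptideId},
#'   \code{d}).
#' @export
simOrthologs <- function(proteins, d = 0.102, seed = 1L) {
  set.seed(seed)
  d <- rep_len(d, length(proteins))
  peps <- vapply(seq_along(proteins), function(i) {
    aa <- strsplit(proteins[[i]], "", fixed = TRUE)[[1]]
    hit <- runif(length(aa)) < d[i]
    aa[hit] <- vapply(aa[hit], function(x)
      sample(setdiff(.AA20, x), 1L), character(1))
    paste(aa, collapse = "")
  }, character(1))
  ids <- paste0("ref_", names(proteins))
  names(peps) <- ids
  list(peptides = peps,
       truth = data.frame(contigFamily = names(proteins), peptideId = ids,
                          d = d, stringsAsFactors = FALSE))
}

#' Split transcripts into fragments
#'
#' Cuts each transcript into two pieces around its midpoint, either
#' overlapping by \code{overlap} nt or separated by a \code{gap}; the
#' fragment-to-transcript map is the clustering ground truth.
#'
#' @param transcripts named character vector.
#' @param mode \code{"overlap"} or \code{"gap"}.
#' @param overlap,gap sizes in nt.
#' @return list with \code{fragments} (named \code{<id>_f1},
#'   \code{<id>_f2}) and \code{truth} (data.frame \code{fragment},
#'   \code{transcript}, \code{start}, \code{end}; 1-based inclusive).
#' @export
simFragments <- function(transcripts, mode = c("overlap", "gap"),
                         overlap = 60L, gap = 50L) {
  mode <- match.arg(mode)
  frags <- character(0)
  truth <- list()
  for (id in names(transcripts)) {
    s <- transcripts[[id]]
    L <- nchar(s)
    mid <- L %/% 2L
    if (mode == "overlap") {
      e1 <- min(L, mid + ceiling(overlap / 2)); s2 <- max(1L, e1 - overlap + 1L)
    } else {
      e1 <- max(1L, mid - ceiling(gap / 2)); s2 <- min(L, e1 + gap + 1L)
    }
    f1 <- paste0(id, "_f1"); f2 <- paste0(id, "_f2")
    frags[f1] <- substr(s, 1L, e1)
    frags[f2] <- substring(s, s2)
    truth[[f1]] <- data.frame(fragment = f1, transcript = id, start = 1L,
                              end = e1, stringsAsFactors = FALSE)
    truth[[f2]] <- data.frame(fragment = f2, transcript = id, start = s2,
                              end = L, stringsAsFactors = FALSE)
  }
  list(fragments = frags, truth = do.call(rbind, unname(truth)))
}

# internal: plant biallelic sites on a transcript set
.plantSnds <- function(transcripts, plantedPi) {
  out <- list()
  for (id in names(transcripts)) {
    s <- transcripts[[id]]
    L <- nchar(s)
    pos <- which(runif(L) < plantedPi)
    if (length(pos) == 0L) next
    ref <- substring(s, pos, pos)
    alt <- vapply(ref, function(b) sample(setdiff(.BASES, b), 1L),
                  character(1))
    out[[id]] <- data.frame(contig = id, pos = pos, ref = ref, alt = alt,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, unname(out))
}

# internal: apply per-base errors to a vector of read char vectors
.applyErrors <- function(chars, errorRate) {
  if (errorRate <= 0) return(chars)
  hit <- which(runif(length(chars)) < errorRate)
  if (length(hit))
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(.BASES, b), 1L), character(1))
  chars
}

#' Simulate paired-end reads from transcripts
#'
#' Draws read pairs from each transcript at the requested depth, plants
#' biallelic sites (pool frequency 0.5: each fragment carries the
#' alternative allele of a planted site with probability 1/2, both mates
#' consistently) and applies uniform per-base sequencing errors.
#'
#' Tiling \code{"uniform"} draws fragment starts uniformly at random, as
#' in shotgun sequencing. Tiling \code{"even"} places fragments of insert
#' length \code{readLen} on an even grid that always includes both
#' transcript termini; with both mates covering the fragment (one per
#' strand) every position, including the ends, receives at least two
#' observations, which isolates assembler behaviour from stochastic
#' end-coverage dropout.
#'
#' @param transcripts named character vector.
#' @param depth mean per-base coverage.
#' @param readLen read length in nt.
#' @param errorRate per-base sequencing error probability.
#' @param plantedPi probability that a position is a planted biallelic
#'   site.
#' @param tiling \code{"uniform"} or \code{"even"}.
#' @param seed RNG seed.
#' @return list with \code{r1}, \code{r2}
#'   ([Biostrings::QualityScaledDNAStringSet], all qualities Q40),
#'   \code{alignments} (data.frame \code{read}, \code{contig},
#'   \code{start}, \code{end}, \code{strand}, \code{seq}: the true origin
#'   of every read, as sequenced) and \code{snd} (planted-site table).
#' @export
simReads <- function(transcripts, depth = 30, readLen = 75L,
                     errorRate = 0.001, plantedPi = 0.02,
                     tiling = c("uniform", "even"), seed = 1L) {
  tiling <- match.arg(tiling)
  set.seed(seed)
  snd <- .plantSnds(transcripts, plantedPi)
  r1 <- character(0); r2 <- character(0)
  aln <- list()
  for (id in names(transcripts)) {
    s <- transcripts[[id]]
    L <- nchar(s)
    if (L < readLen) next
    insert <- if (tiling == "even") readLen else min(L, 2L * readLen)
    nPairs <- max(1L, ceiling(L * depth / (2 * readLen)))
    maxStart <- L - insert + 1L
    starts <- if (tiling == "even")
      unique(round(seq(1L, maxStart, length.out = nPairs)))
    else sample.int(maxStart, nPairs, replace = TRUE)
    txSnd <- snd[snd$contig == id, , drop = FALSE]
    for (p in seq_along(starts)) {
      st <- starts[p]; en <- st + insert - 1L
      frag <- strsplit(substr(s, st, en), "", fixed = TRUE)[[1]]
      # fragment haplotype: each planted site alt with probability 1/2
      inFrag <- which(txSnd$pos >= st & txSnd$pos <= en)
      for (k in inFrag) {
        if (runif(1) < 0.5) frag[txSnd$pos[k] - st + 1L] <- txSnd$alt[k]
      }
      m1 <- .applyErrors(frag[1:readLen], errorRate)
      m2chars <- paste(frag[(insert - readLen + 1L):insert], collapse = "")
      m2 <- .applyErrors(strsplit(.rc1(m2chars), "", fixed = TRUE)[[1]],
                         errorRate)
      rid <- sprintf("%s_p%05d", id, p)
      r1[paste0(rid, "/1")] <- paste(m1, collapse = "")
      r2[paste0(rid, "/2")] <- paste(m2, collapse = "")
      aln[[length(aln) + 1L]] <- data.frame(
        read = c(paste0(rid, "/1"), paste0(rid, "/2")),
        contig = id,
        start = c(st, en - readLen + 1L),
        end = c(st + readLen - 1L, en),
        strand = c("+", "-"),
        seq = c(paste(m1, collapse = ""), paste(m2, collapse = "")),
        stringsAsFactors = FALSE)
    }
  }
  list(r1 = makeReads(r1), r2 = makeReads(r2),
       alignments = do.call(rbind, aln), snd = snd)
}

#' Aggregate simulated reads into a pileup table
#'
#' Uses the true read placements from [simReads()] (no mapping step) to
#' build per-position base counts against the transcript references.
#'
#' @param transcripts named character vector of reference sequences.
#' @param alignments the \code{alignments} table from [simReads()].
#' @return a pileup table in the layout of [readPileup()] (every reference
#'   position present, no indels).
#' @export
buildPileup <- function(transcripts, alignments) {
  out <- list()
  for (id in names(transcripts)) {
    s <- transcripts[[id]]
    L <- nchar(s)
    counts <- matrix(0L, nrow = 5L, ncol = L,
                     dimnames = list(c(.BASES, "N"), NULL))
    al <- alignments[alignments$contig == id, , drop = FALSE]
    for (i in seq_len(nrow(al))) {
      chars <- strsplit(if (al$strand[i] == "+") al$seq[i]
                        else .rc1(al$seq[i]), "", fixed = TRUE)[[1]]
      posn <- al$start[i]:al$end[i]
      bi <- match(chars, rownames(counts))
      counts[cbind(bi, posn)] <- counts[cbind(bi, posn)] + 1L
    }
    out[[id]] <- data.frame(
      contig = id, pos = seq_len(L),
      ref = strsplit(s, "", fixed = TRUE)[[1]],
      depth = as.integer(colSums(counts)),
      A = counts["A", ], C = counts["C", ], G = counts["G", ],
      T = counts["T", ], N = counts["N", ], indels = "",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}

#' Simulate pileups site by site
#'
#' Direct per-site simulation of a read pool with planted heterozygosity:
#' each position is biallelic with probability \code{pi0}; at biallelic
#' sites the alternative-allele count is Binomial(depth, 0.5), matching a
#' pool in which the two alleles segregate at equal frequency. Sequencing
#' errors add singleton-scale noise at rate \code{errorRate} per base.
#' This is the generator of choice for large-scale diversity calibration,
#' where aggregating individual reads would be needlessly slow.
#'
#' @param nContigs,len number and length (bp) of simulated contigs.
#' @param depth uniform read depth.
#' @param pi0 planted per-site heterozygosity.
#' @param errorRate per-base sequencing error probability.
#' @param seed RNG seed.
#' @return list with \code{sites} (pileup table, contigs \code{sim0001},
#'   ...) and \code{truth} (data.frame \code{contig}, \code{pos} of
#'   planted sites).
#' @export
simPileupSites <- function(nContigs = 1000L, len = 1000L, depth = 10L,
                           pi0 = 0.01, errorRate = 0, seed = 1L) {
  set.seed(seed)
  n <- nContigs * len
  contig <- rep(sprintf("sim%04d", seq_len(nContigs)), each = len)
  pos <- rep(seq_len(len), times = nContigs)
  refIdx <- sample.int(4L, n, replace = TRUE)
  poly <- runif(n) < pi0
  altCount <- integer(n)
  altCount[poly] <- rbinom(sum(poly), depth, 0.5)
  altIdx <- ((refIdx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
  errCount <- if (errorRate > 0) rbinom(n, depth - altCount, errorRate)
              else integer(n)
  errIdx <- ((refIdx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
  counts <- matrix(0L, nrow = n, ncol = 4L,
                   dimnames = list(NULL, .BASES))
  counts[cbind(seq_len(n), refIdx)] <- depth - altCount - errCount
  counts[cbind(seq_len(n), altIdx)] <-
    counts[cbind(seq_len(n), altIdx)] + altCount
  counts[cbind(seq_len(n), errIdx)] <-
    counts[cbind(seq_len(n), errIdx)] + errCount
  sites <- data.frame(contig = contig, pos = pos, ref = .BASES[refIdx],
                      depth = as.integer(depth), A = counts[, "A"],
                      C = counts[, "C"], G = counts[, "G"],
                      T = counts[, "T"], N = 0L, indels = "",
                      stringsAsFactors = FALSE)
  list(sites = sites,
       truth = data.frame(contig = contig[poly], pos = pos[poly],
                          stringsAsFactors = FALSE))
}

#' Simulate per-contig expression counts
#'
#' Log-normal expression levels, multinomial read assignment.
#'
#' @param ids contig ids.
#' @param totalReads total mapped reads to distribute.
#' @param sdLog spread of log-expression.
#' @param seed RNG seed.
#' @return named integer vector of counts.
#' @export
simCounts <- function(ids, totalReads = 1e6, sdLog = 1.5, seed = 1L) {
  set.seed(seed)
  lambda <- exp(stats::rnorm(length(ids), sd = sdLog))
  setNames(as.integer(rmultinom(1, totalReads, lambda / sum(lambda))),
           ids)
}

#' Block-structured category annotations
#'
#' Splits the ids into \code{nCategories} consecutive blocks and labels
#' each block with one category; the first block is additionally tagged
#' \code{"immune_like"}, so elevating that block's divergence (via the
#' per-family \code{d} of [simOrthologs()]) produces a category with a
#' known enrichment signal.
#'
#' @param ids character vector of contig/family ids.
#' @param nCategories number of blocks.
#' @return list with \code{categories} (named list id -> character vector
#'   of labels) and \code{immune} (ids of the immune-like block).
#' @export
simCategories <- function(ids, nCategories = 10L) {
  block <- cut(seq_along(ids), breaks = nCategories, labels = FALSE)
  labels <- sprintf("cat%02d", block)
  cats <- lapply(seq_along(ids), function(i) {
    if (block[i] == 1L) c(labels[i], "immune_like") else labels[i]
  })
  names(cats) <- ids
  list(categories = cats, immune = ids[block == 1L])
}
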