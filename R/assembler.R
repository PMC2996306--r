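#' Build a de Bruijn graph from reads or contigs
#'
#' Counts canonical k-mers (lexicographic minimum of each k-mer and its
#' reverse complement) across the input sequences, drops k-mers containing
#' N and k-mers seen fewer than \code{minKmerCoverage} times, and returns
#' the node-centric graph. Edges are implicit (k-1)-overlaps.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet],
#'   [Biostrings::DNAStringSet] or character vector of sequences.
#' @param k odd hash length (>= 15).
#' @param minKmerCoverage minimum multiplicity for a k-mer to enter the
#'   graph; 2 suppresses most isolated sequencing-error k-mers at the read
#'   stage, 1 is appropriate when the inputs are contigs (each contig is a
#'   single observation).
#' @return a [DeBruijnGraph-class].
#' @examples
#' g <- buildGraph(c(strrep("ACGTA", 10), strrep("ACGTA", 10)), k = 15)
#' g
#' @export
buildGraph <- function(reads, k, minKmerCoverage = 2L) {
  k <- stopifnotScalarInt(k, "k", min = 15L)
  if (k %% 2L == 0L) stop("'k' must be odd", call. = FALSE)
  seqs <- if (is.character(reads)) toupper(reads) else as.character(reads)
  seqs <- seqs[nchar(seqs) >= k]
  kmers <- unlist(lapply(seqs, seqKmers, k = k), use.names = FALSE)
  if (length(kmers)) {
    kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
    kmers <- canonicalKmers(kmers)
  }
  if (length(kmers) == 0L)
    return(new("DeBruijnGraph", k = k, coverage = integer(0)))
  r <- rle(sort(kmers))
  keep <- r$lengths >= minKmerCoverage
  new("DeBruijnGraph", k = k,
      coverage = setNames(as.integer(r$lengths[keep]), r$values[keep]))
}

# internal: scalar reverse complement without DNAStringSet overhead
.rc1 <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Extract unitigs from a de Bruijn graph
#'
#' Spells every maximal non-branching path of the bidirected graph to a
#' sequence. Each canonical k-mer is consumed by exactly one unitig; a walk
#' only crosses an edge u -> v when u has a unique successor and v a unique
#' predecessor. Unitigs are reported in canonical orientation (lexicographic
#' minimum of sequence and reverse complement) and sorted lexicographically,
#' so the output is deterministic for a given graph.
#'
#' @param graph a [DeBruijnGraph-class].
#' @return a [ContigSet-class] with provenance \code{"assembled"}; metadata
#'   column \code{meanKmerCoverage} carries the mean multiplicity of the
#'   constituent k-mers.
#' @export
extractUnitigs <- function(graph) {
  k <- graph@k
  cov <- graph@coverage
  if (length(cov) == 0L) return(ContigSet(Biostrings::DNAStringSet()))
  canon <- names(cov)
  # map both orientations of every node to its canonical string
  orient <- new.env(hash = TRUE, size = 2L * length(canon))
  rcCanon <- revCompFast(canon)
  for (i in seq_along(canon)) {
    assign(canon[i], canon[i], envir = orient)
    assign(rcCanon[i], canon[i], envir = orient)
  }
  visited <- new.env(hash = TRUE, size = length(canon))
  bases <- c("A", "C", "G", "T")
  neighbors <- function(x, forward) {
    cand <- if (forward) paste0(substring(x, 2L), bases)
            else paste0(bases, substring(x, 1L, k - 1L))
    cand[vapply(cand, function(t) !is.null(orient[[t]]), logical(1))]
  }
  unitigs <- character(0)
  meanCov <- numeric(0)
  for (c0 in canon) {
    if (!is.null(visited[[c0]])) next
    assign(c0, TRUE, envir = visited)
    path <- c0
    for (dir in c(TRUE, FALSE)) {       # extend right, then left
      cur <- if (dir) path[length(path)] else path[1L]
      repeat {
        nb <- neighbors(cur, forward = dir)
        if (length(nb) != 1L) break
        nxt <- nb
        cn <- orient[[nxt]]
        if (!is.null(visited[[cn]])) break
        if (length(neighbors(nxt, forward = !dir)) != 1L) break
        assign(cn, TRUE, envir = visited)
        path <- if (dir) c(path, nxt) else c(nxt, path)
        cur <- nxt
      }
    }
    seq <- paste0(path[1L],
                  paste(substring(path[-1L], k, k), collapse = ""))
    rc <- .rc1(seq)
    unitigs <- c(unitigs, if (seq <= rc) seq else rc)
    meanCov <- c(meanCov,
                 mean(cov[vapply(path, function(p) orient[[p]], character(1))]))
  }
  ord <- order(unitigs)
  out <- ContigSet(setNames(unitigs[ord],
                            sprintf("utg%05d", seq_along(unitigs))))
  S4Vectors::mcols(out)$meanKmerCoverage <- meanCov[ord]
  out
}

# internal: one complete single-k assembly (graph + unitigs)
assembleOnce <- function(seqs, k, minKmerCoverage) {
  extractUnitigs(buildGraph(seqs, k, minKmerCoverage))
}

#' Reads not represented in an assembly
#'
#' Returns the indices of reads none of whose (N-free) k-mers occur in any
#' contig: the "unused" reads of that assembly, candidates for rescue in a
#' dedicated re-assembly. Reads shorter than k, which contribute no k-mer,
#' are unused by definition.
#'
#' @param reads read set (see [buildGraph()] for accepted types).
#' @param contigs a [ContigSet-class] or character vector of contig
#'   sequences.
#' @param k k-mer length used for the containment test (normally the k of
#'   the assembly that produced \code{contigs}).
#' @return integer vector of read indices.
#' @export
assignUnusedReads <- function(reads, contigs, k) {
  k <- stopifnotScalarInt(k, "k", min = 15L)
  readSeqs <- if (is.character(reads)) toupper(reads) else as.character(reads)
  ctgSeqs <- if (is.character(contigs)) toupper(contigs) else as.character(contigs)
  ckmers <- unlist(lapply(ctgSeqs, seqKmers, k = k), use.names = FALSE)
  if (length(ckmers)) {
    ckmers <- unique(canonicalKmers(ckmers[!grepl("N", ckmers, fixed = TRUE)]))
  }
  if (length(ckmers) == 0L) return(seq_along(readSeqs))
  inGraph <- new.env(hash = TRUE, size = length(ckmers))
  for (km in ckmers) assign(km, TRUE, envir = inGraph)
  which(vapply(readSeqs, function(s) {
    rk <- seqKmers(s, k)
    rk <- rk[!grepl("N", rk, fixed = TRUE)]
    if (length(rk) == 0L) return(TRUE)
    !any(vapply(canonicalKmers(rk),
                function(x) !is.null(inGraph[[x]]), logical(1)))
  }, logical(1), USE.NAMES = FALSE))
}

#' Iterative multi-k assembly
#'
#' The "assembly of assemblies" strategy for coverage-heterogeneous RNA-seq
#' data: (1) independent exploratory unitig assemblies of the reads at each
#' hash length in the plan (different transcripts assemble best at
#' different k, depending on their coverage); (2) an assembly of all reads
#' left unused by a subset of the exploratory runs; (3) summary assemblies
#' that k-merise every contig produced so far, treating each contig as a
#' single observation; and (4) a final summary assembly of the summary
#' contigs, whose unitigs are returned. Sequences shorter than a stage's k
#' are skipped at that stage with a logged warning.
#'
#' The procedure is deterministic: it contains no stochastic step, and
#' unitig extraction orders its output lexicographically.
#'
#' @param reads the QC-passed read set (see [buildGraph()] for accepted
#'   types).
#' @param plan an [AssemblyPlan-class]; the default mirrors the package's
#'   standard plan (see [defaultAssemblyPlan()]).
#' @param verbose log per-stage contig counts to stderr.
#' @return a [ContigSet-class] of final contigs (provenance
#'   \code{"assembled"}), named \code{ctg00001} onward in lexicographic
#'   sequence order.
#' @seealso [assemblyStats()]
#' @export
iterativeAssemble <- function(reads, plan = defaultAssemblyPlan(),
                              verbose = FALSE) {
  methods::validObject(plan)
  readSeqs <- if (is.character(reads)) toupper(reads) else as.character(reads)
  nshort <- sum(nchar(readSeqs) < min(plan@exploratoryK))
  if (nshort > 0L)
    tfLog("iterativeAssemble: ", nshort,
          " reads shorter than the smallest exploratory k are skipped there")
  exploratory <- lapply(plan@exploratoryK, function(k) {
    ctg <- assembleOnce(readSeqs, k, plan@minKmerCoverage)
    if (verbose) tfLog("exploratory k=", k, ": ", length(ctg), " contigs")
    ctg
  })
  names(exploratory) <- as.character(plan@exploratoryK)
  unusedIdx <- integer(0)
  for (k in plan@unusedFromK) {
    idx <- assignUnusedReads(readSeqs, exploratory[[as.character(k)]], k)
    unusedIdx <- union(unusedIdx, idx)
  }
  unusedCtg <- if (length(unusedIdx)) {
    assembleOnce(readSeqs[sort(unusedIdx)], plan@unusedReadK,
                 plan@minKmerCoverage)
  } else ContigSet(Biostrings::DNAStringSet())
  if (verbose) tfLog("unused-read assembly k=", plan@unusedReadK, ": ",
                     length(unusedCtg), " contigs from ",
                     length(unusedIdx), " reads")
  pool <- c(unlist(lapply(exploratory, as.character), use.names = FALSE),
            as.character(unusedCtg))
  summaries <- lapply(plan@summaryK, function(k) {
    short <- sum(nchar(pool) < k)
    if (short > 0L)
      tfLog("summary k=", k, ": skipping ", short, " contigs shorter than k")
    ctg <- assembleOnce(pool, k, plan@summaryKmerCoverage)
    if (verbose) tfLog("summary k=", k, ": ", length(ctg), " contigs")
    ctg
  })
  finalPool <- unlist(lapply(summaries, as.character), use.names = FALSE)
  final <- assembleOnce(finalPool, plan@finalK, plan@summaryKmerCoverage)
  if (verbose) tfLog("final k=", plan@finalK, ": ", length(final), " contigs")
  if (length(final))
    names(final) <- sprintf("ctg%05d", seq_along(final))
  final
}

#' Contig length summary
#'
#' @param contigs a [ContigSet-class], [Biostrings::DNAStringSet] or
#'   numeric vector of lengths.
#' @return one-row data.frame with \code{n}, \code{totalBp}, \code{meanLen},
#'   \code{maxLen} and \code{n50}.
#' @export
assemblyStats <- function(contigs) {
  lens <- if (is.numeric(contigs)) contigs else Biostrings::width(contigs)
  if (length(lens) == 0L)
    return(data.frame(n = 0L, totalBp = 0L, meanLen = NA_real_,
                      maxLen = NA_integer_, n50 = NA_integer_))
  data.frame(n = length(lens), totalBp = sum(lens), meanLen = mean(lens),
             maxLen = max(lens), n50 = n50(lens))
}
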