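#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Multi-k assembly plan
#'
#' Describes one run of the iterative "assembly of assemblies" strategy:
#' a set of exploratory single-k assemblies over the reads, one assembly of
#' reads left unused by a chosen subset of the exploratory runs, a series of
#' summary assemblies that re-assemble all contigs produced so far, and a
#' final summary assembly whose unitigs are the reported contigs.
#'
#' All hash lengths must be odd (canonical k-mers of odd length cannot be
#' their own reverse complement, which keeps the bidirected de Bruijn graph
#' unambiguous).
#'
#' @slot exploratoryK odd integer vector, hash lengths of the exploratory
#'   read assemblies.
#' @slot unusedReadK odd integer, hash length of the unused-reads assembly.
#' @slot unusedFromK subset of \code{exploratoryK} whose unused reads feed
#'   the unused-reads assembly.
#' @slot summaryK odd integer vector, hash lengths of the summary
#'   (contigs-as-reads) assemblies.
#' @slot finalK odd integer, hash length of the final summary assembly.
#' @slot minKmerCoverage integer, minimum k-mer multiplicity retained in the
#'   read-stage graphs (exploratory and unused-reads assemblies).
#' @slot summaryKmerCoverage integer, minimum k-mer multiplicity at the
#'   summary stages; kept at 1 because each input contig is a single
#'   observation and a higher cutoff would delete uniquely assembled contigs.
#' @seealso [defaultAssemblyPlan()], [iterativeAssemble()]
#' @export
setClass("AssemblyPlan",
  representation(
    exploratoryK = "integer",
    unusedReadK = "integer",
    unusedFromK = "integer",
    summaryK = "integer",
    finalK = "integer",
    minKmerCoverage = "integer",
    summaryKmerCoverage = "integer"
  )
)

setValidity("AssemblyPlan", function(object) {
  ks <- c(object@exploratoryK, object@unusedReadK, object@unusedFromK,
          object@summaryK, object@finalK)
  if (length(object@exploratoryK) == 0L) return("exploratoryK must be non-empty")
  if (length(object@summaryK) == 0L) return("summaryK must be non-empty")
  if (length(object@unusedReadK) != 1L || length(object@finalK) != 1L)
    return("unusedReadK and finalK must be single values")
  if (any(ks %% 2L == 0L)) return("all hash lengths must be odd")
  if (any(ks < 15L)) return("hash lengths below 15 are not supported")
  if (!all(object@unusedFromK %in% object@exploratoryK))
    return("unusedFromK must be a subset of exploratoryK")
  if (object@minKmerCoverage < 1L || object@summaryKmerCoverage < 1L)
    return("coverage cutoffs must be >= 1")
  TRUE
})

#' Default assembly plan
#'
#' Exploratory assemblies at k = 21, 25, 31, 35, 41, 49 and 59; an assembly
#' (k = 57) of the reads left unused by the k = 21, 35, 49 and 59 runs;
#' summary assemblies of all resulting contigs at k = 29, 39 and 49; and a
#' final summary assembly at k = 39. Read-stage graphs drop singleton k-mers
#' (\code{minKmerCoverage = 2}); summary stages keep everything.
#'
#' @param exploratoryK,unusedReadK,unusedFromK,summaryK,finalK,
#'   minKmerCoverage,summaryKmerCoverage override any component of the plan.
#' @return an [AssemblyPlan-class] object.
#' @examples
#' defaultAssemblyPlan()
#' defaultAssemblyPlan(exploratoryK = c(21L, 31L), summaryK = 29L, finalK = 29L)
#' @export
defaultAssemblyPlan <- function(exploratoryK = c(21L, 25L, 31L, 35L, 41L, 49L, 59L),
                                unusedReadK = 57L,
                                unusedFromK = c(21L, 35L, 49L, 59L),
                                summaryK = c(29L, 39L, 49L),
                                finalK = 39L,
                                minKmerCoverage = 2L,
                                summaryKmerCoverage = 1L) {
  unusedFromK <- intersect(as.integer(unusedFromK), as.integer(exploratoryK))
  new("AssemblyPlan",
      exploratoryK = as.integer(exploratoryK),
      unusedReadK = as.integer(unusedReadK),
      unusedFromK = as.integer(unusedFromK),
      summaryK = as.integer(summaryK),
      finalK = as.integer(finalK),
      minKmerCoverage = as.integer(minKmerCoverage),
      summaryKmerCoverage = as.integer(summaryKmerCoverage))
}

setMethod("show", "AssemblyPlan", function(object) {
  cat("AssemblyPlan\n")
  cat("  exploratory k: ", paste(object@exploratoryK, collapse = ", "), "\n", sep = "")
  cat("  unused-read k: ", object@unusedReadK, " (fed from k = ",
      paste(object@unusedFromK, collapse = ", "), ")\n", sep = "")
  cat("  summary k:     ", paste(object@summaryK, collapse = ", "), "\n", sep = "")
  cat("  final k:       ", object@finalK, "\n", sep = "")
  cat("  min k-mer coverage: ", object@minKmerCoverage, " (read stage), ",
      object@summaryKmerCoverage, " (summary stage)\n", sep = "")
})

#' De Bruijn graph over canonical k-mers
#'
#' A node-centric bidirected de Bruijn graph: nodes are canonical k-mers
#' (the lexicographic minimum of a k-mer and its reverse complement) with
#' their observed multiplicities; edges are implicit (k-1)-overlaps, probed
#' on demand during unitig extraction.
#'
#' @slot k odd integer hash length.
#' @slot coverage named integer vector; names are canonical k-mers, values
#'   their multiplicities in the input (each >= the coverage cutoff used to
#'   build the graph).
#' @seealso [buildGraph()], [extractUnitigs()]
#' @export
setClass("DeBruijnGraph",
  representation(k = "integer", coverage = "integer")
)

setValidity("DeBruijnGraph", function(object) {
  if (length(object@k) != 1L || object@k %% 2L == 0L || object@k < 15L)
    return("k must be a single odd integer >= 15")
  if (length(object@coverage) && (is.null(names(object@coverage)) ||
      any(object@coverage < 1L)))
    return("coverage must be a named integer vector with values >= 1")
  TRUE
})

#' @describeIn DeBruijnGraph-class hash length of the graph.
#' @param x,object a \code{DeBruijnGraph}.
#' @export
graphK <- function(x) x@k

#' @describeIn DeBruijnGraph-class named multiplicity vector over canonical
#'   k-mers.
#' @export
kmerCoverage <- function(x) x@coverage

setMethod("show", "DeBruijnGraph", function(object) {
  cat("DeBruijnGraph: k = ", object@k, ", ", length(object@coverage),
      " canonical k-mers\n", sep = "")
})

#' Read QC tally
#'
#' Bookkeeping for one pass of the pre-assembly/pre-mapping read filters.
#' \code{nPassed} always reconciles exactly with
#' \code{nInput - nRemovedQuality - nRemovedPolyA}; a read failing both
#' filters is counted once, under the quality filter.
#'
#' @slot nInput,nRemovedQuality,nRemovedPolyA,nTrimmed,nPassed integer counts.
#' @seealso [filterReads()]
#' @export
setClass("QCReport",
  representation(nInput = "integer", nRemovedQuality = "integer",
                 nRemovedPolyA = "integer", nTrimmed = "integer",
                 nPassed = "integer")
)

setValidity("QCReport", function(object) {
  v <- c(object@nInput, object@nRemovedQuality, object@nRemovedPolyA,
         object@nTrimmed, object@nPassed)
  if (any(v < 0L)) return("all counts must be >= 0")
  if (object@nPassed != object@nInput - object@nRemovedQuality - object@nRemovedPolyA)
    return("nPassed must equal nInput - nRemovedQuality - nRemovedPolyA")
  TRUE
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport\n")
  cat("  input reads:        ", object@nInput, "\n")
  cat("  removed (quality):  ", object@nRemovedQuality, "\n")
  cat("  removed (poly-A):   ", object@nRemovedPolyA, "\n")
  cat("  trimmed:            ", object@nTrimmed, "\n")
  cat("  passed:             ", object@nPassed, "\n")
})

#' Assembled/curated contig set
#'
#' A [Biostrings::DNAStringSet] whose metadata columns record how each contig
#' arose: \code{provenance} is one of \code{assembled} (unitig from the final
#' summary assembly), \code{est_joined} (extended around a conspecific EST),
#' \code{peptide_joined} (overlap-merged around a heterospecific peptide),
#' \code{n_scaffolded} (two contigs bridged by an N run sized from peptide
#' HSP coordinates), or \code{unchanged} (passed through a clustering step
#' untouched); \code{sourceIds} is a comma-separated list of contributing
#' sequence ids.
#'
#' @seealso [provenance()], [iterativeAssemble()], [estCluster()],
#'   [peptideCluster()]
#' @export
setClass("ContigSet", contains = "DNAStringSet")

.provenanceLevels <- c("assembled", "est_joined", "peptide_joined",
                       "n_scaffolded", "unchanged")

setValidity("ContigSet", function(object) {
  mc <- S4Vectors::mcols(object)
  if (is.null(mc) || !all(c("provenance", "sourceIds") %in% colnames(mc)))
    return("mcols must contain 'provenance' and 'sourceIds'")
  if (!all(mc$provenance %in% .provenanceLevels))
    return(paste0("provenance must be one of: ",
                  paste(.provenanceLevels, collapse = ", ")))
  if (length(object) && any(Biostrings::width(object) == 0L))
    return("contigs must be non-empty sequences")
  TRUE
})

#' Construct a ContigSet
#'
#' @param seqs a [Biostrings::DNAStringSet] or named character vector.
#' @param provenance character vector recycled along \code{seqs}.
#' @param sourceIds character vector of comma-separated contributing ids;
#'   defaults to each contig's own name.
#' @return a [ContigSet-class].
#' @examples
#' ContigSet(c(c1 = "ACGTACGTACGT"), provenance = "assembled")
#' @export
ContigSet <- function(seqs, provenance = "assembled", sourceIds = NULL) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(sourceIds)) sourceIds <- names(seqs)
  if (is.null(sourceIds)) sourceIds <- character(length(seqs))
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    provenance = rep_len(provenance, length(seqs)),
    sourceIds = rep_len(sourceIds, length(seqs)))
  new("ContigSet", seqs)
}

#' Contig provenance labels
#'
#' @param x a [ContigSet-class].
#' @return character vector of provenance labels, one per contig.
#' @export
provenance <- function(x) S4Vectors::mcols(x)$provenance

#' Contributing source ids of each contig
#'
#' @param x a [ContigSet-class].
#' @return character vector; comma-separated ids of the sequences merged
#'   into each contig.
#' @export
sourceIds <- function(x) S4Vectors::mcols(x)$sourceIds

setMethod("show", "ContigSet", function(object) {
  cat("ContigSet with ", length(object), " contigs\n", sep = "")
  if (length(object)) {
    tab <- table(provenance(object))
    cat("  provenance: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
    cat("  total bp: ", sum(Biostrings::width(object)),
        "; N50 = ", n50(Biostrings::width(object)), "\n", sep = "")
  }
})
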