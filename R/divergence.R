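# Protein divergence between 1:1 orthologues, divergence binning, group
# comparison and functional-category enrichment.

#' Protein divergence from a pairwise alignment
#'
#' The proportion of alignment columns that differ (\code{pDiff}; gap
#' columns count as differences unless \code{countGaps = FALSE}, in which
#' case they are excluded from the denominator), the protein distance
#' \code{dist = sqrt(pDiff)}, and the identity over aligned non-gap
#' columns.
#'
#' @param aln a protein [PairwiseAln-class] (global alignment of an
#'   orthologous pair).
#' @param countGaps treat gap columns as differences (default) or exclude
#'   them.
#' @return list with \code{pDiff}, \code{dist}, \code{identity}.
#' @export
proteinDivergence <- function(aln, countGaps = TRUE) {
  if (nchar(aln@alignedA) == 0L)
    stop("zero-length alignment", call. = FALSE)
  st <- .alnStats(aln@alignedA, aln@alignedB)
  pDiff <- if (countGaps) 1 - st$nIdent / st$ncol
           else if (st$nNonGap > 0L) 1 - st$nIdent / st$nNonGap else 0
  list(pDiff = pDiff, dist = sqrt(pDiff),
       identity = if (st$nNonGap > 0L) st$nIdent / st$nNonGap else 0)
}

#' Exclude low-identity orthologous pairs
#'
#' Automated alignment is unreliable at high divergence, so pairs with
#' identity strictly below \code{minIdentity} are excluded before
#' divergence analysis.
#'
#' @param records data.frame with an \code{identity} column (fractions).
#' @param minIdentity identity threshold; 0.30 keeps a pair at exactly 30%.
#' @return the surviving rows.
#' @export
identityFilter <- function(records, minIdentity = 0.30) {
  records[records$identity >= minIdentity, , drop = FALSE]
}

#' Bin divergence values into Low / Intermediate / High
#'
#' \code{mode = "fixed"} uses explicit cutoffs on the proportion-different
#' scale: Low (<= \code{low}), High (>= \code{high}), Intermediate
#' strictly between; the defaults 0.058 and 0.138 are the package's
#' reference cutoffs for mosquito-scale interspecific comparisons.
#' \code{mode = "terciles"} determines the cutoffs empirically from the
#' input so that one third of the records falls into each bin: the Low
#' cutoff is the floor(n/3)-th smallest value and the High cutoff the
#' (n - floor(n/3) + 1)-th, so for distinct values each bin receives
#' n/3 +/- 1 records (exactly n/3 when n is divisible by 3).
#'
#' @param pDiff numeric vector of proportion-different values.
#' @param mode \code{"fixed"} or \code{"terciles"}.
#' @param low,high fixed-mode cutoffs.
#' @return factor with levels \code{Low}, \code{Intermediate},
#'   \code{High}; the cutoffs used are attached as attribute
#'   \code{"cutoffs"}.
#' @export
binDivergence <- function(pDiff, mode = c("fixed", "terciles"),
                          low = 0.058, high = 0.138) {
  mode <- match.arg(mode)
  if (mode == "terciles") {
    n <- length(pDiff)
    if (n < 3L) stop("tercile binning needs at least 3 records",
                     call. = FALSE)
    s <- sort(pDiff)
    low <- s[floor(n / 3)]
    high <- s[n - floor(n / 3) + 1L]
  }
  bin <- ifelse(pDiff >= high, "High",
                ifelse(pDiff <= low, "Low", "Intermediate"))
  out <- factor(bin, levels = c("Low", "Intermediate", "High"))
  attr(out, "cutoffs") <- c(low = low, high = high)
  out
}

#' Compare divergence between two groups (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test: exact enumeration when the product of
#' group sizes is at most 10^4 and the data contain no ties, otherwise the
#' tie-corrected normal approximation (with continuity correction).
#'
#' @param a,b numeric vectors (e.g. per-pair divergences of an annotated
#'   subset vs the whole set).
#' @return list with \code{U} (statistic for \code{a} relative to
#'   \code{b}) and \code{p} (two-sided).
#' @examples
#' groupCompare(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
groupCompare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && length(a) * length(b) <= 1e4
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Chi-squared enrichment of divergence bins across functional categories
#'
#' For every category with at least \code{minN} annotated records, tests
#' the observed (Low, Intermediate, High) counts against expected
#' proportions with a chi-squared goodness-of-fit test (df = 2). By
#' default the expected proportions are the global bin proportions of the
#' full record set - which are equal thirds by construction under tercile
#' binning, making the two natural expectations coincide;
#' \code{expected = "equal"} forces exact thirds. Significance uses a
#' Bonferroni-adjusted per-test level \code{alphaFamily / m}, with m the
#' number of categories actually tested. Records annotated to several
#' categories contribute to each.
#'
#' @param bins factor from [binDivergence()], one element per record.
#' @param categories list parallel to \code{bins}: each element a
#'   character vector of category labels for that record (possibly empty).
#' @param minN minimum category size for testing.
#' @param alphaFamily family-wise error level.
#' @param expected \code{"global"} or \code{"equal"}.
#' @return data.frame with one row per tested category: observed counts,
#'   \code{chi2}, \code{df}, \code{p}, the per-test \code{alpha},
#'   \code{significant}, and \code{topBin}/\code{direction} naming the bin
#'   with the largest standardised residual and its sign
#'   (\code{"enriched"}/\code{"depleted"}).
#' @export
categoryEnrichment <- function(bins, categories, minN = 15L,
                               alphaFamily = 0.05,
                               expected = c("global", "equal")) {
  expected <- match.arg(expected)
  stopifnot(length(bins) == length(categories))
  lv <- levels(bins)
  props <- if (expected == "equal") rep(1 / 3, 3)
           else as.vector(table(bins)) / length(bins)
  if (any(props == 0))
    stop("a divergence bin is empty in the full record set; ",
         "use expected = \"equal\"", call. = FALSE)
  cats <- sort(unique(unlist(categories)))
  long <- data.frame(
    cat = unlist(categories),
    bin = rep(as.character(bins), times = lengths(categories)),
    stringsAsFactors = FALSE)
  tested <- cats[vapply(cats, function(cc) sum(long$cat == cc) >= minN,
                        logical(1))]
  m <- length(tested)
  if (m == 0L)
    return(data.frame(category = character(0), n = integer(0),
                      obsLow = integer(0), obsIntermediate = integer(0),
                      obsHigh = integer(0), chi2 = numeric(0),
                      df = integer(0), p = numeric(0), alpha = numeric(0),
                      significant = logical(0), topBin = character(0),
                      direction = character(0), stringsAsFactors = FALSE))
  alpha <- alphaFamily / m
  rows <- lapply(tested, function(cc) {
    obs <- table(factor(long$bin[long$cat == cc], levels = lv))
    n <- sum(obs)
    expv <- n * props
    chi2 <- sum((obs - expv)^2 / expv)
    p <- pchisq(chi2, df = 2, lower.tail = FALSE)
    resid <- (obs - expv) / sqrt(expv)
    top <- which.max(abs(resid))
    data.frame(category = cc, n = n,
               obsLow = as.integer(obs[["Low"]]),
               obsIntermediate = as.integer(obs[["Intermediate"]]),
               obsHigh = as.integer(obs[["High"]]),
               chi2 = chi2, df = 2L, p = p, alpha = alpha,
               significant = p < alpha,
               topBin = lv[top],
               direction = if (resid[top] > 0) "enriched" else "depleted",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Divergence records for a set of orthologous pairs
#'
#' Aligns each contig's translated ORF (or supplied protein) to its
#' orthologous peptide, computes divergence, and applies the identity
#' filter.
#'
#' @param pairs data.frame from [reciprocalBestHits()].
#' @param proteins named character vector: contig id -> protein sequence
#'   (e.g. selected-ORF translations).
#' @param peptides named character vector: peptide id -> sequence.
#' @param minIdentity identity cutoff, see [identityFilter()].
#' @param countGaps see [proteinDivergence()].
#' @return data.frame with columns \code{contigId}, \code{peptideId},
#'   \code{pDiff}, \code{dist}, \code{identity}.
#' @export
divergenceRecords <- function(pairs, proteins, peptides,
                              minIdentity = 0.30, countGaps = TRUE) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    cid <- pairs$contigId[i]; pid <- pairs$peptideId[i]
    if (!cid %in% names(proteins) || !pid %in% names(peptides)) return(NULL)
    aln <- globalAlign(setNames(proteins[[cid]], cid),
                       setNames(peptides[[pid]], pid),
                       scheme = protScheme())
    dv <- proteinDivergence(aln, countGaps = countGaps)
    data.frame(contigId = cid, peptideId = pid, pDiff = dv$pDiff,
               dist = dv$dist, identity = dv$identity,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(contigId = character(0), peptideId = character(0),
                      pDiff = numeric(0), dist = numeric(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  identityFilter(do.call(rbind, rows), minIdentity)
}
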