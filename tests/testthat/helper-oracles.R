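# Independent oracles used across the suite. Each is deliberately written
# by a different route than the implementation it checks.

# exhaustive affine-gap global alignment score by enumerating every
# monotone alignment (no dynamic programming); feasible for short sequences
bruteGlobalScore <- function(a, b, match = 5, mismatch = -4,
                             gapOpen = -10, gapExt = -1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  rec <- function(i, j, lastOp, acc) {
    if (i > n && j > m) { best <<- max(best, acc); return(invisible()) }
    if (i <= n && j <= m)
      rec(i + 1L, j + 1L, "M",
          acc + if (av[i] == bv[j]) match else mismatch)
    if (i <= n)
      rec(i + 1L, j, "D", acc + if (identical(lastOp, "D")) gapExt else gapOpen)
    if (j <= m)
      rec(i, j + 1L, "I", acc + if (identical(lastOp, "I")) gapExt else gapOpen)
    invisible()
  }
  rec(1L, 1L, "", 0)
  best
}

# brute-force six-frame ORF lengths via Biostrings translation and regex,
# independent of the package's own codon-walking scan
bruteBestOrfs <- function(seq) {
  s <- Biostrings::DNAString(seq)
  frames <- list(
    Biostrings::subseq(s, 1), Biostrings::subseq(s, 2),
    Biostrings::subseq(s, 3),
    rc <- Biostrings::reverseComplement(s),
    Biostrings::subseq(rc, 2), Biostrings::subseq(rc, 3))
  frames[[4]] <- rc
  bestA <- 0L; bestB <- 0L
  for (f in frames) {
    len <- 3L * (length(f) %/% 3L)
    if (len == 0L) next
    p <- suppressWarnings(as.character(
      Biostrings::translate(Biostrings::subseq(f, 1, len),
                            if.fuzzy.codon = "solve",
                            no.init.codon = TRUE)))
    aMatches <- regmatches(p, gregexpr("M[^*]*(?=\\*)", p, perl = TRUE))[[1]]
    if (length(aMatches)) bestA <- max(bestA, nchar(aMatches))
    bMatches <- regmatches(p, gregexpr("[^*]+", p))[[1]]
    if (length(bMatches)) bestB <- max(bestB, nchar(bMatches))
  }
  list(aLen = bestA, bLen = bestB)
}

# N50 straight from the definition: the largest L among the lengths such
# that lengths >= L sum to at least half the total
bruteN50 <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  stop("unreachable")
}

# exact two-sided Mann-Whitney p by complete enumeration of rank splits
bruteMannWhitney <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  uObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(length(pooled), na)
  uAll <- apply(idx, 2, function(ii) sum(r[ii]) - na * (na + 1) / 2)
  p <- 2 * min(mean(uAll <= uObs), mean(uAll >= uObs))
  list(U = uObs, p = min(1, p))
}

# canonical form of a sequence set for strand-insensitive comparison
canonSeqs <- function(seqs) {
  seqs <- toupper(unname(as.character(seqs)))
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  sort(pmin(seqs, rc))
}

# all canonical k-mers of a set of sequences (containment checks)
canonKmerSet <- function(seqs, k) {
  km <- unlist(lapply(as.character(seqs), function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }))
  if (length(km) == 0L) return(character(0))
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  unique(pmin(km, rc))
}

# random DNA of given length
randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
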