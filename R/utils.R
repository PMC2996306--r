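#' @import methods
#' @importFrom stats median pbinom pchisq rbinom rmultinom runif
#'   setNames wilcox.test
#' @importFrom utils head tail read.delim write.table
NULL

# internal: timestamped status line on stderr; all pipeline chatter goes
# through here so tests can silence it with suppressMessages()
tfLog <- function(...) {
  message(format(Sys.time(), "%H:%M:%S "), ...)
}

#' Reverse complement of plain character sequences
#'
#' Vectorised reverse complement for bare character vectors, used where
#' round-tripping through [Biostrings::DNAStringSet] would dominate runtime
#' (k-mer canonicalisation in the assembler).
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return character vector of reverse complements, uppercase.
#' @examples
#' revCompChr(c("ACGT", "AAN"))
#' @export
revCompChr <- function(x) {
  if (length(x) == 0L) return(character(0))
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# internal: DNAStringSet-backed reverse complement, faster for many strings
revCompFast <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Phred quality to expected error rate
#'
#' The Sanger convention maps a Phred score Q to an expected base-calling
#' error rate of 10^(-Q/10); Q = 20 corresponds to exactly 1%.
#'
#' @param q numeric vector of Phred scores.
#' @return numeric vector of error probabilities.
#' @examples
#' phredErrorRate(20)  # 0.01
#' @export
phredErrorRate <- function(q) 10^(-q / 10)

# internal: all k-mers of one sequence (character scalar); empty if too short
seqKmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# internal: canonical form = lexicographic min of k-mer and reverse complement
canonicalKmers <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  rc <- revCompFast(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

# internal: round half up (R's round() is banker's rounding)
roundHalfUp <- function(x) floor(x + 0.5)

# internal: checkmate-lite argument guards
stopifnotScalarInt <- function(x, name, min = NULL) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x))
    stop("'", name, "' must be a single integer", call. = FALSE)
  if (!is.null(min) && x < min)
    stop("'", name, "' must be >= ", min, call. = FALSE)
  invisible(as.integer(x))
}
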