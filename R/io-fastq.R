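#' Read a FASTQ file (Sanger Phred+33)
#'
#' Thin wrapper around [Biostrings::readQualityScaledDNAStringSet] that
#' enforces the Sanger quality convention. Qualities are assumed Phred+33;
#' files that look Phred+64 encoded (quality characters above 'J', i.e.
#' Phred > 41 under the Sanger reading) trigger a warning rather than a
#' silent re-interpretation, and characters below '!' are impossible and
#' raise an error. Malformed 4-line blocks are reported with the line number
#' of the offending record.
#'
#' @param path path to an (optionally gzipped) FASTQ file.
#' @return a [Biostrings::QualityScaledDNAStringSet].
#' @seealso [writeFastq()], [readQuals()]
#' @export
readFastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n == 0L)
    return(Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(), Biostrings::PhredQuality(character(0))))
  .validateFastq(lines, path)
  ids <- sub("^@", "", sub("\\s.*", "", lines[seq(1L, n, 4L)]))
  seqs <- lines[seq(2L, n, 4L)]
  quals <- lines[seq(4L, n, 4L)]
  qmax <- max(utf8ToInt(paste(quals, collapse = "")))
  if (qmax < utf8ToInt("!"))
    stop("quality characters below '!' are impossible in Phred+33",
         call. = FALSE)
  if (qmax > utf8ToInt("J") + 19L)  # far beyond the plausible Sanger range
    warning("quality characters far beyond 'J' suggest Phred+64 encoding; ",
            "qualities are interpreted as Phred+33 regardless", call. = FALSE)
  makeReads(seqs, quals, ids)
}

# internal: check 4-line block structure, reporting the offending line
.validateFastq <- function(lines, path) {
  n <- length(lines)
  blockStarts <- seq(1L, n - n %% 4L, 4L)
  if (n %% 4L != 0L)
    stop("malformed FASTQ record starting at line ", n - n %% 4L + 1L,
         " of ", path, call. = FALSE)
  bad <- !startsWith(lines[blockStarts], "@") |
    !startsWith(lines[blockStarts + 2L], "+") |
    nchar(lines[blockStarts + 1L]) != nchar(lines[blockStarts + 3L]) |
    nchar(lines[blockStarts + 1L]) == 0L
  if (any(bad))
    stop("malformed FASTQ record starting at line ",
         blockStarts[which(bad)[1]], " of ", path, call. = FALSE)
  invisible(TRUE)
}

#' Write reads as FASTQ (Sanger Phred+33)
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path output path.
#' @export
writeFastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' Integer Phred scores of a quality-scaled read set
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @return an [IRanges::IntegerList], one element of per-base scores per read.
#' @examples
#' qs <- Biostrings::QualityScaledDNAStringSet(
#'   Biostrings::DNAStringSet(c(r = "ACG")), Biostrings::PhredQuality("I!5"))
#' readQuals(qs)[[1]]  # 40 0 20
#' @export
readQuals <- function(reads) {
  methods::as(Biostrings::quality(reads), "IntegerList")
}

# internal: build a QualityScaledDNAStringSet from character vectors
makeReads <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(ids)) ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  dss <- Biostrings::DNAStringSet(unname(seqs))
  names(dss) <- ids
  if (is.null(quals))
    quals <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  Biostrings::QualityScaledDNAStringSet(dss, Biostrings::PhredQuality(unname(quals)))
}
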