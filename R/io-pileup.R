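#' Read a text pileup file
#'
#' Parses the classic samtools text-pileup dialect: one line per covered
#' reference position with columns contig, position (1-based), reference
#' base, read depth, base string and quality string, plus an optional
#' seventh column of per-read mapping-quality characters (Phred+33). In the
#' base string, `.`/`,` are reference-matching observations, letters are
#' alternative bases, `*` is a deleted base, `^X` and `$` mark read starts
#' and ends, and `+n<seq>`/`-n<seq>` encode an insertion/deletion attached
#' to the preceding read.
#'
#' Base and indel counts only include reads whose mapping quality is at
#' least \code{minMapq}; when the file carries no MAPQ column every read is
#' assumed to have \code{defaultMapq} (the minimal dialect cannot represent
#' per-read mapping qualities). Reported \code{depth} is the raw column-4
#' depth, so sites where every read fails the MAPQ cutoff keep their depth
#' but have empty counts.
#'
#' @param path path to the pileup file.
#' @param minMapq minimum mapping quality for a read to contribute counts.
#' @param defaultMapq constant MAPQ assumed when the file has only 6 columns.
#' @return a data.frame with columns \code{contig}, \code{pos}, \code{ref},
#'   \code{depth}, per-base MAPQ-passing counts \code{A}, \code{C}, \code{G},
#'   \code{T}, \code{N}, and \code{indels} (encoded
#'   \code{"+SEQ:count|-SEQ:count"}, empty string when none).
#' @seealso [writePileup()], [callSnds()]
#' @export
readPileup <- function(path, minMapq = 20, defaultMapq = 60) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(emptyPileup())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L)
      stop("pileup line ", i, ": expected >= 6 tab-separated columns",
           call. = FALSE)
    depth <- as.integer(f[4])
    ref <- toupper(f[3])
    if (depth == 0L) {
      return(data.frame(contig = f[1], pos = as.integer(f[2]), ref = ref,
                        depth = 0L, A = 0L, C = 0L, G = 0L, T = 0L, N = 0L,
                        indels = "", stringsAsFactors = FALSE))
    }
    dec <- decodeBaseString(f[5], ref, line = i)
    if (length(dec$base) != depth)
      stop("pileup line ", i, ": depth ", depth, " but ",
           length(dec$base), " read observations in base string",
           call. = FALSE)
    mapq <- if (length(f) >= 7L && nzchar(f[7])) {
      utf8ToInt(f[7]) - 33L
    } else rep(defaultMapq, depth)
    if (length(mapq) != depth)
      stop("pileup line ", i, ": MAPQ string length does not match depth",
           call. = FALSE)
    keep <- mapq >= minMapq
    bases <- dec$base[keep]
    counts <- vapply(c("A", "C", "G", "T", "N"),
                     function(b) sum(bases == b), integer(1))
    ind <- dec$indel[keep]
    ind <- ind[nzchar(ind)]
    enc <- if (length(ind)) {
      tab <- sort(table(ind))
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = "|")
    } else ""
    data.frame(contig = f[1], pos = as.integer(f[2]), ref = ref,
               depth = depth, A = counts[["A"]], C = counts[["C"]],
               G = counts[["G"]], T = counts[["T"]], N = counts[["N"]],
               indels = enc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# internal: empty pileup table with the right shape
emptyPileup <- function() {
  data.frame(contig = character(0), pos = integer(0), ref = character(0),
             depth = integer(0), A = integer(0), C = integer(0),
             G = integer(0), T = integer(0), N = integer(0),
             indels = character(0), stringsAsFactors = FALSE)
}

# internal: decode one pileup base string into per-read base calls plus the
# indel (if any) attached to each read; bases are uppercased, './,' resolved
# to the reference base, '*' (deleted base) kept as "*" and later ignored
# for base counts
decodeBaseString <- function(s, ref, line = NA) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  base <- character(0); indel <- character(0)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") { i <- i + 2L; next }          # read start + mapq char
    if (ch == "$") { i <- i + 1L; next }          # read end
    if (ch %in% c("+", "-")) {                    # indel on previous read
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (is.na(len) || j + len - 1L > n)
        stop("pileup line ", line, ": malformed indel encoding", call. = FALSE)
      if (length(base) == 0L)
        stop("pileup line ", line, ": indel with no preceding read",
             call. = FALSE)
      indel[length(base)] <- paste0(
        ch, toupper(paste(chars[j:(j + len - 1L)], collapse = "")))
      i <- j + len
      next
    }
    if (ch %in% c(".", ",")) {
      base <- c(base, ref); indel <- c(indel, "")
    } else if (toupper(ch) %in% c("A", "C", "G", "T", "N", "*")) {
      base <- c(base, ifelse(ch == "*", "*", toupper(ch)))
      indel <- c(indel, "")
    } else {
      stop("pileup line ", line, ": unexpected character '", ch,
           "' in base string", call. = FALSE)
    }
    i <- i + 1L
  }
  list(base = base, indel = indel)
}

#' Write a pileup table as text pileup
#'
#' Inverse of [readPileup()] for tables whose depth equals the number of
#' counted reads: each counted base becomes one read observation (reference
#' matches as `.`), indels are attached to the first observations, and a
#' constant MAPQ column is emitted so the counts survive a round trip at any
#' cutoff up to \code{mapq}.
#'
#' @param sites a pileup table as returned by [readPileup()].
#' @param path output path.
#' @param mapq constant per-read mapping quality to emit.
#' @export
writePileup <- function(sites, path, mapq = 60L) {
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    r <- sites[i, ]
    ev <- character(0)
    for (b in c("A", "C", "G", "T", "N")) {
      cnt <- r[[b]]
      if (cnt > 0L)
        ev <- c(ev, rep(if (b == r$ref) "." else b, cnt))
    }
    if (length(ev) == 0L)
      return(paste(r$contig, r$pos, r$ref, 0L, "*", "*", sep = "\t"))
    if (nzchar(r$indels)) {
      for (spec1 in strsplit(r$indels, "|", fixed = TRUE)[[1]]) {
        parts <- strsplit(spec1, ":", fixed = TRUE)[[1]]
        key <- parts[1]; cnt <- as.integer(parts[2])
        enc <- paste0(substr(key, 1, 1), nchar(key) - 1L, substring(key, 2))
        free <- which(!grepl("[+-]", ev))[seq_len(cnt)]
        ev[free] <- paste0(ev[free], enc)
      }
    }
    paste(r$contig, r$pos, r$ref, length(grep("^[.ACGTN*]", ev)),
          paste(ev, collapse = ""),
          strrep("I", length(ev)),
          strrep(intToUtf8(mapq + 33L), length(ev)),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
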