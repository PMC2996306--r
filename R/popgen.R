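# SND calling and depth-corrected nucleotide diversity.
#
# An SND (short nucleotide discrepancy) is a SNP or short indel called
# from a read pileup. The calling rules are: reads contribute only at
# mapping quality >= 20 (enforced when the pileup is read); a site must be
# covered by at least 6 reads; the alternative allele must be seen at
# least twice, or at least ceiling(0.025 x depth) times when depth exceeds
# 80 (sequencing errors are expected to be singletons but accumulate
# linearly with depth); and exactly one alternative allele may reach that
# threshold. Indel alleles compete with SNP alleles under the same rule.

# internal: per-site alternative-allele count threshold
.sndThreshold <- function(depth, minAlt = 2L, fracWhenDeep = 0.025,
                          deepCutoff = 80L) {
  ifelse(depth > deepCutoff,
         pmax(minAlt, ceiling(fracWhenDeep * depth)),
         minAlt)
}

#' Call SNDs from a pileup table
#'
#' Applies the depth, allele-count and single-alternative rules to every
#' site of a (MAPQ-filtered) pileup table. The output is invariant to site
#' order.
#'
#' @param sites pileup table as returned by [readPileup()] or
#'   [simPileupSites()].
#' @param minDepth minimum raw read depth at the site.
#' @param minAlt minimum alternative-allele observations.
#' @param fracWhenDeep fraction of depth replacing \code{minAlt} at deep
#'   sites.
#' @param deepCutoff depth above which the fractional rule applies.
#' @return data.frame with columns \code{contig}, \code{pos}, \code{ref},
#'   \code{alt} (a base, or an indel string such as \code{"+AG"}/
#'   \code{"-T"}), \code{altCount}, \code{depth}, \code{kind}
#'   (\code{"snp"}/\code{"indel"}).
#' @export
callSnds <- function(sites, minDepth = 6L, minAlt = 2L,
                     fracWhenDeep = 0.025, deepCutoff = 80L) {
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      altCount = integer(0), depth = integer(0),
                      kind = character(0), stringsAsFactors = FALSE)
  if (nrow(sites) == 0L) return(empty)
  thr <- .sndThreshold(sites$depth, minAlt, fracWhenDeep, deepCutoff)
  baseM <- as.matrix(sites[, c("A", "C", "G", "T")])
  refIdx <- match(sites$ref, c("A", "C", "G", "T"))
  ok <- !is.na(refIdx)
  baseM[cbind(seq_len(nrow(sites))[ok], refIdx[ok])] <- 0L  # mask reference
  qual <- baseM >= thr
  nQual <- rowSums(qual)
  # indel alleles qualifying at the same threshold
  indelAlt <- vector("list", nrow(sites))
  hasIndel <- nzchar(sites$indels)
  for (i in which(hasIndel)) {
    specs <- strsplit(sites$indels[i], "|", fixed = TRUE)[[1]]
    parts <- strsplit(specs, ":", fixed = TRUE)
    keys <- vapply(parts, `[`, character(1), 1L)
    cnts <- as.integer(vapply(parts, `[`, character(1), 2L))
    q <- cnts >= thr[i]
    if (any(q)) {
      indelAlt[[i]] <- setNames(cnts[q], keys[q])
      nQual[i] <- nQual[i] + sum(q)
    }
  }
  called <- sites$depth >= minDepth & nQual == 1L
  idx <- which(called)
  if (length(idx) == 0L) return(empty)
  bases <- c("A", "C", "G", "T")
  alt <- character(length(idx)); altCount <- integer(length(idx))
  kind <- character(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (length(indelAlt[[i]])) {
      alt[j] <- names(indelAlt[[i]])[1]
      altCount[j] <- indelAlt[[i]][[1]]
      kind[j] <- "indel"
    } else {
      b <- which(qual[i, ])
      alt[j] <- bases[b]
      altCount[j] <- baseM[i, b]
      kind[j] <- "snp"
    }
  }
  out <- data.frame(contig = sites$contig[idx], pos = sites$pos[idx],
                    ref = sites$ref[idx], alt = alt, altCount = altCount,
                    depth = sites$depth[idx], kind = kind,
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Callable length of a contig
#'
#' The number of positions covered by at least \code{minDepth} reads, the
#' denominator of raw per-contig nucleotide diversity. Positions absent
#' from the pileup have depth 0 and therefore never count.
#'
#' @param sites pileup table for one contig.
#' @param minDepth minimum depth.
#' @return integer count of callable positions.
#' @export
callableLength <- function(sites, minDepth = 6L) {
  sum(sites$depth >= minDepth)
}

#' Detection probability of a polymorphic site at a given depth
#'
#' The probability that a truly polymorphic site - with the alternative
#' allele at pool frequency 0.5, sampled binomially across reads - yields
#' enough alternative observations to be called at depth d: Phi(d) =
#' P(Binom(d, 0.5) >= t(d)), where t(d) is the caller's own threshold
#' ([callSnds()] rules). Non-integer depths (per-contig medians) are
#' rounded half up. This binomial model, evaluated at the per-contig
#' median depth, is this package's read-depth ascertainment correction;
#' a user-supplied Phi can be substituted via \code{phi}.
#'
#' @param medianDepth median read depth (>= 1).
#' @param minAlt,fracWhenDeep,deepCutoff caller threshold rule, as in
#'   [callSnds()].
#' @param phi optional replacement: a function of integer depth returning
#'   a probability in (0, 1].
#' @return detection probability in (0, 1].
#' @examples
#' detectProb(6)   # 1 - 7/64 = 57/64
#' detectProb(2)   # 0.25: both reads must carry the alternative allele
#' @export
detectProb <- function(medianDepth, minAlt = 2L, fracWhenDeep = 0.025,
                       deepCutoff = 80L, phi = NULL) {
  if (length(medianDepth) != 1L || is.na(medianDepth) || medianDepth < 1)
    stop("'medianDepth' must be a single value >= 1", call. = FALSE)
  d <- as.integer(roundHalfUp(medianDepth))
  if (!is.null(phi)) return(phi(d))
  t <- .sndThreshold(d, minAlt, fracWhenDeep, deepCutoff)
  1 - pbinom(t - 1, d, 0.5)
}

#' Per-contig nucleotide diversity with depth corrections
#'
#' Raw diversity is the SND count divided by the callable length (bases
#' covered by >= \code{minDepth} reads). Because a site's polymorphism is
#' only detected when enough alternative reads are sampled, raw diversity
#' underestimates the true rate at low coverage; the adjusted value
#' divides by the detection probability [detectProb()] evaluated at the
#' contig's median depth over callable positions.
#'
#' @param calls SND table from [callSnds()] (any number of contigs).
#' @param sites pileup table covering the same contigs.
#' @param minDepth callable-depth threshold.
#' @param minAlt,fracWhenDeep,deepCutoff caller threshold rule.
#' @param phi optional detection-probability override, see [detectProb()].
#' @return data.frame with one row per contig present in \code{sites}:
#'   \code{contig}, \code{nSnd}, \code{callableLen}, \code{piRaw},
#'   \code{medianDepth}, \code{detectProb}, \code{piAdj}.
#' @export
contigDiversity <- function(calls, sites, minDepth = 6L, minAlt = 2L,
                            fracWhenDeep = 0.025, deepCutoff = 80L,
                            phi = NULL) {
  contigs <- unique(sites$contig)
  nSnd <- table(factor(calls$contig, levels = contigs))
  depthByContig <- split(sites$depth, factor(sites$contig, levels = contigs))
  rows <- lapply(contigs, function(cid) {
    d <- depthByContig[[cid]]
    callable <- d >= minDepth
    cl <- sum(callable)
    piRaw <- if (cl > 0L) as.integer(nSnd[[cid]]) / cl else 0
    md <- if (cl > 0L) median(d[callable]) else NA_real_
    dp <- if (cl > 0L)
      detectProb(md, minAlt, fracWhenDeep, deepCutoff, phi) else NA_real_
    data.frame(contig = cid, nSnd = as.integer(nSnd[[cid]]),
               callableLen = cl, piRaw = piRaw, medianDepth = md,
               detectProb = dp,
               piAdj = if (cl > 0L) piRaw / dp else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Reads Per Kilobase per Million mapped reads
#'
#' RPKM_i = c_i x 10^9 / (N x L_i) for read count c_i, contig length L_i
#' (bp) and total mapped reads N. When N equals the sum of the counts,
#' sum(RPKM_i x L_i / 1000) is exactly 10^6.
#'
#' @param readCounts named integer vector (contig -> mapped read count).
#' @param lengths named vector of contig lengths in bp (same names).
#' @param totalMapped total mapped reads N; defaults to
#'   \code{sum(readCounts)}.
#' @return data.frame with columns \code{contig}, \code{readCount},
#'   \code{lengthBp}, \code{rpkm}.
#' @examples
#' rpkm(c(g = 400), c(g = 2000), totalMapped = 1e7)  # 20
#' @export
rpkm <- function(readCounts, lengths, totalMapped = NULL) {
  ids <- names(readCounts)
  if (is.null(ids) || is.null(names(lengths)))
    stop("'readCounts' and 'lengths' must be named", call. = FALSE)
  lens <- lengths[ids]
  if (any(is.na(lens)))
    stop("missing lengths for: ",
         paste(ids[is.na(lens)], collapse = ", "), call. = FALSE)
  if (any(lens <= 0)) stop("contig lengths must be positive", call. = FALSE)
  if (is.null(totalMapped)) totalMapped <- sum(as.numeric(readCounts))
  data.frame(contig = ids, readCount = as.integer(readCounts),
             lengthBp = as.integer(lens),
             rpkm = as.numeric(readCounts) * 1e9 /
               (as.numeric(totalMapped) * as.numeric(lens)),
             stringsAsFactors = FALSE)
}

#' Write SND calls as a minimal VCF
#'
#' Emits VCF 4.2 with site coordinates, alleles and an \code{INFO} field
#' carrying depth and alternative-allele count. Insertions/deletions are
#' written with the anchored-reference convention.
#'
#' @param calls SND table from [callSnds()].
#' @param path output path.
#' @param refSeqs optional named character vector of contig sequences, used
#'   to anchor indel alleles; without it indels are written with a
#'   placeholder \code{N} anchor.
#' @export
writeSndVcf <- function(calls, path, refSeqs = NULL) {
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw depth\">",
              "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt observations\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- vapply(seq_len(nrow(calls)), function(i) {
    r <- calls[i, ]
    if (r$kind == "snp") {
      ref <- r$ref; alt <- r$alt; pos <- r$pos
    } else {
      anchor <- if (!is.null(refSeqs) && r$contig %in% names(refSeqs))
        substr(refSeqs[[r$contig]], r$pos, r$pos) else "N"
      indelSeq <- substring(r$alt, 2)
      if (startsWith(r$alt, "+")) {        # insertion after pos
        ref <- anchor; alt <- paste0(anchor, indelSeq)
      } else {                             # deletion after pos
        ref <- paste0(anchor, indelSeq); alt <- anchor
      }
      pos <- r$pos
    }
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AC=%d",
            r$contig, pos, ref, alt, r$depth, r$altCount)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
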