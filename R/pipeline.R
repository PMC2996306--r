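# Pipeline orchestration: qc -> assemble -> cluster -> validate ->
# orthology -> popgen/rpkm -> divergence, driven by a single configuration
# list (or YAML file), with a hash-based run manifest for idempotent
# re-runs. Every stage reads and writes plain files in standard formats,
# so any stage can equally be run standalone through the exported
# functions.

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @param alphabet \code{"dna"} or \code{"protein"}.
#' @return named character vector.
#' @export
readFasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  x <- if (alphabet == "dna") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector, [Biostrings::XStringSet] or
#'   [ContigSet-class].
#' @param path output path.
#' @param alphabet \code{"dna"} or \code{"protein"}.
#' @export
writeFasta <- function(seqs, path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  x <- setNames(as.character(seqs), names(seqs))
  xss <- if (alphabet == "dna") Biostrings::DNAStringSet(x)
         else Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(xss, path)
  invisible(path)
}

# internal: md5 of a set of files (NA for missing)
.hashes <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(as.character(h), basename(paths))
}

# internal: should a stage re-run? (missing outputs, changed inputs or
# parameters invalidate it)
.stageStale <- function(manifest, stage, inPaths, outPaths, params) {
  prev <- manifest[[stage]]
  if (is.null(prev)) return(TRUE)
  if (!all(file.exists(outPaths))) return(TRUE)
  if (!identical(prev$inputs, as.list(.hashes(inPaths)))) return(TRUE)
  if (!identical(prev$outputs, as.list(.hashes(outPaths)))) return(TRUE)
  if (!identical(prev$params, params)) return(TRUE)
  FALSE
}

#' Run the full pipeline
#'
#' Executes the stages in workflow order, skipping any stage whose inputs,
#' parameters and outputs all match the manifest of a previous run
#' (content-hash comparison); a changed or corrupted intermediate
#' invalidates its stage and every stage downstream of it. Stages are only
#' run when their inputs are configured: a config without \code{pileup},
#' for instance, simply omits the popgen stage.
#'
#' Configuration entries (paths are resolved relative to the working
#' directory): \code{reads1}, \code{reads2} (FASTQ), \code{ests},
#' \code{peptides} (FASTA), \code{evidence} (named list: evidence tag ->
#' peptide/protein FASTA to search), \code{pileup} (text pileup),
#' \code{counts} (TSV contig/count), \code{annotations} (TSV
#' contig/category), \code{outdir}, and optional parameter blocks
#' \code{qc} (maxNFrac, maxLowQFrac, minQ, maxAFrac, trimTo) and
#' \code{assembly} (arguments of [defaultAssemblyPlan()]).
#'
#' @param config a named list, or path to a YAML file with these entries.
#' @return the run manifest (named list per executed stage: input/output
#'   hashes, parameters, timestamp, and whether the stage was skipped),
#'   invisibly; also written to \code{outdir/manifest.json}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- config$outdir
  if (is.null(outdir)) stop("config must name an 'outdir'", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  required <- unlist(config[intersect(names(config),
                                      c("reads1", "reads2", "ests",
                                        "peptides", "pileup", "counts",
                                        "annotations"))])
  missing <- required[!file.exists(required)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  manifestPath <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(manifestPath))
    jsonlite::read_json(manifestPath, simplifyVector = FALSE) else list()
  p <- function(...) file.path(outdir, ...)
  downstreamInvalid <- FALSE

  runStage <- function(stage, inPaths, outPaths, params, fun) {
    # normalise parameters through a JSON round trip so in-memory values
    # compare identically with a manifest re-read from disk
    params <- jsonlite::parse_json(
      jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA))
    if (!downstreamInvalid &&
        !.stageStale(manifest, stage, inPaths, outPaths, params)) {
      tfLog("stage ", stage, ": up to date, skipped")
      manifest[[stage]]$skipped <<- TRUE
      return(invisible(NULL))
    }
    tfLog("stage ", stage, ": running")
    fun()
    manifest[[stage]] <<- list(
      inputs = as.list(.hashes(inPaths)),
      outputs = as.list(.hashes(outPaths)),
      params = params,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      skipped = FALSE)
    downstreamInvalid <<- TRUE
    invisible(NULL)
  }

  # --- qc ---------------------------------------------------------------
  if (!is.null(config$reads1)) {
    qcp <- config$qc
    qcParams <- list(maxNFrac = qcp$maxNFrac %||% 0.33,
                     maxLowQFrac = qcp$maxLowQFrac %||% 0.34,
                     minQ = qcp$minQ %||% 20,
                     maxAFrac = qcp$maxAFrac %||% 0.33,
                     trimTo = qcp$trimTo %||% 75)
    ins <- c(config$reads1, config$reads2)
    outs <- c(p("qc_R1.fq"), if (!is.null(config$reads2)) p("qc_R2.fq"),
              p("qc_report.tsv"))
    runStage("qc", ins, outs, qcParams, function() {
      r1 <- readFastq(config$reads1)
      r2 <- if (!is.null(config$reads2)) readFastq(config$reads2)
      res <- filterReads(r1, r2, maxNFrac = qcParams$maxNFrac,
                         maxLowQFrac = qcParams$maxLowQFrac,
                         minQ = qcParams$minQ, maxAFrac = qcParams$maxAFrac,
                         trimTo = qcParams$trimTo)
      writeFastq(res$reads, p("qc_R1.fq"))
      if (!is.null(res$mates)) writeFastq(res$mates, p("qc_R2.fq"))
      rep <- res$report
      write.table(data.frame(metric = c("nInput", "nRemovedQuality",
                                        "nRemovedPolyA", "nTrimmed",
                                        "nPassed"),
                             value = c(rep@nInput, rep@nRemovedQuality,
                                       rep@nRemovedPolyA, rep@nTrimmed,
                                       rep@nPassed)),
                  p("qc_report.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
  }

  # --- assemble ---------------------------------------------------------
  if (!is.null(config$reads1)) {
    ap <- config$assembly %||% list()
    plan <- do.call(defaultAssemblyPlan, ap)
    ins <- c(p("qc_R1.fq"), if (!is.null(config$reads2)) p("qc_R2.fq"))
    runStage("assemble", ins, p("contigs.fa"), ap, function() {
      reads <- c(as.character(readFastq(p("qc_R1.fq"))),
                 if (!is.null(config$reads2))
                   as.character(readFastq(p("qc_R2.fq"))))
      ctg <- iterativeAssemble(reads, plan)
      writeFasta(ctg, p("contigs.fa"))
    })
  }

  # --- cluster ----------------------------------------------------------
  if (!is.null(config$ests) || !is.null(config$peptides)) {
    ins <- c(p("contigs.fa"), config$ests, config$peptides)
    outs <- c(p("clustered.fa"), p("joins.tsv"))
    runStage("cluster", ins, outs, list(), function() {
      ctg <- readFasta(p("contigs.fa"))
      joins <- emptyJoins()
      if (!is.null(config$ests)) {
        res <- estCluster(ctg, readFasta(config$ests))
        joins <- rbind(joins, res$joins)
        afterEst <- setNames(as.character(res$contigs),
                             names(res$contigs))
        prov <- provenance(res$contigs)
      } else {
        afterEst <- ctg
        prov <- rep("unchanged", length(ctg))
      }
      if (!is.null(config$peptides)) {
        unjoined <- afterEst[prov == "unchanged"]
        res2 <- peptideCluster(unjoined, readFasta(config$peptides,
                                                   "protein"))
        joins <- rbind(joins, res2$joins)
        keepJoined <- afterEst[prov != "unchanged"]
        final <- c(keepJoined, setNames(as.character(res2$contigs),
                                        names(res2$contigs)))
      } else {
        final <- afterEst
      }
      writeFasta(final, p("clustered.fa"))
      write.table(joins, p("joins.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
  }

  # --- validate ---------------------------------------------------------
  if (!is.null(config$evidence)) {
    evFiles <- unlist(config$evidence)
    ins <- c(p("clustered.fa"), evFiles)
    outs <- c(p("final.fa"), p("validate.tsv"))
    runStage("validate", ins, outs, list(minAa = 50), function() {
      ctg <- readFasta(p("clustered.fa"))
      orfs <- selectedOrfs(ctg)
      hitsBySource <- lapply(config$evidence, function(f) {
        targets <- readFasta(f, "protein")
        localSearchAll(ctg, targets, mode = "x")
      })
      ev <- buildEvidenceTable(hitsBySource)
      sel <- selectFinal(ctg, orfs, ev)
      writeFasta(setNames(as.character(sel$final), names(sel$final)),
                 p("final.fa"))
      tagStr <- vapply(names(sel$final), function(id)
        paste(ev[[id]], collapse = ","), character(1))
      rep <- data.frame(contig = names(sel$final),
                        lengthBp = nchar(as.character(sel$final)),
                        orfAa = sel$orfs$aaLen[match(names(sel$final),
                                                     sel$orfs$contigId)],
                        tags = tagStr)
      write.table(rep, p("validate.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
  }

  # --- orthology --------------------------------------------------------
  if (!is.null(config$peptides)) {
    src <- if (!is.null(config$evidence)) p("final.fa") else p("clustered.fa")
    ins <- c(src, config$peptides)
    runStage("orthology", ins, p("pairs.tsv"), list(), function() {
      ctg <- readFasta(src)
      pairs <- findOrthologs(ctg, readFasta(config$peptides, "protein"))
      write.table(pairs, p("pairs.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
  }

  # --- popgen -----------------------------------------------------------
  if (!is.null(config$pileup)) {
    outs <- c(p("snds.vcf"), p("diversity.tsv"))
    runStage("popgen", config$pileup, outs, list(), function() {
      sites <- readPileup(config$pileup)
      calls <- callSnds(sites)
      writeSndVcf(calls, p("snds.vcf"))
      div <- contigDiversity(calls, sites)
      write.table(div, p("diversity.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
  }

  # --- rpkm -------------------------------------------------------------
  if (!is.null(config$counts)) {
    src <- if (!is.null(config$evidence)) p("final.fa") else p("clustered.fa")
    ins <- c(config$counts, src)
    runStage("rpkm", ins, p("rpkm.tsv"), list(), function() {
      cnt <- read.delim(config$counts, header = TRUE,
                        stringsAsFactors = FALSE)
      counts <- setNames(cnt[[2]], cnt[[1]])
      lens <- nchar(readFasta(src))
      common <- intersect(names(counts), names(lens))
      ex <- rpkm(counts[common], lens[common])
      write.table(ex, p("rpkm.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
  }

  # --- divergence -------------------------------------------------------
  if (!is.null(config$peptides) && !is.null(config$annotations)) {
    src <- if (!is.null(config$evidence)) p("final.fa") else p("clustered.fa")
    ins <- c(p("pairs.tsv"), src, config$peptides, config$annotations)
    outs <- c(p("divergence.tsv"), p("enrichment.tsv"))
    runStage("divergence", ins, outs, list(), function() {
      pairs <- read.delim(p("pairs.tsv"), stringsAsFactors = FALSE)
      ctg <- readFasta(src)
      peps <- readFasta(config$peptides, "protein")
      orfs <- selectedOrfs(ctg)
      prots <- setNames(orfs$protein, orfs$contigId)
      recs <- divergenceRecords(pairs, prots, peps)
      ann <- read.delim(config$annotations, stringsAsFactors = FALSE)
      if (nrow(recs) >= 3L) {
        recs$bin <- as.character(binDivergence(recs$pDiff,
                                               mode = "terciles"))
        cats <- lapply(recs$contigId, function(id)
          ann[[2]][ann[[1]] == id])
        enr <- categoryEnrichment(
          factor(recs$bin, levels = c("Low", "Intermediate", "High")),
          cats)
      } else {
        recs$bin <- character(nrow(recs))
        enr <- categoryEnrichment(factor(character(0),
                                         levels = c("Low", "Intermediate",
                                                    "High")),
                                  list())
      }
      write.table(recs, p("divergence.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write.table(enr, p("enrichment.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
  }

  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

# internal: NULL-coalescing helper
`%||%` <- function(a, b) if (is.null(a)) b else a
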