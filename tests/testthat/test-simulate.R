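test_that("transcript generation is deterministic, coding and near-uniform", {
  a <- simTranscriptome(10, c(300, 900), seed = 5)
  b <- simTranscriptome(10, c(300, 900), seed = 5)
  expect_identical(a, b)
  lens <- nchar(a$transcripts)
  expect_true(all(lens %% 3 == 0))
  expect_true(all(lens >= 300 & lens <= 900))
  # the frame +1 type A ORF spans the whole CDS
  for (id in names(a$transcripts)[1:3]) {
    o <- extractOrfs(a$transcripts[id])
    expect_equal(o$typeA$protein, unname(a$proteins[id]))
    expect_equal(o$typeA$frame, 1L)
  }
  # base composition: interior codons uniform over the 61 sense codons,
  # whose expected GC is 94/183 (excluding AT-rich stops raises GC)
  big <- simTranscriptome(100, c(600, 1200), seed = 6)
  seqs <- paste(big$transcripts, collapse = "")
  nBase <- nchar(seqs)
  gc <- sum(strsplit(seqs, "")[[1]] %in% c("G", "C")) / nBase
  se <- sqrt(94 / 183 * (1 - 94 / 183) / nBase)
  expect_lt(abs(gc - 94 / 183), 3 * se + 0.003)  # + small start/stop effect
})

test_that("ortholog simulation plants the requested divergence", {
  sim <- simTranscriptome(30, c(450, 900), seed = 7)
  same <- simOrthologs(sim$proteins, d = 0, seed = 8)
  expect_identical(unname(same$peptides), unname(sim$proteins))
  div <- simOrthologs(sim$proteins, d = 0.1, seed = 9)
  pd <- vapply(seq_along(sim$proteins), function(i) {
    a <- strsplit(sim$proteins[[i]], "")[[1]]
    b <- strsplit(div$peptides[[i]], "")[[1]]
    mean(a != b)
  }, numeric(1))
  nAa <- sum(nchar(sim$proteins))
  se <- sqrt(0.1 * 0.9 / nAa)
  expect_lt(abs(weighted.mean(pd, nchar(sim$proteins)) - 0.1), 3 * se)
})

test_that("read simulation is faithful: clean settings give a clean pileup", {
  tx <- simTranscriptome(2, c(400, 600), seed = 10)$transcripts
  rd <- simReads(tx, depth = 12, errorRate = 0, plantedPi = 0,
                 tiling = "even", seed = 11)
  sites <- buildPileup(tx, rd$alignments)
  nonRef <- vapply(seq_len(nrow(sites)), function(i) {
    sum(unlist(sites[i, c("A", "C", "G", "T", "N")])) -
      sites[[sites$ref[i]]][i]
  }, numeric(1))
  expect_true(all(nonRef == 0))
  expect_true(all(sites$depth >= 2))       # even tiling covers the termini
  # planted sites appear at intermediate frequency with plantedPi > 0
  rd2 <- simReads(tx, depth = 30, errorRate = 0, plantedPi = 0.02,
                  tiling = "even", seed = 12)
  sites2 <- buildPileup(tx, rd2$alignments)
  snd <- rd2$snd
  expect_gt(nrow(snd), 0)
  altFrac <- vapply(seq_len(nrow(snd)), function(i) {
    row <- sites2[sites2$contig == snd$contig[i] &
                    sites2$pos == snd$pos[i], ]
    row[[snd$alt[i]]] / row$depth
  }, numeric(1))
  expect_gt(mean(altFrac), 0.25)
  expect_lt(mean(altFrac), 0.75)
})

test_that("reads round-trip through FASTQ and pass their own QC", {
  tx <- simTranscriptome(1, c(400, 500), seed = 13)$transcripts
  rd <- simReads(tx, depth = 10, seed = 14)
  f <- tempfile(fileext = ".fq")
  writeFastq(rd$r1, f)
  back <- readFastq(f)
  expect_identical(as.character(back), as.character(rd$r1))
  expect_true(all(qualityFilter(back)))
})

test_that("site-level pileup simulation plants heterozygosity at the right rate", {
  sp <- simPileupSites(50, 500, 20, 0.02, seed = 15)
  expect_equal(nrow(sp$sites), 25000L)
  # non-reference observations only at planted sites
  baseM <- as.matrix(sp$sites[, c("A", "C", "G", "T")])
  alt <- rowSums(baseM) -
    baseM[cbind(seq_len(nrow(sp$sites)),
                match(sp$sites$ref, c("A", "C", "G", "T")))]
  plantedKey <- paste(sp$truth$contig, sp$truth$pos)
  allKey <- paste(sp$sites$contig, sp$sites$pos)
  expect_true(all(alt[!allKey %in% plantedKey] == 0))
  p <- nrow(sp$truth) / nrow(sp$sites)
  expect_lt(abs(p - 0.02), 3 * sqrt(0.02 * 0.98 / 25000))
  # zero rates give a fully clean pileup
  clean <- simPileupSites(5, 100, 10, 0, seed = 16)
  expect_equal(nrow(clean$truth), 0L)
})

test_that("category blocks carry an immune-like label on the first block", {
  ids <- sprintf("t%03d", 1:50)
  sc <- simCategories(ids, nCategories = 5)
  expect_length(sc$immune, 10L)
  expect_true(all(vapply(sc$categories[sc$immune],
                         function(x) "immune_like" %in% x, logical(1))))
  expect_equal(sort(unique(unlist(sc$categories))),
               sort(c(sprintf("cat%02d", 1:5), "immune_like")))
})

test_that("simulated counts are deterministic and sum to the total", {
  cnt <- simCounts(letters[1:10], totalReads = 1e5, seed = 17)
  expect_equal(sum(cnt), 1e5L)
  expect_identical(cnt, simCounts(letters[1:10], totalReads = 1e5, seed = 17))
})
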