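test_that("graph construction enumerates canonical k-mers with coverage", {
  set.seed(7)
  src <- randDna(60)
  g <- buildGraph(rep(src, 10), k = 21, minKmerCoverage = 2)
  expect_s4_class(g, "DeBruijnGraph")
  expect_equal(length(kmerCoverage(g)), 40L)   # 60 - 21 + 1
  expect_setequal(names(kmerCoverage(g)), canonKmerSet(src, 21))
  expect_true(all(kmerCoverage(g) == 10L))
  expect_error(buildGraph(src, k = 22), "odd")
})

test_that("coverage cutoff removes singleton error k-mers; N k-mers skipped", {
  set.seed(8)
  src <- randDna(60)
  err <- src
  substr(err, 30, 30) <- if (substr(src, 30, 30) == "A") "C" else "A"
  g <- buildGraph(c(rep(src, 5), err), k = 21, minKmerCoverage = 2)
  gClean <- buildGraph(rep(src, 5), k = 21, minKmerCoverage = 1)
  expect_setequal(names(kmerCoverage(g)), names(kmerCoverage(gClean)))
  gN <- buildGraph(paste0(substr(src, 1, 30), "N", substring(src, 32)),
                   k = 21, minKmerCoverage = 1)
  expect_false(any(grepl("N", names(kmerCoverage(gN)))))
})

test_that("unitig extraction reconstructs repeat-free sequences", {
  set.seed(9)
  src <- randDna(200)
  ctg <- extractUnitigs(buildGraph(rep(src, 3), 21, 2))
  expect_length(ctg, 1L)
  expect_equal(canonSeqs(ctg), canonSeqs(src))
  # empty graph
  expect_length(extractUnitigs(buildGraph(character(0), 21, 1)), 0L)
})

test_that("a shared repeat splits unitigs into flanks plus repeat (X shape)", {
  set.seed(10)
  repeat_ <- randDna(26)                 # > k, shared between transcripts
  t1 <- paste0(randDna(80), repeat_, randDna(80))
  t2 <- paste0(randDna(80), repeat_, randDna(80))
  ctg <- extractUnitigs(buildGraph(c(t1, t2), 21, 1))
  expect_length(ctg, 5L)
  # the repeat's interior k-mers live in exactly one unitig
  repKmers <- canonKmerSet(repeat_, 21)
  hitsPer <- vapply(as.character(ctg), function(s)
    sum(repKmers %in% canonKmerSet(s, 21)), integer(1))
  expect_equal(sum(hitsPer > 0), 1L)
})

test_that("unused-read detection is a k-mer containment test", {
  set.seed(11)
  t1 <- randDna(300); t2 <- randDna(300)
  reads <- c(substr(t1, 1, 75), substr(t1, 100, 174), substr(t2, 1, 75))
  idx <- assignUnusedReads(reads, t1, k = 21)
  expect_equal(idx, 3L)
  expect_equal(assignUnusedReads(reads, character(0), 21), 1:3)
  expect_equal(assignUnusedReads(reads, c(t1, t2), 21), integer(0))
})

smallPlan <- defaultAssemblyPlan(exploratoryK = c(21L, 31L),
                                 unusedFromK = 21L, unusedReadK = 25L,
                                 summaryK = c(29L, 39L), finalK = 39L)

test_that("iterative assembly reconstructs transcripts exactly and deterministically", {
  tx <- simTranscriptome(2, c(450, 750), seed = 21)$transcripts
  rd <- simReads(tx, depth = 25, errorRate = 0, plantedPi = 0,
                 tiling = "even", seed = 22)
  reads <- c(as.character(rd$r1), as.character(rd$r2))
  ctg <- suppressMessages(iterativeAssemble(reads, smallPlan))
  expect_equal(canonSeqs(ctg), canonSeqs(tx))
  ctg2 <- suppressMessages(iterativeAssemble(reads, smallPlan))
  expect_identical(as.character(ctg), as.character(ctg2))
})

test_that("final contigs cover at least what any single exploratory assembly covers", {
  tx <- simTranscriptome(3, c(400, 700), seed = 23)$transcripts
  rd <- simReads(tx, depth = 25, errorRate = 0, plantedPi = 0,
                 tiling = "even", seed = 24)
  reads <- c(as.character(rd$r1), as.character(rd$r2))
  final <- suppressMessages(iterativeAssemble(reads, smallPlan))
  finalKmers <- canonKmerSet(as.character(final), 21)
  for (k in c(21L, 31L)) {
    expl <- extractUnitigs(buildGraph(reads, k, 2))
    exKmers <- canonKmerSet(as.character(expl), 21)
    expect_true(all(exKmers %in% finalKmers), label = paste("k =", k))
  }
})

test_that("assembly summary statistics are consistent", {
  st <- assemblyStats(c(1000, 500, 500))
  expect_equal(st$n, 3L)
  expect_equal(st$totalBp, 2000)
  expect_equal(st$n50, 1000)
})
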