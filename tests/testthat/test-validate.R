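test_that("ORF extraction finds canonical Met-to-stop and stop-free regions", {
  o <- extractOrfs(c(x = "ATGAAATAA"))
  expect_equal(o$typeA$protein, "MK")
  expect_equal(o$typeA$aaLen, 2L)
  expect_equal(o$typeA$frame, 1L)
  expect_equal(c(o$typeA$start, o$typeA$end), c(0L, 6L))
  # strand symmetry: the same ORF is found on the minus strand
  padded <- paste0("CC", txForge:::.rc1("ATGAAATAA"), "CC")
  o2 <- extractOrfs(c(x = padded))
  expect_equal(o2$typeA$protein, "MK")
  expect_true(o2$typeA$frame < 0)
  # no ATG anywhere: type A absent, type B present
  o3 <- extractOrfs(c(x = "CCTCCTCCTCCTCC"))
  expect_null(o3$typeA)
  expect_gt(o3$typeB$aaLen, 0L)
})

test_that("ORF extraction agrees with a brute-force six-frame oracle", {
  set.seed(51)
  for (i in 1:12) {
    s <- randDna(sample(120:600, 1))
    got <- extractOrfs(c(x = s))
    want <- bruteBestOrfs(s)
    gotA <- if (is.null(got$typeA)) 0L else got$typeA$aaLen
    expect_equal(gotA, want$aLen, label = paste("type A, case", i))
    expect_equal(got$typeB$aaLen, want$bLen, label = paste("type B, case", i))
  }
})

test_that("ORF selection prefers the start codon unless type B reaches the 5' end", {
  tx <- simTranscriptome(1, c(300, 300), seed = 52)$transcripts[[1]]
  full <- extractOrfs(c(x = tx))
  sel <- selectOrf(full$typeA, full$typeB, nchar(tx))
  expect_equal(sel$orfType, "A")
  # truncated CDS: type B spans from position 0, upstream of the internal A
  trunc <- substring(tx, 31)              # cut the start codon away
  o <- extractOrfs(c(x = trunc))
  if (!is.null(o$typeA) && o$typeB$start == 0L &&
      o$typeB$start < o$typeA$start) {
    sel2 <- selectOrf(o$typeA, o$typeB, nchar(trunc))
    expect_equal(sel2$orfType, "B")
  }
  expect_equal(selectOrf(NULL, full$typeB, nchar(tx))$orfType, "B")
})

test_that("ORF length filter partitions strictly at 50 aa", {
  orfs <- data.frame(contigId = c("a", "b", "c"),
                     aaLen = c(49L, 50L, 120L))
  part <- orfLengthFilter(orfs)
  expect_equal(part$discarded, "a")
  expect_setequal(part$kept, c("b", "c"))
  expect_setequal(c(part$kept, part$discarded), orfs$contigId)
  # a 147-nt contig cannot host a 50-aa ORF
  o <- selectedOrfs(c(tiny = randDna(147)))
  expect_lt(o$aaLen, 50L)
})

test_that("final selection requires both a long ORF and evidence, with core tally", {
  sim <- simTranscriptome(4, c(400, 600), seed = 53)
  ctgs <- sim$transcripts
  names(ctgs) <- c("c1", "c2", "c3", "c4")
  ctgs["c4"] <- randDna(140)              # no credible ORF
  orfs <- selectedOrfs(ctgs)
  mkHits <- function(ids) data.frame(queryId = ids, evalue = 1e-20,
                                     stringsAsFactors = FALSE)
  ev <- buildEvidenceTable(list(
    agam_pep = mkHits(c("c1", "c2", "c4")),
    aaeg_pep = mkHits("c1"), cqui_pep = mkHits("c1"),
    dmel_pep = mkHits("c1"), pfam = mkHits("c2")))
  sel <- selectFinal(ctgs, orfs, ev)
  # c3 has an ORF but no evidence; c4 evidence but no ORF
  expect_setequal(names(sel$final), c("c1", "c2"))
  expect_equal(sel$coreCount, 1L)
  expect_equal(unname(sel$perSource["agam_pep"]), 2L)
  expect_equal(unname(sel$perSource["pfam"]), 1L)
  expect_error(buildEvidenceTable(list(badTag = mkHits("c1"))), "badTag")
})

test_that("evidence respects the e-value cutoff", {
  h <- data.frame(queryId = c("a", "b"), evalue = c(1e-7, 1e-5))
  ev <- buildEvidenceTable(list(pfam = h))
  expect_equal(names(ev), "a")
})

test_that("n50 matches its definition on examples and random inputs", {
  expect_equal(n50(c(4, 3, 3, 2, 2, 2)), 3)
  expect_equal(n50(777), 777)
  expect_equal(n50(c(1000, 500, 500)), 1000)
  expect_error(n50(numeric(0)))
  set.seed(54)
  for (i in 1:20) {
    lens <- sample(1:5000, sample(1:100, 1), replace = TRUE)
    expect_equal(n50(lens), bruteN50(lens))
    expect_equal(n50(sample(lens)), n50(lens))   # permutation invariant
  }
})
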