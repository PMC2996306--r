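test_that("global alignment matches hand-computable scores", {
  s30 <- randDna(30)
  aln <- globalAlign(c(a = s30), c(b = s30))
  expect_equal(aln@rawScore, 150)
  expect_equal(aln@pDiff, 0)
  expect_equal(aln@normScore, 100)
  aln2 <- globalAlign(c(a = "ACGT"), c(b = "ACGA"))
  expect_equal(aln2@rawScore, 11)        # 3 matches x5, 1 mismatch -4
  # empty subject: forced all-gap alignment
  aln3 <- globalAlign(c(a = "ACGTACGT"), c(b = ""))
  expect_equal(aln3@rawScore, -10 - 7 * 1)
  expect_equal(aln3@alignedB, strrep("-", 8))
  expect_error(globalAlign(c(a = "ACGT"), c(b = "MKV")), "alphabet")
})

test_that("global alignment equals the exhaustive-enumeration oracle on short sequences", {
  set.seed(31)
  cases <- list(c("ACGT", "ACGA"), c("AAAA", "AA"), c("ACGTAC", "AGTAC"))
  for (n in c(5, 6, 8)) cases <- c(cases, list(c(randDna(n), randDna(n))))
  for (cs in cases) {
    got <- globalAlign(c(a = cs[1]), c(b = cs[2]))@rawScore
    want <- bruteGlobalScore(cs[1], cs[2])
    expect_equal(got, want, label = paste(cs, collapse = " vs "))
  }
})

test_that("six-frame translation follows the standard code with strand symmetry", {
  expect_equal(sixFrameTranslate("ATGAAATAA")[["F1"]], "MK*")
  s <- randDna(100)
  fw <- sixFrameTranslate(s)
  rv <- sixFrameTranslate(txForge:::.rc1(s))
  expect_equal(unname(fw[c("F1", "F2", "F3")]),
               unname(rv[c("R1", "R2", "R3")]))
  # 8-nt input, frame +3: two complete codons
  expect_equal(nchar(sixFrameTranslate("ATGAAATT")[["F3"]]), 2L)
  # N codons become X, never stops
  expect_equal(sixFrameTranslate("ATGANATAA")[["F1"]], "MX*")
})

test_that("local search finds exact containments at the right coordinates", {
  set.seed(32)
  q <- randDna(300)
  inner <- substr(q, 51, 250)
  # target is exactly the substring: the HSP is pinned to its position
  hits <- localSearch(c(q1 = q), c(hit = inner, miss = randDna(200)))
  top <- hits[1, ]
  expect_equal(top$targetId, "hit")
  expect_equal(c(top$qStart, top$qEnd), c(51L, 250L))
  expect_equal(c(top$tStart, top$tEnd), c(1L, 200L))
  expect_lt(top$evalue, 1e-6)
  # embedded in random flanks: the HSP must cover the planted substring
  # (local alignment may pick up a few chance matches at the edges)
  t1 <- paste0(randDna(40), inner, randDna(40))
  h2 <- localSearch(c(q1 = q), c(hit = t1))[1, ]
  expect_lte(h2$qStart, 51L)
  expect_gte(h2$qEnd, 250L)
  expect_gt(h2$pctIdentity, 80)
  # self-hit covers the full length
  self <- localSearch(c(q1 = q), c(q1 = q))
  expect_equal(c(self$qStart[1], self$qEnd[1]), c(1L, 300L))
})

test_that("local search returns nothing without a shared seed word", {
  # homopolymer pair sharing no 11-mer on either strand
  hits <- localSearch(c(q = strrep("A", 30)), c(t = strrep("G", 30)))
  expect_equal(nrow(hits), 0L)
})

test_that("nucleotide search is reverse-complement symmetric", {
  set.seed(33)
  q <- randDna(120)
  t <- paste0(randDna(30), substr(q, 21, 100), randDna(30))
  h1 <- localSearch(c(q = q), c(t = t))
  h2 <- localSearch(c(q = txForge:::.rc1(q)), c(t = txForge:::.rc1(t)))
  expect_equal(h1$rawScore[1], h2$rawScore[1])
  expect_equal(h1$evalue[1], h2$evalue[1])
  # a minus-strand hit is flagged and coordinate-normalised
  h3 <- localSearch(c(q = q), c(t = txForge:::.rc1(t)))
  expect_equal(h3$tStrand[1], "-")
  expect_true(h3$tStart[1] <= h3$tEnd[1])
})

test_that("e-values decrease strictly with score at fixed search size", {
  sc <- nucScheme()
  e <- txForge:::.evalue(c(50, 100, 200), 1000, 1e6, sc)
  expect_true(all(diff(e) < 0))
})

test_that("translated search modes report frames and nucleotide coordinates", {
  sim <- simTranscriptome(1, c(300, 300), seed = 34)
  tx <- sim$transcripts[[1]]
  pep <- sim$proteins
  names(pep) <- "pep1"
  hx <- localSearch(c(c1 = tx), pep, mode = "x")
  expect_equal(hx$frame[1], 1L)
  expect_equal(hx$qStart[1], 1L)
  # reverse-complement query hits in a minus frame
  hr <- localSearch(c(c1 = txForge:::.rc1(tx)), pep, mode = "x")
  expect_true(hr$frame[1] < 0)
  # tx mode: protein query vs nucleotide target
  ht <- localSearch(pep, c(c1 = tx), mode = "tx")
  expect_equal(ht$targetId[1], "c1")
  expect_true(ht$tEnd[1] <= nchar(tx))
})
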