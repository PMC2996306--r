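test_that("EST deduplication removes duplicates and contained sequences", {
  set.seed(41)
  a <- randDna(200)
  b <- substr(a, 40, 160)                 # contained in a
  c_ <- randDna(150)
  ests <- c(e1 = a, e2 = a, e3 = b, e4 = c_,
            e5 = txForge:::.rc1(substr(c_, 10, 100)))  # rc containment
  out <- dedupeEsts(ests)
  expect_setequal(names(out), c("e1", "e4"))
  # disjoint sequences all survive
  dis <- c(x = randDna(100), y = randDna(100))
  expect_setequal(names(dedupeEsts(dis)), c("x", "y"))
})

test_that("EST prefilter applies the strict 50 + 3L rule", {
  fakeAln <- function(score) list(score = score)
  c100 <- randDna(100); e200 <- randDna(200)
  expect_false(estPrefilter(c100, e200, fakeAln(350)))   # not greater than
  expect_true(estPrefilter(c100, e200, fakeAln(351)))
  # a perfect 30-nt overlap scores 150 > 140 under the default scheme
  s <- randDna(30)
  aln <- globalAlign(c(a = s), c(b = s))
  expect_true(estPrefilter(s, s, aln))
})

test_that("normalised-score filter discards below 0.7, keeps the boundary", {
  expect_equal(normScoreFilter(c(200, 140, 90)), c(TRUE, TRUE, FALSE))
  expect_equal(normScoreFilter(c(400, 280)), c(TRUE, TRUE))   # 0.7 kept
  expect_equal(normScoreFilter(c(400, 200)), c(TRUE, FALSE))  # 0.5 dropped
  expect_true(normScoreFilter(123))
  expect_true(all(normScoreFilter(rep(50, 4))))
})

test_that("two fragments sharing an EST are rejoined into the full transcript", {
  tx <- simTranscriptome(1, c(700, 800), seed = 42)$transcripts
  L <- nchar(tx[[1]])
  fr <- simFragments(tx, mode = "overlap", overlap = 80)$fragments
  est <- setNames(substr(tx[[1]], 100, L - 100), "est1")
  res <- suppressMessages(estCluster(fr, est))
  joined <- as.character(res$contigs)[provenance(res$contigs) == "est_joined"]
  expect_length(joined, 1L)
  # joined length = left overhang + EST + right overhang
  expect_equal(unname(nchar(joined)), 99 + unname(nchar(est)) + 100)
  expect_equal(unname(joined), unname(tx[[1]]))
  expect_setequal(res$consumed, names(fr))
  expect_equal(res$joins$rule, "est_extend")
})

test_that("a contig identical to its EST joins with zero overhangs", {
  est <- setNames(randDna(400), "e")
  res <- suppressMessages(estCluster(c(c1 = est[[1]]), est))
  joined <- as.character(res$contigs)[1]
  expect_equal(unname(joined), est[[1]])
})

test_that("reverse-complement fragments are oriented before joining", {
  tx <- simTranscriptome(1, c(700, 800), seed = 43)$transcripts
  L <- nchar(tx[[1]])
  fr <- simFragments(tx, mode = "overlap", overlap = 80)$fragments
  fr[2] <- txForge:::.rc1(fr[[2]])
  est <- setNames(substr(tx[[1]], 100, L - 100), "est1")
  res <- suppressMessages(estCluster(fr, est))
  joined <- as.character(res$contigs)[provenance(res$contigs) == "est_joined"]
  expect_equal(unname(joined), unname(tx[[1]]))
})

test_that("contigs failing the group filters pass through unconsumed", {
  tx <- simTranscriptome(1, c(700, 800), seed = 44)$transcripts
  L <- nchar(tx[[1]])
  est <- setNames(substr(tx[[1]], 100, L - 100), "est1")
  good <- c(cGood = tx[[1]])
  weak <- c(cWeak = paste0(substr(tx[[1]], 200, 320), randDna(300)))
  res <- suppressMessages(estCluster(c(good, weak), est))
  expect_false("cWeak" %in% res$consumed)
  expect_true("cWeak" %in% names(res$contigs))
  expect_equal(provenance(res$contigs)[names(res$contigs) == "cWeak"],
               "unchanged")
})

test_that("non-overlapping peptide-group contigs are N-scaffolded from HSP coordinates", {
  set.seed(45)
  # synthetic HSPs at peptide residues 1-50 and 81-130: gap of 30 aa -> 90 Ns
  c1 <- randDna(150); c2 <- randDna(150)
  hits <- data.frame(
    queryId = c("c1", "c2"), targetId = "pep1",
    pctIdentity = 100, alnLen = 50, mismatches = 0, gapOpens = 0,
    qStart = 1L, qEnd = 150L, tStart = c(1L, 81L), tEnd = c(50L, 130L),
    evalue = 1e-30, rawScore = c(250, 240), tStrand = "+",
    frame = c(1L, 1L), stringsAsFactors = FALSE)
  res <- suppressMessages(
    peptideCluster(c(c1 = c1, c2 = c2), c(pep1 = strrep("M", 130)),
                   hits = hits))
  expect_equal(res$joins$rule, "pep_n_scaffold")
  expect_equal(res$joins$nGapLen, 3L * (81L - 50L - 1L))
  joined <- as.character(res$contigs)[1]
  expect_equal(unname(joined), paste0(c1, strrep("N", 90), c2))
  expect_equal(provenance(res$contigs)[1], "n_scaffolded")
  # no sequence loss: all non-N input bases present in the output
  expect_equal(sum(nchar(gsub("N", "", as.character(res$contigs)))),
               nchar(c1) + nchar(c2))
})

test_that("two overlapping peptide-group contigs merge only above norm score 90", {
  sim <- simTranscriptome(1, c(600, 750), seed = 46)
  tx <- sim$transcripts[[1]]
  fr <- simFragments(setNames(tx, "t"), mode = "overlap",
                     overlap = 90)$fragments
  pep <- setNames(sim$proteins[[1]], "pep1")
  res <- suppressMessages(peptideCluster(fr, pep))
  expect_equal(res$joins$rule, "pep_overlap_merge")
  merged <- as.character(res$contigs)[1]
  expect_equal(unname(merged), tx)
  # a noisy overlap (norm score <= 90) is not merged
  f2 <- fr
  ov <- substr(f2[[2]], 1, 90)
  chars <- strsplit(ov, "")[[1]]
  flip <- seq(1, 90, by = 5)
  chars[flip] <- vapply(chars[flip], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "")
  f2[2] <- paste0(paste(chars, collapse = ""), substring(f2[[2]], 91))
  res2 <- suppressMessages(peptideCluster(f2, pep))
  expect_equal(nrow(res2$joins), 0L)
})

test_that("groups of three join transitively only among high-scoring pairs", {
  sim <- simTranscriptome(1, c(900, 990), seed = 47)
  tx <- sim$transcripts[[1]]
  L <- nchar(tx)
  # f1 and f2 overlap heavily; f3 matches the same peptide at a similar
  # score but shares no sequence with either
  f1 <- substr(tx, 1, round(L * 0.45))
  f2 <- substr(tx, round(L * 0.15), round(L * 0.60))
  f3 <- substring(tx, round(L * 0.62))
  pep <- setNames(sim$proteins[[1]], "pep1")
  res <- suppressMessages(
    peptideCluster(c(f1 = f1, f2 = f2, f3 = f3), pep))
  expect_true(any(res$joins$rule == "pep_overlap_merge"))
  parts <- strsplit(res$joins$parts[1], ",")[[1]]
  expect_true(all(c("f1", "f2") %in% parts))
  # consumption is exclusive: every contig appears in at most one join
  allParts <- unlist(strsplit(res$joins$parts, ","))
  expect_equal(anyDuplicated(allParts), 0L)
})
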