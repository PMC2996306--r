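mkSite <- function(pos, ref, counts, depth = sum(unlist(counts)),
                   indels = "", contig = "c1") {
  row <- data.frame(contig = contig, pos = pos, ref = ref,
                    depth = as.integer(depth), A = 0L, C = 0L, G = 0L,
                    T = 0L, N = 0L, indels = indels,
                    stringsAsFactors = FALSE)
  for (b in names(counts)) row[[b]] <- as.integer(counts[[b]])
  row
}

test_that("SND calling reproduces the boundary truth table", {
  sites <- rbind(
    mkSite(1, "A", list(A = 4, C = 2)),              # depth 6, alt 2: called
    mkSite(2, "A", list(A = 4, C = 1)),              # singleton: never
    mkSite(3, "A", list(A = 196, C = 4)),            # depth 200, t = 5
    mkSite(4, "A", list(A = 195, C = 5)),            # depth 200: called
    mkSite(5, "A", list(A = 94, C = 3, G = 3)),      # two alts at t = 3
    mkSite(6, "A", list(A = 3, C = 2)),              # depth 5 < 6
    mkSite(7, "A", list(A = 50, C = 30)))            # clean deep call
  calls <- callSnds(sites)
  expect_equal(calls$pos, c(1L, 4L, 7L))
  expect_equal(calls$alt, c("C", "C", "C"))
  expect_equal(calls$kind, rep("snp", 3))
  expect_equal(calls$altCount[2], 5L)
})

test_that("indel alleles compete with SNPs under the same threshold", {
  sites <- rbind(
    mkSite(1, "A", list(A = 7), depth = 10, indels = "+AG:3"),
    mkSite(2, "A", list(A = 6, C = 2), depth = 10, indels = "-T:2"),
    mkSite(3, "A", list(A = 9), depth = 10, indels = "+A:1"))
  calls <- callSnds(sites)
  expect_equal(calls$pos, 1L)             # site 2: two qualifying alleles
  expect_equal(calls$kind, "indel")
  expect_equal(calls$alt, "+AG")
})

test_that("SND calls are invariant to site order and never below 2 observations", {
  set.seed(71)
  sp <- simPileupSites(5, 200, 12, 0.03, seed = 72)
  calls <- callSnds(sp$sites)
  shuffled <- sp$sites[sample(nrow(sp$sites)), ]
  expect_equal(callSnds(shuffled), calls)
  expect_true(all(calls$altCount >= 2))
  expect_true(all(calls$depth >= 6))
})

test_that("callable length counts positions at depth >= 6", {
  sites <- rbind(mkSite(1:600, "A", list(A = 10)),
                 mkSite(601:1000, "A", list(A = 5)))
  expect_equal(callableLength(sites), 600L)
  expect_equal(callableLength(txForge:::emptyPileup()), 0L)
})

test_that("detection probability is the binomial tail of the caller's threshold", {
  expect_equal(detectProb(6), 57 / 64)
  expect_equal(detectProb(2), 0.25)
  expect_gt(detectProb(200), 0.999)        # deep limit approaches 1
  expect_equal(detectProb(6.4), detectProb(6))   # half-up rounding
  expect_equal(detectProb(6.5), detectProb(7))
  expect_error(detectProb(0.5), "medianDepth")
  # user-supplied correction hook
  expect_equal(detectProb(10, phi = function(d) 0.8), 0.8)
})

test_that("contig diversity divides SNDs by callable length and detection probability", {
  set.seed(73)
  sites <- mkSite(1:1000, "A", list(A = 10))
  callPos <- sample(1000, 19)
  sites$A[callPos] <- 7L
  sites$G[callPos] <- 3L
  calls <- callSnds(sites)
  expect_equal(nrow(calls), 19L)
  div <- contigDiversity(calls, sites)
  expect_equal(div$piRaw, 0.019)
  expect_equal(div$medianDepth, 10)
  expect_equal(div$piAdj, 0.019 / detectProb(10))
  expect_true(div$piAdj >= div$piRaw)
  # explicit ratio example: pi 0.02 at phi 0.8 adjusts to 0.025
  div2 <- contigDiversity(calls, sites, phi = function(d) 0.8)
  expect_equal(div2$piAdj, div2$piRaw / 0.8)
  # zero SNDs
  div0 <- contigDiversity(calls[0, ], sites)
  expect_equal(div0$piRaw, 0)
  expect_equal(div0$piAdj, 0)
})

test_that("RPKM matches its formula and conserves mass", {
  ex <- rpkm(c(g = 400L), c(g = 2000L), totalMapped = 1e7)
  expect_equal(ex$rpkm, 20)
  expect_equal(rpkm(c(g = 0L), c(g = 500L), totalMapped = 100)$rpkm, 0)
  expect_error(rpkm(c(g = 5L), c(g = 0L)), "positive")
  set.seed(74)
  for (i in 1:5) {
    n <- sample(5:50, 1)
    ids <- sprintf("c%03d", seq_len(n))
    counts <- setNames(sample(0:5000, n, TRUE), ids)
    lens <- setNames(sample(200:3000, n, TRUE), ids)
    ex <- rpkm(counts, lens)
    expect_equal(sum(ex$rpkm * ex$lengthBp / 1000), 1e6)
  }
})

test_that("SND calls export as minimal VCF", {
  sites <- rbind(mkSite(10, "A", list(A = 4, C = 3)),
                 mkSite(20, "T", list(T = 8), depth = 10, indels = "+AG:3"))
  calls <- callSnds(sites)
  f <- tempfile(fileext = ".vcf")
  writeSndVcf(calls, f, refSeqs = c(c1 = strrep("T", 30)))
  lines <- readLines(f)
  expect_true(any(startsWith(lines, "##fileformat=VCFv4")))
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2L)
  expect_match(body[2], "T\tTAG")          # anchored insertion
})
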