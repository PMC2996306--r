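protAln <- function(a, b) globalAlign(c(a = a), c(b = b),
                                      scheme = protScheme())

test_that("protein divergence is the square root of the proportion different", {
  p <- strrep("MKVLAETG", 5)
  dv <- proteinDivergence(protAln(p, p))
  expect_equal(dv$pDiff, 0)
  expect_equal(dv$dist, 0)
  expect_equal(dv$identity, 1)
  # 25% of columns differ -> dist 0.5
  a <- strrep("MKVL", 10)
  b <- paste0(strrep("MKVL", 5), strrep("WKVL", 5))  # 5 of 40 differ? no:
  # build an exact 25%-different pair positionally
  av <- strsplit(a, "")[[1]]
  bv <- av
  bv[seq(1, 40, by = 4)] <- "W"
  dv2 <- proteinDivergence(protAln(a, paste(bv, collapse = "")))
  expect_equal(dv2$pDiff, 0.25)
  expect_equal(dv2$dist, 0.5)
  expect_equal(dv2$dist^2, dv2$pDiff)
  # all-different columns
  dv3 <- proteinDivergence(protAln(strrep("K", 10), strrep("D", 10)))
  expect_equal(dv3$dist, 1)
})

test_that("protein distance agrees with seqinr's identity distance", {
  skip_if_not_installed("seqinr")
  set.seed(81)
  a <- paste(sample(c("M","K","V","L","A","E","T","G"), 60, TRUE),
             collapse = "")
  bv <- strsplit(a, "")[[1]]
  flip <- sample(60, 12)
  bv[flip] <- vapply(bv[flip], function(x)
    sample(setdiff(c("D","R","S","P"), x), 1), "")
  b <- paste(bv, collapse = "")
  dv <- proteinDivergence(protAln(a, b))
  sq <- seqinr::dist.alignment(
    structure(list(nb = 2, nam = c("a", "b"),
                   seq = tolower(c(a, b)), com = NA),
              class = "alignment"), matrix = "identity")
  expect_equal(dv$dist, as.numeric(sq), tolerance = 1e-8)
})

test_that("identity filter keeps the 30% boundary", {
  rec <- data.frame(identity = c(0.29, 0.30, 1.0))
  kept <- identityFilter(rec)
  expect_equal(kept$identity, c(0.30, 1.0))
})

test_that("fixed-cutoff binning places boundaries in High and Low", {
  bins <- binDivergence(c(0.138, 0.058, 0.1, 0.2, 0.01), mode = "fixed")
  expect_equal(as.character(bins),
               c("High", "Low", "Intermediate", "High", "Low"))
  expect_true(all(diff(as.integer(
    binDivergence(sort(runif(50)), mode = "fixed"))) >= 0))  # monotone
})

test_that("empirical terciles split distinct values into exact thirds", {
  set.seed(82)
  x <- sample(seq(0.001, 0.999, length.out = 300))
  bins <- binDivergence(x, mode = "terciles")
  expect_equal(as.vector(table(bins)), c(100, 100, 100))
  # n not divisible by 3: bins within +/- 1 of n/3
  y <- runif(100)
  expect_true(all(abs(table(binDivergence(y, mode = "terciles")) -
                        100 / 3) <= 1))
  expect_error(binDivergence(c(0.1, 0.2), mode = "terciles"), "3")
})

test_that("Mann-Whitney comparison matches exact enumeration", {
  res <- groupCompare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  # identical multisets: U = n_a n_b / 2
  res2 <- groupCompare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(res2$U, 8)
  set.seed(83)
  for (i in 1:6) {
    a <- round(runif(sample(3:6, 1)), 6)
    b <- round(runif(sample(3:6, 1)), 6)
    got <- groupCompare(a, b)
    want <- bruteMannWhitney(a, b)
    expect_equal(got$U, want$U, label = paste("U, case", i))
    expect_equal(got$p, want$p, tolerance = 1e-9,
                 label = paste("p, case", i))
  }
})

test_that("exact and approximate Mann-Whitney p-values agree for n >= 20", {
  set.seed(99)
  a <- rnorm(30); b <- rnorm(30, 0.4)
  pExact <- suppressWarnings(
    wilcox.test(a, b, exact = TRUE)$p.value)
  got <- groupCompare(a, b)$p            # exact path (no ties, n_a n_b <= 1e4)
  expect_equal(got, pExact)
  approx <- suppressWarnings(
    wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value)
  expect_lt(abs(approx - pExact) / pExact, 0.1)
})

test_that("a strong shift is detected between groups", {
  set.seed(85)
  hits <- replicate(20, {
    a <- rnorm(100); b <- rnorm(100, 1)
    groupCompare(a, b)$p < 0.001
  })
  expect_gte(mean(hits), 0.99)
})

test_that("chi-squared enrichment matches the textbook statistic", {
  bins <- factor(rep(c("Low", "Intermediate", "High"), times = c(20, 20, 20)),
                 levels = c("Low", "Intermediate", "High"))
  cats <- c(rep(list("flat"), 30), rep(list("skew"), 30))
  res <- categoryEnrichment(bins, cats, minN = 15, expected = "equal")
  # statistic equals sum((O-E)^2/E) with E = n/3 in every tested category
  for (i in seq_len(nrow(res))) {
    obs <- unlist(res[i, c("obsLow", "obsIntermediate", "obsHigh")])
    expectd <- sum(obs) / 3
    expect_equal(res$chi2[i], sum((obs - expectd)^2 / expectd))
    expect_equal(res$p[i], pchisq(res$chi2[i], 2, lower.tail = FALSE))
  }
  # uniform observed counts give chi2 0, p 1
  binsU <- factor(rep(c("Low", "Intermediate", "High"), 10),
                  levels = c("Low", "Intermediate", "High"))
  resU <- categoryEnrichment(binsU, rep(list("u"), 30), expected = "equal")
  expect_equal(resU$chi2, 0)
  expect_equal(resU$p, 1)
  expect_false(resU$significant)
  # fully concentrated: (30,0,0) -> chi2 60
  binsC <- factor(rep("Low", 30), levels = c("Low", "Intermediate", "High"))
  resC <- categoryEnrichment(binsC, rep(list("c"), 30), expected = "equal")
  expect_equal(resC$chi2, 60)
  expect_equal(resC$df, 2L)
  expect_equal(resC$topBin, "Low")
  expect_equal(resC$direction, "enriched")
})

test_that("categories below 15 records are not tested; Bonferroni uses tested count", {
  bins <- factor(rep(c("Low", "Intermediate", "High"), 20),
                 levels = c("Low", "Intermediate", "High"))
  cats <- c(rep(list("big"), 46), rep(list("small"), 14))
  res <- categoryEnrichment(bins, cats, minN = 15, expected = "equal")
  expect_false("small" %in% res$category)
  expect_equal(res$alpha, 0.05 / nrow(res))
})

test_that("the chi-squared test holds its nominal size under the null", {
  set.seed(86)
  nSim <- 4000
  tabs <- rmultinom(nSim, 60, rep(1 / 3, 3))
  bins <- factor(rep(rep(c("Low", "Intermediate", "High"), nSim),
                     times = as.vector(tabs)),
                 levels = c("Low", "Intermediate", "High"))
  cats <- as.list(rep(sprintf("s%05d", seq_len(nSim)), each = 60))
  res <- categoryEnrichment(bins, cats, minN = 15, expected = "equal")
  expect_equal(nrow(res), nSim)
  rate <- mean(res$p < 0.05)
  expect_lt(abs(rate - 0.05), 0.01)
})

test_that("multi-category records contribute to every category", {
  bins <- factor(rep(c("Low", "Intermediate", "High"), 10),
                 levels = c("Low", "Intermediate", "High"))
  cats <- rep(list(c("a", "b")), 30)
  res <- categoryEnrichment(bins, cats, expected = "equal")
  expect_setequal(res$category, c("a", "b"))
  expect_equal(res$n, c(30L, 30L))
})
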