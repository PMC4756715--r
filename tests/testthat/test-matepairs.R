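test_that("an unrearranged genome yields concordant FR pairs with the right spans", {
  lens <- c(chrA = 300000L)
  g <- makeToyGenome(lens, 0.5, seed = 20)
  mp <- simulateMatePairs(g, identityMap(lens), 2000L, seed = 21)
  expect_equal(length(mp), 2000L)
  f <- firstRead(mp); s <- secondRead(mp)
  expect_true(all(as.character(GenomeInfoDb::seqnames(f)) ==
                    as.character(GenomeInfoDb::seqnames(s))))
  expect_true(all(as.character(BiocGenerics::strand(f)) == "+"))
  expect_true(all(as.character(BiocGenerics::strand(s)) == "-"))
  span <- BiocGenerics::end(s) - BiocGenerics::start(f) + 1L
  expect_true(all(span >= 100L))   # truncation bound 2*readLen
})

test_that("concordant span distribution matches the truncated normal (KS)", {
  lens <- c(chrA = 2000000L)
  g <- makeToyGenome(lens, 0.5, seed = 22)
  mp <- simulateMatePairs(g, identityMap(lens), 10000L, seed = 23)
  span <- BiocGenerics::end(secondRead(mp)) -
    BiocGenerics::start(firstRead(mp)) + 1L
  lo <- 100
  ptrunc <- function(x) {
    (stats::pnorm(x, 3000, 300) - stats::pnorm(lo - 0.5, 3000, 300)) /
      (1 - stats::pnorm(lo - 0.5, 3000, 300))
  }
  # +0.5 continuity correction for integer rounding of lengths
  ks <- suppressWarnings(stats::ks.test(span + 0.5, ptrunc))
  expect_gt(ks$p.value, 0.001)
})

test_that("a fragment over a deletion lifts to the expected reference span", {
  # fragment of length 3000 starting 1500 bp before a 10 kb deletion:
  # the reference span grows by exactly the deleted length
  g <- makeToyGenome(c(chrA = 50000), 0.5, seed = 24)
  rr <- applyRearrangements(g, RearrangementEvent("deletion", "chrA",
                                                  10001, 20000))
  l1 <- liftRangeToReference(rr$map, "chrA", 8501L, 8550L)
  l2 <- liftRangeToReference(rr$map, "chrA", 11451L, 11500L)
  expect_equal(l1$start, 8501L)
  expect_equal(l2$end, 21500L)
  expect_equal(l2$end - l1$start + 1L, 13000L)
})

test_that("mate-pair simulation is byte-deterministic under a fixed seed", {
  lens <- c(chrA = 200000L)
  g <- makeToyGenome(lens, 0.5, seed = 25)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  writeBedpe(simulateMatePairs(g, identityMap(lens), 500L, seed = 9), p1)
  writeBedpe(simulateMatePairs(g, identityMap(lens), 500L, seed = 9), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("discordance flagging applies the orientation and span window", {
  mp <- combineMatePairs(
    mpFixture("chr1", 10000L, "+", "chr1", 10000L + 3000L - 50L, "-"),
    mpFixture("chr1", 10000L, "+", "chr1", 10000L + 4200L - 50L, "-"),
    mpFixture("chr1", 10000L, "-", "chr1", 13000L, "+"),
    mpFixture("chr1", 10000L, "+", "chr2", 10000L, "-"))
  fl <- flagDiscordant(mp, insertMean = 3000, insertSd = 300, k = 3)
  expect_equal(length(fl$concordant), 1L)   # span exactly the mean
  expect_equal(length(fl$discordant), 3L)   # long span, RF orientation, inter-chrom
})

test_that("single-linkage clustering matches a brute-force oracle", {
  maxGap <- 1000
  mk <- function(offsets, sample = "s1")
    mpFixture("chr1", 10000L + offsets, "+", "chr1", 50000L + offsets, "+",
              sample = sample)
  mp <- mk(c(0L, 500L, 3000L))
  cl <- clusterDiscordant(mp, maxGap = maxGap, slack = 3800)
  expect_equal(nrow(cl), 2L)
  expect_equal(sort(cl$support), c(1L, 2L))

  # brute-force transitive closure on random offsets
  set.seed(31)
  off <- sort(sample.int(8000L, 9L))
  mp <- mk(off)
  cl <- clusterDiscordant(mp, maxGap = maxGap, slack = 3800)
  adj <- abs(outer(off, off, "-")) <= maxGap
  groups <- seq_along(off)
  for (i in seq_along(off)) for (j in seq_along(off))
    if (adj[i, j]) groups[groups == groups[j]] <- groups[i]
  expect_equal(nrow(cl), length(unique(groups)))
  expect_equal(sort(cl$support), sort(unname(table(groups))),
               ignore_attr = TRUE)

  # identical coordinates, opposite signatures: never merged
  mp2 <- combineMatePairs(
    mpFixture("chr1", 10000L, "+", "chr1", 50000L, "+"),
    mpFixture("chr1", 10000L, "-", "chr1", 50000L, "-"))
  expect_equal(nrow(clusterDiscordant(mp2, maxGap = maxGap, slack = 3800)), 2L)
})

test_that("clustering commutes with sample relabeling", {
  set.seed(32)
  off <- sample.int(30000L, 12L)
  mp1 <- mpFixture("chr1", 10000L + off, "+", "chr1", 60000L + off, "+",
                   sample = rep(c("a", "b", "c"), 4L))
  mp2 <- mpFixture("chr1", 10000L + off, "+", "chr1", 60000L + off, "+",
                   sample = rep(c("x2", "y2", "z2"), 4L))
  c1 <- clusterDiscordant(mp1, maxGap = 1000, slack = 3800)
  c2 <- clusterDiscordant(mp2, maxGap = 1000, slack = 3800)
  expect_equal(c1$support, c2$support)
  expect_equal(c1$bp1Start, c2$bp1Start)
  expect_equal(c1$nSamples, c2$nSamples)
})

test_that("cross-sample clusters are filtered, private ones retained", {
  shared <- combineMatePairs(
    mpFixture("chr1", 10000L, "+", "chr1", 60000L, "+", sample = "s1"),
    mpFixture("chr1", 10100L, "+", "chr1", 60100L, "+", sample = "s2"))
  private <- combineMatePairs(
    mpFixture("chr2", 10000L, "-", "chr2", 60000L, "-", sample = "s1"),
    mpFixture("chr2", 10100L, "-", "chr2", 60100L, "-", sample = "s1"))
  cl <- clusterDiscordant(combineMatePairs(shared, private),
                          maxGap = 1000, slack = 3800)
  expect_equal(nrow(cl), 2L)
  uq <- filterUniqueClusters(cl, minSupport = 2L)
  expect_equal(nrow(uq), 1L)
  expect_equal(uq$sample, "s1")
  expect_equal(uq$chrom1, "chr2")
  # support below the minimum is dropped even when private
  single <- mpFixture("chr3", 1000L, "+", "chr3", 90000L, "-", sample = "s1")
  cl1 <- clusterDiscordant(single, maxGap = 1000, slack = 3800)
  expect_equal(nrow(filterUniqueClusters(cl1, minSupport = 2L)), 0L)
})

test_that("signature classification is total and matches the orientation table", {
  tab <- classifySignature(c("tail", "head", "tail", "head"),
                           c("head", "tail", "tail", "head"))
  expect_equal(tab$svType, c("deletion", "tandem_duplication",
                             "inversion", "inversion"))
  expect_equal(tab$orientationLabel, c("tail-to-head", "head-to-tail",
                                       "tail-to-tail", "head-to-head"))
  expect_equal(classifySignature("tail", "head", interChrom = TRUE)$svType,
               "translocation")
  expect_error(classifySignature("tail", NA), "unresolved")
})

test_that("binned copy ratios behave under symmetry, scaling and conservation", {
  lens <- c(chrA = 100000L)
  mids <- seq(2050L, 98000L, by = 50L)
  ctl <- midpointPairs("chrA", mids)
  bins <- binnedCopyRatio(ctl, ctl, 10000L, lens)
  expect_true(all(abs(bins$log2_ratio) < 1e-12))
  expect_equal(sum(bins$case_count), length(mids))

  # uniform doubling cancels through depth normalization (up to the
  # pseudocount, negligible at these counts)
  case2 <- combineMatePairs(ctl, ctl)
  bins2 <- binnedCopyRatio(case2, ctl, 10000L, lens)
  expect_true(all(abs(bins2$log2_ratio) < 0.01))

  expect_error(binnedCopyRatio(ctl, ctl[0], 10000L, lens), "control")
})

test_that("a one-extra-copy region shows log2(3/2) against the control", {
  lens <- c(chrA = 1000000L)
  mids <- seq(500L, 999500L, by = 250L)
  ctl <- midpointPairs("chrA", mids)
  # heterozygous gain over [400001, 450000]: 50% extra fragments there
  gainMids <- seq(400001L, 450000L, by = 500L)
  case <- combineMatePairs(midpointPairs("chrA", mids),
                           midpointPairs("chrA", gainMids))
  bins <- binnedCopyRatio(case, ctl, 10000L, lens)
  inEvent <- BiocGenerics::start(bins) >= 400001L &
    BiocGenerics::end(bins) <= 450000L
  expect_lt(abs(mean(bins$log2_ratio[inEvent]) - log2(3 / 2)), 0.05)
})

test_that("a planted deletion is recovered end to end at 20x coverage", {
  lens <- c(chrA = 200000L)
  g <- makeToyGenome(lens, 0.45, seed = 33)
  rr <- applyRearrangements(g, RearrangementEvent("deletion", "chrA",
                                                  80001, 120000))
  case <- simulateMatePairs(rr$genome, rr$map,
                            round(20 * sum(genomeLengths(rr$genome)) / 3000),
                            sample = "case", seed = 34)
  ctl <- simulateMatePairs(rr$reference, identityMap(genomeLengths(rr$reference)),
                           round(20 * 200000 / 3000), sample = "control",
                           seed = 35)
  fl <- flagDiscordant(combineMatePairs(case, ctl))
  calls <- classifyClusters(filterUniqueClusters(clusterDiscordant(fl$discordant)))
  hit <- calls$svType == "deletion" & calls$sample == "case" &
    calls$bp1Start <= 80000L & calls$bp1End >= 80000L &
    calls$bp2Start <= 120001L & calls$bp2End >= 120001L
  expect_equal(sum(hit), 1L)
  expect_equal(calls$orientationLabel[hit], "tail-to-head")
})
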