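test_that("reciprocal overlap obeys its defining arithmetic", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  expect_equal(reciprocalOverlap(a, a), 1)
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250))
  expect_equal(reciprocalOverlap(a, b), 0.5)
  expect_equal(reciprocalOverlap(b, a), 0.5)   # symmetric
  d <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 600))
  expect_equal(reciprocalOverlap(a, d), 0)
  other <- GenomicRanges::GRanges("chr2", IRanges::IRanges(101, 200))
  expect_equal(reciprocalOverlap(a, other), 0)
})

test_that("the uniqueness filter removes cross-clone matches inclusively at 60%", {
  # same-type calls at RO 0.8 in two clones: both removed
  calls <- cnaFixture(c("c1", "c2", "c3"), c("chr1", "chr1", "chr2"),
                      c(1001, 1201, 5000), c(2000, 2200, 9000),
                      c("gain", "gain", "loss"))
  fu <- filterUniqueCnas(calls)
  expect_equal(fu$unique$sample, "c3")
  expect_equal(length(fu$removed), 2L)

  # boundary: RO exactly 0.60 removed, 0.59 retained
  ro60 <- c(cnaFixture("c1", "chr1", 1, 1000, "gain"),
            cnaFixture("c2", "chr1", 401, 1400, "gain"))
  expect_length(filterUniqueCnas(ro60, 0.6)$unique, 0L)
  ro59 <- c(cnaFixture("c1", "chr1", 1, 1000, "gain"),
            cnaFixture("c2", "chr1", 411, 1410, "gain"))
  expect_length(filterUniqueCnas(ro59, 0.6)$unique, 2L)

  # different types never match each other
  mixed <- c(cnaFixture("c1", "chr1", 1, 1000, "gain"),
             cnaFixture("c2", "chr1", 51, 1050, "loss"))
  expect_length(filterUniqueCnas(mixed, 0.6)$unique, 2L)

  # same clone repeats do not remove each other
  sameClone <- c(cnaFixture("c1", "chr1", 1, 1000, "gain"),
                 cnaFixture("c1", "chr1", 1, 1000, "gain"))
  expect_length(filterUniqueCnas(sameClone, 0.6)$unique, 2L)
})

test_that("the uniqueness filter matches the brute-force oracle and is stable", {
  set.seed(41)
  n <- 40L
  calls <- cnaFixture(sample(paste0("c", 1:6), n, TRUE),
                      sample(c("chr1", "chr2"), n, TRUE),
                      s <- sample.int(50000L, n),
                      s + sample(500:5000, n, TRUE),
                      sample(c("gain", "loss"), n, TRUE))
  fu <- filterUniqueCnas(calls)
  oracle <- bruteUniqueFilter(calls)
  keys <- function(gr) sort(paste(gr$sample,
                                  as.character(GenomeInfoDb::seqnames(gr)),
                                  BiocGenerics::start(gr),
                                  BiocGenerics::end(gr), gr$cna_type))
  expect_equal(keys(fu$unique), keys(calls[oracle]))

  # invariant under clone reordering
  perm <- sample.int(n)
  fu2 <- filterUniqueCnas(calls[perm])
  expect_equal(sort(BiocGenerics::start(fu2$unique)),
               sort(BiocGenerics::start(fu$unique)))
  # idempotent
  fu3 <- filterUniqueCnas(fu$unique)
  expect_equal(length(fu3$unique), length(fu$unique))
  expect_length(fu3$removed, 0L)
})

test_that("the closed-form enrichment probability equals exhaustive enumeration", {
  expect_equal(exactEnrichmentProb(5, 5, 0), 1)
  configs <- list(c(1, 1, 1), c(3, 3, 2), c(4, 8, 2), c(6, 6, 3), c(5, 5, 5),
                  c(6, 6, 6), c(2, 10, 1))
  for (cf in configs) {
    expect_equal(exactEnrichmentProb(cf[1], cf[2], cf[3]),
                 enumEnrichment(cf[1], cf[2], cf[3]),
                 tolerance = 1e-12, label = paste(cf, collapse = "/"))
    # independent combinatorial identity C(n-k, nCase-k)/C(n, nCase)
    n <- cf[1] + cf[2]
    expect_equal(exactEnrichmentProb(cf[1], cf[2], cf[3]),
                 choose(n - cf[3], cf[1] - cf[3]) / choose(n, cf[1]),
                 tolerance = 1e-12)
  }
  # per-set vectors multiply
  expect_equal(exactEnrichmentProb(c(3, 3), c(3, 3), c(1, 2)),
               enumEnrichment(3, 3, 1) * enumEnrichment(3, 3, 2),
               tolerance = 1e-12)
  expect_warning(p0 <- exactEnrichmentProb(2, 2, 3), "probability 0")
  expect_equal(p0, 0)
})

test_that("Monte-Carlo permutation agrees with the exact probability", {
  clones <- data.frame(clone = paste0("k", 1:6),
                       group = rep(c("case", "control"), each = 3L),
                       set = 1L)
  calls <- cnaFixture(c("k1", "k2"), "chr1", c(1000, 9000),
                      c(2000, 10000), "loss")
  cohort <- CloneCohort(clones, calls)
  pr <- permutationEnrichment(cohort, calls, nPerm = 2e4, scheme = "joint",
                              seed = 5)
  expect_equal(pr@analyticP, 0.2)   # (3/6)*(2/5), verified by enumeration
  expect_lt(abs(pr@pValue - 0.2), 4 * sqrt(0.2 * 0.8 / 2e4))

  # single case vs single control, one positive clone: p -> 1/2 exactly
  c2 <- data.frame(clone = c("a", "b"), group = c("case", "control"), set = 1L)
  call1 <- cnaFixture("a", "chr1", 100, 200, "gain")
  pr2 <- permutationEnrichment(CloneCohort(c2, call1), call1, nPerm = 2e4,
                               scheme = "joint", seed = 6)
  expect_equal(pr2@analyticP, 0.5)
  expect_lt(abs(pr2@pValue - 0.5), 4 * sqrt(0.25 / 2e4))

  empty <- cnaFixture(character(0), character(0), integer(0), integer(0),
                      character(0))
  expect_error(permutationEnrichment(cohort, empty, nPerm = 10),
               "undefined statistic")
})

test_that("the probe-threshold caller implements the inclusive run rule", {
  mkProfile <- function(lr) data.frame(chrom = "chr1",
                                       position = seq_along(lr) * 1000L,
                                       log2_ratio = lr)
  # 5 consecutive probes at the single-copy-gain level, flanked by 0
  calls <- callAcghAberrations(mkProfile(c(0, 0, rep(0.585, 5), 0, 0)))
  expect_length(calls, 1L)
  expect_equal(calls$cna_type, "gain")
  expect_equal(BiocGenerics::start(calls), 3000L)
  expect_equal(BiocGenerics::end(calls), 7000L)
  expect_equal(calls$n_probes, 5L)

  # 4 aberrant probes never qualify, however strong
  expect_length(callAcghAberrations(mkProfile(c(0, rep(0.9, 4), 0))), 0L)

  # inclusive threshold: exactly -0.30 for 6 probes is a loss
  calls <- callAcghAberrations(mkProfile(c(0, rep(-0.30, 6), 0)))
  expect_equal(calls$cna_type, "loss")
  expect_equal(calls$n_probes, 6L)

  # a non-aberrant probe breaks the run
  expect_length(callAcghAberrations(
    mkProfile(c(rep(0.585, 3), 0, rep(0.585, 3)))), 0L)

  unsorted <- data.frame(chrom = "chr1", position = c(2000L, 1000L),
                         log2_ratio = c(0, 0))
  expect_error(callAcghAberrations(unsorted), "input error")
})

test_that("the caller agrees with a brute-force run scanner on noisy profiles", {
  set.seed(51)
  probes <- data.frame(
    chrom = rep(c("chr1", "chr2"), each = 300L),
    position = rep(seq_len(300L) * 1000L, 2L),
    log2_ratio = sample(c(0, 0.45, -0.35), 600L, TRUE,
                        prob = c(0.6, 0.2, 0.2)))
  got <- callAcghAberrations(probes)
  want <- bruteAcgh(probes)
  expect_equal(length(got), nrow(want))
  expect_equal(BiocGenerics::start(got), want$start)
  expect_equal(BiocGenerics::end(got), want$end)
  expect_equal(got$cna_type, want$cna_type)
})

test_that("noise-free profiles recover planted events snapped to probes", {
  lens <- c(chr1 = 2e6, chr2 = 2e6)
  truth <- cnaFixture(c("x", "x"), c("chr1", "chr2"),
                      c(300001L, 1000001L), c(600000L, 1400000L),
                      c("gain", "loss"))
  pp <- simulateProbeProfile(truth, lens, spacing = 25e3, noiseSd = 0,
                             seed = 1)
  calls <- callAcghAberrations(pp)
  expect_length(calls, 2L)
  for (i in 1:2) {
    tr <- truth[i]
    call <- calls[as.character(GenomeInfoDb::seqnames(calls)) ==
                    as.character(GenomeInfoDb::seqnames(tr))]
    # call spans first to last probe inside the truth interval
    inProbes <- pp$position[pp$chrom == as.character(GenomeInfoDb::seqnames(tr)) &
                              pp$position >= BiocGenerics::start(tr) &
                              pp$position <= BiocGenerics::end(tr)]
    expect_equal(BiocGenerics::start(call), min(inProbes))
    expect_equal(BiocGenerics::end(call), max(inProbes))
    expect_equal(call$cna_type, tr$cna_type)
  }
})

test_that("fragile-site annotation tests breakpoints as points", {
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(851, 2000))
  sites$name <- "FS1"
  cna <- cnaFixture("c1", "chr1", 101, 900, "loss")
  fo <- fragileOverlap(cna, sites)
  expect_equal(fo$nOverlap, 1L)
  expect_equal(unlist(fo$annotated$fragile_sites), "FS1")
  # span crosses the site but neither breakpoint is inside: no overlap
  spanOnly <- cnaFixture("c1", "chr1", 100, 3000, "loss")
  expect_equal(fragileOverlap(spanOnly, sites)$nOverlap, 0L)
  # empty catalog
  empty <- GenomicRanges::GRanges()
  empty$name <- character(0)
  expect_equal(fragileOverlap(cna, empty)$nOverlap, 0L)
})
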