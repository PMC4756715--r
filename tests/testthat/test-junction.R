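# junction reads are built from explicit P / X / Q blocks so expected split
# counts come from construction, independently of the package's generator
randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

test_that("a junction with no shared bases has exactly one split", {
  set.seed(1)
  P <- randSeq(30); Q <- randSeq(30)
  ctxL <- randSeq(100); ctxR <- randSeq(100)
  # force boundary mismatches so no chance homology arises
  P <- paste0(substr(P, 1, 29), "A"); Q <- paste0("C", substr(Q, 2, 30))
  leftFlank <- paste0(ctxL, P, "G")      # continuation G != C = Q[1]
  rightFlank <- paste0("T", Q, ctxR)     # pre-context T != A = P[30]
  read <- paste0(P, Q)
  loc <- locateJunction(read, leftFlank, rightFlank)
  expect_equal(loc$splits, 30L)
  mh <- microhomology(read, loc)
  expect_equal(mh$mhLen, 0L)
  expect_equal(mh$mhSeq, "")
  expect_equal(classifyJunction(mh), "blunt")
})

test_that("4 shared junction bases give 5 admissible splits", {
  set.seed(2)
  X <- "TTAG"
  P <- paste0(randSeq(29), "C")   # P ends C != G (break below)
  Q <- paste0(randSeq(29), "A")
  Q <- paste0("A", substr(Q, 2, 30))
  leftFlank <- paste0(randSeq(80), P, X, "C")  # left locus: ...P X, continues C
  rightFlank <- paste0(randSeq(80), "G", X, Q, randSeq(20)) # right: ...G X Q...
  # read continues after X with Q[1] = "A" != "C"; pre-X context "G" != "C"
  read <- paste0(P, X, Q)
  loc <- locateJunction(read, leftFlank, rightFlank)
  expect_length(loc$splits, 5L)
  expect_equal(loc$splits, 30:34)
  mh <- microhomology(read, loc)
  expect_equal(mh$mhLen, 4L)
  expect_equal(mh$mhSeq, "TTAG")
  expect_equal(classifyJunction(mh, mhThreshold = 2L), "microhomology-mediated")
})

test_that("a non-templated insertion is reported when no exact split exists", {
  set.seed(3)
  P <- paste0(randSeq(29), "A")
  Q <- paste0("C", randSeq(29))
  leftFlank <- paste0(randSeq(80), P, "T")   # continuation T != ins[1] = G
  rightFlank <- paste0("A", Q, randSeq(80))  # pre-context A != ins[last] = T
  read <- paste0(P, "GT", Q)
  loc <- locateJunction(read, leftFlank, rightFlank)
  expect_equal(loc$insertedSeq, "GT")
  mh <- microhomology(read, loc)
  expect_equal(mh$mhLen, 0L)
  expect_equal(mh$insertedSeq, "GT")
  expect_equal(classifyJunction(mh), "insertion")
})

test_that("junction location is invariant under global reverse-complement", {
  set.seed(4)
  for (m in c(0L, 3L, 7L)) {
    g <- makeToyGenome(c(chrA = 20000), 0.5, seed = 40L + m)
    rr <- applyRearrangements(g, RearrangementEvent("deletion", "chrA",
                                                    8001, 12000, mhLen = m))
    ob <- makeJunctionObservation(rr$reference, rr$junctions[1, ])
    fwd <- analyzeJunction(ob)
    rcObs <- list(read = aneuscan:::.revcomp(ob$read),
                  leftFlank = aneuscan:::.revcomp(ob$rightFlank),
                  rightFlank = aneuscan:::.revcomp(ob$leftFlank))
    rev <- analyzeJunction(rcObs)
    expect_equal(rev$mhLen, fwd$mhLen)
    expect_equal(rev$mhSeq, aneuscan:::.revcomp(fwd$mhSeq))
  }
})

test_that("unrelated flanks raise a no-junction error", {
  set.seed(5)
  read <- randSeq(80)
  expect_error(locateJunction(read, randSeq(200), randSeq(200)),
               "no junction")
  expect_error(locateJunction(randSeq(20), randSeq(200), randSeq(200),
                              minAnchor = 15L), "shorter")
})

test_that("detected microhomology equals the brute-force shared substring", {
  # independent oracle: the maximal d with identical oriented junction-
  # adjacent bases on both loci, computed directly from the reference
  set.seed(6)
  for (trial in 1:25) {
    m <- trial %% 9L
    g <- makeToyGenome(c(chrA = 25000), 0.5, seed = 600L + trial)
    rr <- applyRearrangements(g, RearrangementEvent("tandem_duplication",
                                                    "chrA", 9001, 16000,
                                                    mhLen = m))
    ref <- as.character(rr$reference[[1]])
    s <- 9001L; e <- 16000L
    d <- 0L
    # shift the dup junction split: d bases before the copy-2 start equal
    # the d bases at the copy-1 end (and extensions beyond must fail)
    while (substr(ref, s - d - 1L, s - d - 1L) ==
           substr(ref, e - d, e - d) && d < 50L) d <- d + 1L
    u <- 0L
    while (substr(ref, s + u, s + u) == substr(ref, e + 1L + u, e + 1L + u) &&
           u < 50L) u <- u + 1L
    oracle <- d + u
    ob <- makeJunctionObservation(rr$reference, rr$junctions[1, ])
    res <- analyzeJunction(ob)
    expect_equal(res$mhLen, oracle)
    expect_equal(res$mhLen, m)   # engineering keeps it at the planted value
  }
})
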