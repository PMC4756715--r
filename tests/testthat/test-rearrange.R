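test_that("deletion geometry and coordinate lifting are exact", {
  g <- makeToyGenome(c(chrA = 50000), 0.5, seed = 3)
  rr <- applyRearrangements(g, RearrangementEvent("deletion", "chrA",
                                                  10001, 20000))
  expect_equal(unname(genomeLengths(rr$genome)[["chrA"]]), 40000L)
  # first base after the deletion: derived 10001 maps to reference 20001
  lift <- liftToReference(rr$map, "chrA", c(10000L, 10001L))
  expect_equal(lift$pos, c(10000L, 20001L))
  expect_equal(lift$strand, c("+", "+"))
})

test_that("tandem duplication equals the concatenation construction", {
  g <- makeToyGenome(c(chrA = 50000), 0.5, seed = 4)
  rr <- applyRearrangements(g, RearrangementEvent("tandem_duplication",
                                                  "chrA", 10001, 20000))
  ref <- as.character(rr$reference[[1]])
  want <- paste0(substr(ref, 1, 20000), substr(ref, 10001, 50000))
  expect_identical(as.character(rr$genome[[1]]), want)
  expect_equal(unname(genomeLengths(rr$genome)[["chrA"]]), 60000L)
  # the junction joins reference base 20000 (tail of copy 1) to reference
  # base 10001 (head of copy 2): the head-to-tail signature
  jx <- rr$junctions
  expect_equal(jx$p, 20000L)
  expect_equal(jx$q, 10001L)
  expect_equal(junctionSides(RearrangementEvent("tandem_duplication", "chrA",
                                                10001, 20000)),
               c("head", "tail"))
})

test_that("inversion conserves base content and flips orientation", {
  g <- makeToyGenome(c(chrA = 40000), 0.45, seed = 5)
  rr <- applyRearrangements(g, RearrangementEvent("inversion", "chrA",
                                                  10001, 20000))
  # an in-place reverse complement conserves complement-pair content
  # (A+T and C+G counts) and the total length
  f0 <- Biostrings::letterFrequency(rr$reference[[1]], c("A", "C", "G", "T"))
  f1 <- Biostrings::letterFrequency(rr$genome[[1]], c("A", "C", "G", "T"))
  expect_equal(f0[["A"]] + f0[["T"]], f1[["A"]] + f1[["T"]])
  expect_equal(f0[["C"]] + f0[["G"]], f1[["C"]] + f1[["G"]])
  expect_equal(unname(genomeLengths(rr$genome)[["chrA"]]), 40000L)
  # the inverted span is exactly the reverse complement of the reference span
  ref <- as.character(rr$reference[[1]])
  der <- as.character(rr$genome[[1]])
  expect_identical(substr(der, 10001, 20000),
                   aneuscan:::.revcomp(substr(ref, 10001, 20000)))
  lift <- liftToReference(rr$map, "chrA", 10001L)
  expect_equal(lift$pos, 20000L)
  expect_equal(lift$strand, "-")
})

test_that("length changes by exactly the event span", {
  g <- makeToyGenome(c(chrA = 80000), 0.5, seed = 6)
  for (m in c(0L, 3L)) {
    del <- applyRearrangements(g, RearrangementEvent("deletion", "chrA",
                                                     30001, 45000, mhLen = m))
    expect_equal(unname(genomeLengths(del$genome)[["chrA"]]), 80000L - 15000L)
    dup <- applyRearrangements(g, RearrangementEvent("tandem_duplication",
                                                     "chrA", 30001, 45000,
                                                     mhLen = m))
    expect_equal(unname(genomeLengths(dup$genome)[["chrA"]]), 80000L + 15000L)
  }
})

test_that("coordinate lifts are invertible on non-junction positions", {
  g <- makeToyGenome(c(chrA = 60000, chrB = 30000), 0.5, seed = 8)
  rr <- applyRearrangements(g, list(
    RearrangementEvent("deletion", "chrA", 10001, 15000),
    RearrangementEvent("inversion", "chrA", 30001, 40000),
    RearrangementEvent("tandem_duplication", "chrB", 5001, 9000)))
  set.seed(99)
  for (ch in names(genomeLengths(rr$genome))) {
    pos <- sample.int(genomeLengths(rr$genome)[[ch]], 40L)
    lift <- liftToReference(rr$map, rep(ch, 40L), pos)
    back <- mapToDerived(rr$map, lift$chrom, lift$pos)
    for (i in seq_along(pos)) {
      hits <- back[back$query == i, ]
      expect_true(any(hits$dchrom == ch & hits$dpos == pos[i]))
    }
  }
})

test_that("whole-chromosome gain appends a distinguishable full copy", {
  g <- makeToyGenome(c(chrA = 30000, chrB = 20000), 0.5, seed = 9)
  rr <- applyRearrangements(g, RearrangementEvent("whole_chromosome_gain",
                                                  "chrB"))
  lens <- genomeLengths(rr$genome)
  expect_true("chrB_gain" %in% names(lens))
  expect_equal(unname(lens[["chrB_gain"]]), 20000L)
  expect_identical(as.character(rr$genome[["chrB_gain"]]),
                   as.character(rr$reference[["chrB"]]))
  # no novel junction: invisible to junction analysis
  expect_equal(nrow(rr$junctions), 0L)
})

test_that("overlapping events in one call are rejected", {
  g <- makeToyGenome(c(chrA = 50000), 0.5, seed = 10)
  expect_error(applyRearrangements(g, list(
    RearrangementEvent("deletion", "chrA", 10001, 20000),
    RearrangementEvent("inversion", "chrA", 15000, 30000))),
    "sequentially")
})

test_that("engineered microhomology survives the junction round trip", {
  # the simulator plants (event kind, mh) and junction analysis must
  # recover mh exactly, over 200 junctions with mh in 0..10
  set.seed(17)
  kinds <- c("deletion", "tandem_duplication", "inversion")
  count <- 0L
  for (trial in seq_len(200L)) {
    kind <- kinds[(trial %% 3L) + 1L]
    m <- trial %% 11L
    g <- makeToyGenome(c(chrA = 30000), 0.45, seed = 1000L + trial)
    rr <- applyRearrangements(g, RearrangementEvent(kind, "chrA",
                                                    10001, 20000, mhLen = m))
    ob <- makeJunctionObservation(rr$reference, rr$junctions[1, ])
    res <- analyzeJunction(ob)
    expect_equal(res$mhLen, m)
    count <- count + 1L
  }
  expect_equal(count, 200L)
})
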