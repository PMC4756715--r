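# Shared fixture builders -- everything is generated in code at test time.

# a MatePairSet from plain vectors (1-based read starts, fixed read length)
mpFixture <- function(chrom1, start1, strand1, chrom2, start2, strand2,
                      sample = "s1", readLen = 50L) {
  g1 <- GenomicRanges::GRanges(chrom1,
          IRanges::IRanges(start1, width = readLen), strand = strand1)
  g2 <- GenomicRanges::GRanges(chrom2,
          IRanges::IRanges(start2, width = readLen), strand = strand2)
  MatePairSet(g1, g2, sample = sample)
}

# pairs whose fragment midpoints are exactly `mid`, outer span 3000, FR
midpointPairs <- function(chrom, mid, sample = "s1") {
  mpFixture(chrom, mid - 1500L + 1L, "+", chrom, mid + 1500L - 50L, "-",
            sample = sample)
}

# CNA call GRanges from vectors
cnaFixture <- function(sample, chrom, start, end, type,
                       copy_number = NA_integer_, source = "test") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  gr$sample <- rep_len(sample, length(gr))
  gr$cna_type <- rep_len(type, length(gr))
  gr$copy_number <- rep_len(as.integer(copy_number), length(gr))
  gr$source <- rep_len(source, length(gr))
  gr
}

# independent all-pairs brute-force reciprocal-overlap filter
bruteUniqueFilter <- function(calls, minRo = 0.6) {
  n <- length(calls)
  removed <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (calls$sample[i] == calls$sample[j]) next
    if (calls$cna_type[i] != calls$cna_type[j]) next
    if (as.character(GenomeInfoDb::seqnames(calls)[i]) !=
        as.character(GenomeInfoDb::seqnames(calls)[j])) next
    o <- min(BiocGenerics::end(calls)[i], BiocGenerics::end(calls)[j]) -
      max(BiocGenerics::start(calls)[i], BiocGenerics::start(calls)[j]) + 1L
    if (o <= 0L) next
    ro <- min(o / BiocGenerics::width(calls)[i], o / BiocGenerics::width(calls)[j])
    if (ro >= minRo) removed[i] <- TRUE
  }
  which(!removed)
}

# exhaustive label-permutation oracle: probability that all `k` positive
# clones (taken to be the first k) receive a case label, enumerating every
# nCase-subset of n = nCase + nControl clones
enumEnrichment <- function(nCase, nControl, k) {
  n <- nCase + nControl
  if (k == 0L) return(1)
  subsets <- utils::combn(n, nCase)
  mean(apply(subsets, 2L, function(s) all(seq_len(k) %in% s)))
}

# independent run-scanner for the aCGH threshold caller
bruteAcgh <- function(probes, ampThresh = 0.39, delThresh = -0.30,
                      minRun = 5L) {
  out <- list()
  for (ch in unique(probes$chrom)) {
    sub <- probes[probes$chrom == ch, ]
    for (type in c("gain", "loss")) {
      ab <- if (type == "gain") sub$log2_ratio >= ampThresh
            else sub$log2_ratio <= delThresh
      i <- 1L
      while (i <= length(ab)) {
        if (ab[i]) {
          j <- i
          while (j < length(ab) && ab[j + 1L]) j <- j + 1L
          if (j - i + 1L >= minRun)
            out[[length(out) + 1L]] <- data.frame(chrom = ch,
              start = sub$position[i], end = sub$position[j], cna_type = type)
          i <- j + 1L
        } else i <- i + 1L
      }
    }
  }
  if (length(out)) {
    df <- do.call(rbind, out)
    df[order(df$chrom, df$start), ]
  } else data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), cna_type = character(0))
}

# identity coordinate map over a reference genome
identityMap <- function(lens) identityCoordinateMap(lens)

# standard small cohort used across tests (paper-scale design)
cohortFixture <- function(seed = 42L, fragileFraction = 8 / 12,
                          deNovoEvents = 12L, deNovoPositiveClones = 8L) {
  lens <- stats::setNames(rep(60e6, 7), paste0("chr", 1:7))
  sites <- makeFragileCatalog(lens, 15L, seed = seed + 1L)
  co <- simulateClonalCohort(lens, sites = sites, seed = seed,
                             fragileFraction = fragileFraction,
                             deNovoEvents = deNovoEvents,
                             deNovoPositiveClones = deNovoPositiveClones)
  c(co, list(sites = sites, lens = lens))
}
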