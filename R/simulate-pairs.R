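#' Simulate a mapped mate-pair library from a derived genome
#'
#' Fragments start uniformly over the derived genome; fragment length is
#' Normal(`insertMean`, `insertSd`) rounded to integer bp and truncated at
#' `2 * readLen`. The two terminal `readLen` segments of each fragment are
#' lifted through the coordinate map to reference coordinates, in
#' forward/reverse (facing) orientation: the lower-coordinate read on `+`,
#' its mate on `-`. Fragments spanning a rearrangement junction therefore
#' acquire discordant reference geometry, while a read falling *across* a
#' junction cannot be placed and its whole pair is dropped (the count is
#' reported via `attr(, "droppedPairs")` and a message) -- discordant pairs,
#' not split reads, carry the signal here.
#'
#' @param derived derived genome `DNAStringSet` (only lengths are used).
#' @param map [CoordinateMap-class] from derived to reference.
#' @param nPairs number of fragments to draw.
#' @param sample sample identifier stamped on every pair.
#' @param insertMean,insertSd insert size model in bp (3 kb libraries
#'   emulated by default; the dispersion of such libraries is a free
#'   parameter, 300 bp by default).
#' @param readLen read length in bp.
#' @param seed integer RNG seed.
#' @return A [MatePairSet-class] in reference coordinates.
#' @export
simulateMatePairs <- function(derived, map, nPairs, sample = "sample1",
                              insertMean = 3000, insertSd = 300,
                              readLen = 50, seed) {
  stopifnot(!missing(seed), nPairs > 0, insertMean > 2 * readLen)
  set.seed(as.integer(seed))
  lens <- genomeLengths(derived)
  lens <- lens[lens >= insertMean + 6 * insertSd + 1]
  if (!length(lens)) stop("no derived chromosome long enough for the insert model")
  chrom <- sample(names(lens), nPairs, replace = TRUE,
                  prob = lens / sum(lens))
  flen <- as.integer(round(stats::rnorm(nPairs, insertMean, insertSd)))
  lo <- as.integer(2 * readLen)
  while (any(bad <- flen < lo))
    flen[bad] <- as.integer(round(stats::rnorm(sum(bad), insertMean, insertSd)))
  maxStart <- lens[chrom] - flen + 1L
  fstart <- as.integer(floor(stats::runif(nPairs, 1, maxStart + 1)))

  r1s <- fstart; r1e <- fstart + as.integer(readLen) - 1L
  r2e <- fstart + flen - 1L; r2s <- r2e - as.integer(readLen) + 1L
  l1 <- liftRangeToReference(map, chrom, r1s, r1e)
  l2 <- liftRangeToReference(map, chrom, r2s, r2e)
  # derived + read keeps the block strand; derived - read flips it
  s1 <- ifelse(l1$strand == "+", "+", "-")
  s2 <- ifelse(l2$strand == "+", "-", "+")
  keep <- !is.na(l1$chrom) & !is.na(l2$chrom)
  nDropped <- sum(!keep)
  if (nDropped)
    .msg("dropped %d junction-straddling read pair(s) of %d", nDropped, nPairs)
  g1 <- GenomicRanges::GRanges(l1$chrom[keep],
          IRanges::IRanges(l1$start[keep], l1$end[keep]), strand = s1[keep])
  g2 <- GenomicRanges::GRanges(l2$chrom[keep],
          IRanges::IRanges(l2$start[keep], l2$end[keep]), strand = s2[keep])
  mp <- MatePairSet(g1, g2, sample = sample,
                    name = paste0(sample, "_", which(keep)))
  attr(mp, "droppedPairs") <- nDropped
  mp
}

#' Synthesize junction reads for all novel junctions of a rearranged genome
#'
#' Convenience wrapper around [makeJunctionObservation()] producing one
#' observation per junction, plus a `DNAStringSet` of the reads suitable for
#' FASTA export.
#'
#' @param rearranged result of [applyRearrangements()].
#' @param readHalf,flankLen,pad see [makeJunctionObservation()].
#' @return list with `observations` (list of junction observations, named
#'   `jxn_<event>_<kind>`) and `reads` (`DNAStringSet`).
#' @export
simulateJunctionReads <- function(rearranged, readHalf = 60, flankLen = 200,
                                  pad = 30) {
  jx <- rearranged$junctions
  obs <- list()
  if (nrow(jx)) {
    for (i in seq_len(nrow(jx))) {
      o <- makeJunctionObservation(rearranged$reference, jx[i, ],
                                   readHalf = readHalf, flankLen = flankLen,
                                   pad = pad)
      obs[[paste0("jxn_", jx$event[i], "_", jx$kind[i])]] <- o
    }
  }
  reads <- Biostrings::DNAStringSet(vapply(obs, `[[`, "", "read"))
  list(observations = obs, reads = reads)
}
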