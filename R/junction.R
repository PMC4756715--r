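#' Locate a rearrangement junction in a junction-spanning read
#'
#' The read is modelled as the concatenation of left-locus sequence and
#' right-locus sequence (with an optional non-templated insertion between
#' them). Both flanks must be pre-oriented so their junction-adjacent ends
#' face the split (the caller reverse-complements as the event's sides
#' require). Matching is exact -- these are Sanger-scale consensus reads;
#' error tolerance is out of scope.
#'
#' The read's prefix is anchored in the left flank with its first
#' `minAnchor` bases and extended maximally (`a*`); the suffix is anchored
#' and extended likewise in the right flank (`b*`). When the two maximal
#' alignments overlap (`a* + b* >= n`), every split index in
#' `[n - b*, a*]` is admissible and the junction carries
#' `a* + b* - n` bases of microhomology; when they leave a gap, the gap is
#' a non-templated insertion and the (unique) split is placed at `a*`.
#' The leftmost admissible split is the canonical breakpoint.
#'
#' @param read junction-spanning read (character).
#' @param leftFlank,rightFlank reference sequence around the two junction
#'   loci, pre-oriented; each should extend a little past the junction so
#'   shared microhomologous bases are visible on both sides.
#' @param minAnchor minimum anchored bases per side (default 15 bp, enough
#'   for uniqueness at toy-genome scale).
#' @return list with `splits` (admissible split offsets: the junction lies
#'   after read base `s`), `aStar`, `bStar`, `insertedSeq`.
#' @export
locateJunction <- function(read, leftFlank, rightFlank, minAnchor = 15L) {
  n <- nchar(read)
  minAnchor <- as.integer(minAnchor)
  if (n < 2L * minAnchor)
    stop("read shorter than 2*minAnchor")
  aStar <- .maxPrefixMatch(read, leftFlank, minAnchor)
  bStar <- .maxSuffixMatch(read, rightFlank, minAnchor)
  if (is.na(aStar))
    stop("no junction: left flank matches fewer than minAnchor bases")
  if (is.na(bStar))
    stop("no junction: right flank matches fewer than minAnchor bases")
  if (aStar + bStar >= n) {
    list(splits = (n - bStar):aStar, aStar = aStar, bStar = bStar,
         insertedSeq = "")
  } else {
    list(splits = aStar, aStar = aStar, bStar = bStar,
         insertedSeq = substr(read, aStar + 1L, n - bStar))
  }
}

# longest read prefix matching contiguously inside `flank`, anchored by the
# first minAnchor bases (all anchor occurrences are tried; repeats resolve
# to the longest extension)
.maxPrefixMatch <- function(read, flank, minAnchor) {
  anchor <- substr(read, 1L, minAnchor)
  occ <- gregexpr(anchor, flank, fixed = TRUE)[[1L]]
  if (occ[1L] == -1L) return(NA_integer_)
  n <- nchar(read); fn <- nchar(flank)
  best <- minAnchor
  for (o in as.integer(occ)) {
    len <- minAnchor
    while (len < n && o + len <= fn &&
           substr(read, len + 1L, len + 1L) ==
           substr(flank, o + len, o + len))
      len <- len + 1L
    if (len > best) best <- len
  }
  best
}

.maxSuffixMatch <- function(read, flank, minAnchor) {
  n <- nchar(read)
  anchor <- substr(read, n - minAnchor + 1L, n)
  occ <- gregexpr(anchor, flank, fixed = TRUE)[[1L]]
  if (occ[1L] == -1L) return(NA_integer_)
  best <- minAnchor
  for (o in as.integer(occ)) {
    len <- minAnchor
    # anchor occupies flank[o .. o+minAnchor-1]; extend leftward
    while (len < n && o - (len - minAnchor) > 1L &&
           substr(read, n - len, n - len) ==
           substr(flank, o - (len - minAnchor) - 1L, o - (len - minAnchor) - 1L))
      len <- len + 1L
    if (len > best) best <- len
  }
  best
}

#' Measure microhomology at a located junction
#'
#' Microhomology is the stretch of bases compatible with every admissible
#' breakpoint placement: `mh_len = |splits| - 1`, and the homologous
#' sequence is the read between the smallest and largest admissible split.
#' A junction resolved with a non-templated insertion has zero
#' microhomology by definition.
#'
#' @param read the junction read.
#' @param junction result of [locateJunction()].
#' @return list with `mhLen`, `mhSeq`, `placement` (range of admissible
#'   splits), `insertedSeq`.
#' @export
microhomology <- function(read, junction) {
  sp <- junction$splits
  if (!length(sp)) stop("no junction located")
  if (nzchar(junction$insertedSeq)) {
    list(mhLen = 0L, mhSeq = "", placement = range(sp),
         insertedSeq = junction$insertedSeq)
  } else {
    list(mhLen = length(sp) - 1L,
         mhSeq = if (length(sp) > 1L) substr(read, min(sp) + 1L, max(sp)) else "",
         placement = range(sp), insertedSeq = "")
  }
}

#' Classify the junction formation mechanism
#'
#' Junctions with at least `mhThreshold` bases of microhomology are labelled
#' microhomology-mediated, the signature of replication-associated repair;
#' a non-templated insertion is its own class; everything else is blunt.
#' 1 bp of homology arises by chance a quarter of the time, so the default
#' threshold is 2 bp.
#'
#' @param mh result of [microhomology()].
#' @param mhThreshold minimum microhomology length (bp).
#' @return One of `"microhomology-mediated"`, `"blunt"`, `"insertion"`.
#' @export
classifyJunction <- function(mh, mhThreshold = 2L) {
  if (nzchar(mh$insertedSeq)) "insertion"
  else if (mh$mhLen >= mhThreshold) "microhomology-mediated"
  else "blunt"
}

#' Full junction analysis of one observation
#'
#' Convenience wrapper: locate the junction, measure microhomology and
#' classify the mechanism.
#'
#' @param obs a junction observation (list with `read`, `leftFlank`,
#'   `rightFlank`), e.g. from [makeJunctionObservation()].
#' @param minAnchor see [locateJunction()].
#' @param mhThreshold see [classifyJunction()].
#' @return list with `mhLen`, `mhSeq`, `insertedSeq`, `placement`,
#'   `mechanism`, `canonicalSplit` (leftmost admissible split).
#' @export
analyzeJunction <- function(obs, minAnchor = 15L, mhThreshold = 2L) {
  loc <- locateJunction(obs$read, obs$leftFlank, obs$rightFlank, minAnchor)
  mh <- microhomology(obs$read, loc)
  c(mh, list(mechanism = classifyJunction(mh, mhThreshold),
             canonicalSplit = min(loc$splits)))
}
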