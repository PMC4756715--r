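#' @importFrom IRanges IRanges CharacterList IntegerList
NULL

# strand of a read encodes which way its retained segment runs at the
# junction it supports: a + read lies left of (and points at) the junction,
# so the joined segment extends toward lower coordinates ("tail"); a - read
# lies right of it ("head").
.sideFromStrand <- function(strand) ifelse(strand == "+", "tail", "head")

#' Partition mate pairs into concordant and discordant
#'
#' A pair is concordant iff both reads map to the same chromosome, in
#' canonical forward/reverse orientation (`+` then `-`), with an outer span
#' inside the insert-size acceptance window
#' `[insertMean - k*insertSd, insertMean + k*insertSd]`. Everything else --
#' wrong chromosome, wrong orientation, span outside the window -- is
#' discordant. The criterion is deliberately simple insert-size gating, the
#' standard practice for insert-size based SV detection.
#'
#' @param pairs a [MatePairSet-class].
#' @param insertMean,insertSd library insert model (bp).
#' @param k half-width of the acceptance window in SDs.
#' @return list with elements `concordant` and `discordant`
#'   ([MatePairSet-class] each).
#' @export
flagDiscordant <- function(pairs, insertMean = 3000, insertSd = 300, k = 3) {
  stopifnot(k > 0)
  if (length(pairs) == 0L)
    return(list(concordant = pairs, discordant = pairs))
  f <- firstRead(pairs); s <- secondRead(pairs)
  sameChrom <- as.character(GenomeInfoDb::seqnames(f)) ==
    as.character(GenomeInfoDb::seqnames(s))
  fr <- as.character(BiocGenerics::strand(f)) == "+" &
    as.character(BiocGenerics::strand(s)) == "-"
  span <- BiocGenerics::end(s) - BiocGenerics::start(f) + 1L
  inWin <- span >= insertMean - k * insertSd & span <= insertMean + k * insertSd
  conc <- sameChrom & fr & inWin
  list(concordant = pairs[conc], discordant = pairs[!conc])
}

#' Cluster discordant mate pairs supporting the same junction
#'
#' Pairs join a cluster iff they share the signature (chromosome pair and
#' strand pair) and, transitively by single linkage, both their left-end
#' starts and their right-end starts differ by at most `maxGap`. Clusters
#' pool pairs across samples: the cross-sample uniqueness filter depends on
#' clustering all samples together.
#'
#' Breakpoint uncertainty windows are oriented by the signature: a tail-side
#' end (reads on `+`, junction to their right) yields
#' `[max member end, max member end + slack]`; a head-side end (reads on
#' `-`) yields `[min member start - slack, min member start]`, where `slack`
#' is the largest distance a junction can lie from a read end
#' (`insertMean + k*insertSd - 2*readLen` for a concordant-length fragment).
#' For deletion-type (tail, head) clusters the two windows are additionally
#' capped at the opposite side's innermost read edge. A window whose bounds
#' invert collapses to a 1 bp midpoint and is flagged low-confidence.
#'
#' @param pairs discordant pairs ([MatePairSet-class]) carrying sample ids.
#' @param maxGap single-linkage gap (bp); default `insertMean + 3*insertSd`.
#' @param slack breakpoint window slack (bp); default
#'   `insertMean + k*insertSd - 2*readLen`.
#' @param insertMean,insertSd,k,readLen used only for the two defaults.
#' @return `DataFrame` with one row per cluster: signature columns, both
#'   breakpoint windows, `support`, `samples`, `sample` (set when private to
#'   one sample), `lowConfidence` and `members` (indices into `pairs`).
#' @export
clusterDiscordant <- function(pairs, maxGap = NULL, slack = NULL,
                              insertMean = 3000, insertSd = 300, k = 3,
                              readLen = 50) {
  if (is.null(maxGap)) maxGap <- insertMean + 3 * insertSd
  if (is.null(slack)) slack <- insertMean + k * insertSd - 2 * readLen
  stopifnot(maxGap > 0, slack > 0)
  n <- length(pairs)
  f <- firstRead(pairs); s <- secondRead(pairs)
  c1 <- as.character(GenomeInfoDb::seqnames(f))
  c2 <- as.character(GenomeInfoDb::seqnames(s))
  s1 <- as.character(BiocGenerics::strand(f))
  s2 <- as.character(BiocGenerics::strand(s))
  st1 <- BiocGenerics::start(f); en1 <- BiocGenerics::end(f)
  st2 <- BiocGenerics::start(s); en2 <- BiocGenerics::end(s)
  key <- paste(c1, c2, s1, s2, sep = "\r")

  clusterId <- integer(n)
  nextId <- 0L
  for (kk in unique(key)) {
    idx <- which(key == kk)
    idx <- idx[order(st1[idx])]
    m <- length(idx)
    parent <- seq_len(m)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(m)) {
      j <- i + 1L
      while (j <= m && st1[idx[j]] - st1[idx[i]] <= maxGap) {
        if (abs(st2[idx[j]] - st2[idx[i]]) <= maxGap) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
        j <- j + 1L
      }
    }
    roots <- vapply(seq_len(m), find, 1L)
    clusterId[idx] <- nextId + match(roots, unique(roots))
    nextId <- nextId + length(unique(roots))
  }

  ids <- sort(unique(clusterId))
  rows <- lapply(ids, function(ci) {
    mem <- which(clusterId == ci)
    side1 <- .sideFromStrand(s1[mem[1L]])
    side2 <- .sideFromStrand(s2[mem[1L]])
    inter <- c1[mem[1L]] != c2[mem[1L]]
    if (side1 == "tail") {
      b1 <- c(max(en1[mem]), max(en1[mem]) + slack)
    } else {
      b1 <- c(min(st1[mem]) - slack, min(st1[mem]))
    }
    if (side2 == "tail") {
      b2 <- c(max(en2[mem]), max(en2[mem]) + slack)
    } else {
      b2 <- c(min(st2[mem]) - slack, min(st2[mem]))
    }
    if (!inter && side1 == "tail" && side2 == "head") {
      b1[2L] <- min(b1[2L], min(st2[mem]))
      b2[1L] <- max(b2[1L], max(en1[mem]))
    }
    low <- FALSE
    fix <- function(b) {
      if (b[2L] < b[1L]) { low <<- TRUE; m <- (b[1L] + b[2L]) %/% 2L; c(m, m) }
      else b
    }
    b1 <- fix(b1); b2 <- fix(b2)
    b1 <- pmax(b1, 1L); b2 <- pmax(b2, 1L)
    smp <- sort(unique(pairSample(pairs)[mem]))
    S4Vectors::DataFrame(
      chrom1 = c1[mem[1L]], chrom2 = c2[mem[1L]],
      strand1 = s1[mem[1L]], strand2 = s2[mem[1L]],
      side1 = side1, side2 = side2, interChrom = inter,
      bp1Start = as.integer(b1[1L]), bp1End = as.integer(b1[2L]),
      bp2Start = as.integer(b2[1L]), bp2End = as.integer(b2[2L]),
      support = length(mem), nSamples = length(smp),
      samples = CharacterList(list(smp)),
      sample = if (length(smp) == 1L) smp else NA_character_,
      lowConfidence = low,
      members = IntegerList(list(mem)))
  })
  if (length(rows)) do.call(rbind, rows) else
    S4Vectors::DataFrame(chrom1 = character(0))
}

#' Retain clusters private to a single sample with sufficient support
#'
#' Unique clusters are identified by filtering out clusters supported by
#' read pairs in more than one sample; a minimum read-pair support guards
#' against chimera-like singletons (a single discordant pair is
#' indistinguishable from noise, so the default asks for 2).
#'
#' @param clusters `DataFrame` from [clusterDiscordant()] (built over all
#'   samples jointly).
#' @param minSupport minimum member count.
#' @return The retained subset of `clusters`.
#' @export
filterUniqueClusters <- function(clusters, minSupport = 2L) {
  if (!nrow(clusters)) return(clusters)
  clusters[clusters$nSamples == 1L & clusters$support >= minSupport, ,
           drop = FALSE]
}

#' Classify a junction signature into a rearrangement type
#'
#' Deterministic, total mapping from the orientation signature:
#' (tail, head) is a deletion (tail-to-head), (head, tail) a tandem
#' duplication (head-to-tail), (tail, tail) and (head, head) are the two
#' junctions of an inversion, and any inter-chromosomal signature a
#' translocation. All (head, tail) intra-chromosomal clusters are called
#' tandem duplications; resolving dispersed duplications is not attempted.
#'
#' @param side1,side2 junction sides (`"head"`/`"tail"`).
#' @param interChrom logical, inter-chromosomal cluster.
#' @return data.frame with `svType` and `orientationLabel` (vectorized).
#' @export
classifySignature <- function(side1, side2, interChrom = FALSE) {
  n <- max(length(side1), length(side2), length(interChrom))
  side1 <- rep_len(side1, n); side2 <- rep_len(side2, n)
  interChrom <- rep_len(interChrom, n)
  bad <- is.na(side1) | is.na(side2) |
    !side1 %in% c("head", "tail") | !side2 %in% c("head", "tail")
  if (any(bad & !interChrom)) stop("unresolved junction signature")
  key <- paste(side1, side2, sep = "-")
  svType <- ifelse(interChrom, "translocation",
            ifelse(key == "tail-head", "deletion",
            ifelse(key == "head-tail", "tandem_duplication", "inversion")))
  label <- ifelse(interChrom, "inter-chromosomal",
           ifelse(key == "tail-head", "tail-to-head",
           ifelse(key == "head-tail", "head-to-tail",
           ifelse(key == "tail-tail", "tail-to-tail", "head-to-head"))))
  data.frame(svType = svType, orientationLabel = label,
             stringsAsFactors = FALSE)
}

#' Turn discordant clusters into typed SV calls
#'
#' @param clusters `DataFrame` from [clusterDiscordant()] (typically after
#'   [filterUniqueClusters()]).
#' @return The input with `svType` and `orientationLabel` columns appended.
#' @export
classifyClusters <- function(clusters) {
  if (!nrow(clusters)) {
    clusters$svType <- character(0)
    clusters$orientationLabel <- character(0)
    return(clusters)
  }
  cls <- classifySignature(clusters$side1, clusters$side2, clusters$interChrom)
  clusters$svType <- cls$svType
  clusters$orientationLabel <- cls$orientationLabel
  clusters
}

#' Binned fragment-count copy-ratio profile relative to a control
#'
#' Each same-chromosome fragment is assigned to the genomic bin containing
#' its midpoint; per-bin counts are depth-normalized and compared as
#' `log2(((case+eps)/caseTotal) / ((control+eps)/controlTotal))`. This is
#' the read-depth view of the mate-pair data; it is the only channel in
#' which a whole-chromosome gain is visible, since a gained chromosome copy
#' creates no novel junction.
#'
#' @param casePairs,controlPairs [MatePairSet-class] objects.
#' @param binSize bin width in bp.
#' @param genomeLengths named integer vector of reference chromosome lengths.
#' @param epsilon pseudocount.
#' @return `GRanges` of bins with mcols `case_count`, `control_count`,
#'   `log2_ratio`.
#' @export
binnedCopyRatio <- function(casePairs, controlPairs, binSize, genomeLengths,
                            epsilon = 0.5) {
  stopifnot(binSize > 0)
  if (length(controlPairs) == 0L)
    stop("copy ratio undefined: control fragment set is empty")
  bins <- GenomicRanges::tileGenome(genomeLengths, tilewidth = binSize,
                                    cut.last.tile.in.chrom = TRUE)
  mids <- function(mp) {
    f <- firstRead(mp); s <- secondRead(mp)
    same <- as.character(GenomeInfoDb::seqnames(f)) ==
      as.character(GenomeInfoDb::seqnames(s))
    mid <- (BiocGenerics::start(f) + BiocGenerics::end(s)) %/% 2L
    GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(f))[same],
                           IRanges(mid[same], width = 1L))
  }
  cm <- mids(casePairs); km <- mids(controlPairs)
  cc <- GenomicRanges::countOverlaps(bins, cm)
  kc <- GenomicRanges::countOverlaps(bins, km)
  ct <- sum(cc); kt <- sum(kc)
  if (kt == 0L) stop("copy ratio undefined: no control fragments on the genome")
  bins$case_count <- cc
  bins$control_count <- kc
  bins$log2_ratio <- log2(((cc + epsilon) / ct) / ((kc + epsilon) / kt))
  bins
}
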