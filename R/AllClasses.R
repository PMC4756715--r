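#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRanges
NULL

.SV_KINDS <- c("tandem_duplication", "deletion", "inversion", "whole_chromosome_gain")

#' RearrangementEvent: a planted structural rearrangement
#'
#' Describes one rearrangement on a reference chromosome. Coordinates are
#' 1-based and inclusive: for a deletion the bases `start..end` are removed,
#' for a tandem duplication they are copied in place, for an inversion they
#' are reverse-complemented in place. `whole_chromosome_gain` appends a full
#' extra copy of the chromosome and carries no `start`/`end`.
#'
#' `mhLen` is the microhomology length engineered at the novel junction: the
#' generator edits the reference before rearranging so that the two loci
#' joined by the junction share exactly `mhLen` identical bases, the
#' signature of microhomology-mediated (replication-associated) repair.
#' `insertedSeq` optionally places a non-templated insertion at the junction
#' instead (mutually exclusive with `mhLen > 0`).
#'
#' @slot kind one of `"tandem_duplication"`, `"deletion"`, `"inversion"`,
#'   `"whole_chromosome_gain"`.
#' @slot chrom reference chromosome name.
#' @slot start,end 1-based inclusive span of affected bases.
#' @slot mhLen engineered junction microhomology length (>= 0).
#' @slot insertedSeq non-templated junction insertion ("" for none).
#' @exportClass RearrangementEvent
setClass("RearrangementEvent",
  representation(kind = "character", chrom = "character",
                 start = "integer", end = "integer",
                 mhLen = "integer", insertedSeq = "character"))

setValidity("RearrangementEvent", function(object) {
  msg <- character(0)
  if (length(object@kind) != 1L || !object@kind %in% .SV_KINDS)
    msg <- c(msg, sprintf("kind must be one of: %s", paste(.SV_KINDS, collapse = ", ")))
  if (length(object@chrom) != 1L || is.na(object@chrom) || !nzchar(object@chrom))
    msg <- c(msg, "chrom must be a non-empty string")
  if (object@kind != "whole_chromosome_gain") {
    if (is.na(object@start) || is.na(object@end))
      msg <- c(msg, "start and end are required for segmental events")
    else {
      if (object@start < 1L || object@end < object@start)
        msg <- c(msg, "need 1 <= start <= end")
      if (!is.na(object@start) && object@mhLen >= (object@end - object@start + 1L))
        msg <- c(msg, "engineered microhomology must be shorter than the event")
    }
  }
  if (object@mhLen < 0L) msg <- c(msg, "mhLen must be >= 0")
  if (object@mhLen > 0L && nzchar(object@insertedSeq))
    msg <- c(msg, "a junction has either microhomology or an insertion, not both")
  if (nzchar(object@insertedSeq) &&
      !grepl("^[ACGT]+$", object@insertedSeq))
    msg <- c(msg, "insertedSeq must be over {A,C,G,T}")
  if (length(msg)) msg else TRUE
})

#' Construct a RearrangementEvent
#'
#' @param kind event kind (see [RearrangementEvent-class]).
#' @param chrom reference chromosome name.
#' @param start,end 1-based inclusive affected span (ignored for
#'   `whole_chromosome_gain`).
#' @param mhLen engineered junction microhomology length.
#' @param insertedSeq optional non-templated junction insertion.
#' @return A [RearrangementEvent-class] object.
#' @examples
#' RearrangementEvent("deletion", "chrA", 10001, 20000)
#' @export
RearrangementEvent <- function(kind, chrom, start = NA, end = NA,
                               mhLen = 0L, insertedSeq = "") {
  new("RearrangementEvent", kind = as.character(kind), chrom = as.character(chrom),
      start = as.integer(start), end = as.integer(end),
      mhLen = as.integer(mhLen), insertedSeq = as.character(insertedSeq))
}

#' Junction sides of a rearrangement kind
#'
#' At a breakpoint, "head" means the retained segment runs toward higher
#' reference coordinates and "tail" toward lower. A deletion joins tail to
#' head, a tandem duplication head to tail, and an inversion joins two tails
#' (its second, reciprocal junction joins two heads).
#'
#' @param event a [RearrangementEvent-class].
#' @return Character vector of length 2 (left side, right side), or `NULL`
#'   for `whole_chromosome_gain`, which creates no novel junction.
#' @export
junctionSides <- function(event) {
  stopifnot(is(event, "RearrangementEvent"))
  switch(event@kind,
         deletion = c("tail", "head"),
         tandem_duplication = c("head", "tail"),
         inversion = c("tail", "tail"),
         whole_chromosome_gain = NULL)
}

setMethod("show", "RearrangementEvent", function(object) {
  if (object@kind == "whole_chromosome_gain") {
    cat(sprintf("RearrangementEvent: %s of %s\n", object@kind, object@chrom))
  } else {
    cat(sprintf("RearrangementEvent: %s %s:%d-%d (mh=%d%s)\n",
                object@kind, object@chrom, object@start, object@end, object@mhLen,
                if (nzchar(object@insertedSeq))
                  paste0(", ins=", object@insertedSeq) else ""))
  }
})

#' CoordinateMap: piecewise-affine map from a derived genome to its reference
#'
#' Every base of a rearranged (derived) genome maps to exactly one reference
#' base through an ordered set of blocks, each colinear (`strand == "+"`) or
#' reverse-complemented (`strand == "-"`). The map is total: blocks tile each
#' derived chromosome exactly from 1 to its length.
#'
#' @slot blocks data.frame with columns `dchrom`, `dstart`, `dend`,
#'   `rchrom`, `rstart`, `rend`, `strand` (all coordinates 1-based closed).
#' @slot derivedLengths named integer vector of derived chromosome lengths.
#' @exportClass CoordinateMap
setClass("CoordinateMap",
  representation(blocks = "data.frame", derivedLengths = "integer"))

setValidity("CoordinateMap", function(object) {
  b <- object@blocks
  need <- c("dchrom", "dstart", "dend", "rchrom", "rstart", "rend", "strand")
  if (!all(need %in% names(b))) return("blocks must have the standard columns")
  if (nrow(b) == 0L) return("a CoordinateMap needs at least one block")
  if (!all(b$strand %in% c("+", "-"))) return("block strand must be + or -")
  mapped <- !is.na(b$rchrom)   # insertion blocks map to nothing
  if (!all(b$dend[mapped] - b$dstart[mapped] ==
             b$rend[mapped] - b$rstart[mapped]))
    return("derived and reference block widths must agree")
  for (ch in unique(b$dchrom)) {
    bb <- b[b$dchrom == ch, , drop = FALSE]
    bb <- bb[order(bb$dstart), , drop = FALSE]
    if (bb$dstart[1L] != 1L) return("blocks must start at derived position 1")
    if (nrow(bb) > 1L && !all(bb$dstart[-1L] == bb$dend[-nrow(bb)] + 1L))
      return("blocks must tile the derived chromosome without gaps")
    ln <- object@derivedLengths[ch]
    if (is.na(ln) || bb$dend[nrow(bb)] != ln)
      return("blocks must end at the derived chromosome length")
  }
  TRUE
})

setMethod("show", "CoordinateMap", function(object) {
  cat(sprintf("CoordinateMap: %d block(s) over %d derived chromosome(s)\n",
              nrow(object@blocks), length(object@derivedLengths)))
})

#' Accessor: blocks of a CoordinateMap
#' @param map a [CoordinateMap-class].
#' @return The block `data.frame`.
#' @export
mapBlocks <- function(map) { stopifnot(is(map, "CoordinateMap")); map@blocks }

#' Accessor: derived chromosome lengths of a CoordinateMap
#' @param map a [CoordinateMap-class].
#' @return Named integer vector.
#' @export
derivedLengths <- function(map) { stopifnot(is(map, "CoordinateMap")); map@derivedLengths }

#' MatePairSet: mapped mate-pair records
#'
#' Each record is a mapped read pair in reference coordinates: two reads of
#' fixed length with chromosome, start and strand, stored canonically with
#' the lower-coordinate end first (ends are swapped wholesale, each keeping
#' its own strand). In the expected concordant geometry of a 3 kb mate-pair
#' library simulated in forward/reverse orientation, the first read is `+`,
#' the second `-`, and the outer span is close to the insert size; deviations
#' in chromosome, orientation or span are the discordant signatures that
#' reveal structural variants.
#'
#' @slot first,second [GenomicRanges::GRanges] of the two read alignments
#'   (parallel, strand set).
#' @slot sample sample identifier per pair.
#' @slot name pair name.
#' @slot score numeric score column (BEDPE column 8).
#' @exportClass MatePairSet
setClass("MatePairSet",
  representation(first = "GRanges", second = "GRanges",
                 sample = "character", name = "character", score = "numeric"))

setValidity("MatePairSet", function(object) {
  n <- length(object@first)
  if (length(object@second) != n || length(object@sample) != n ||
      length(object@name) != n || length(object@score) != n)
    return("all slots must have equal length")
  if (n == 0L) return(TRUE)
  s1 <- as.character(BiocGenerics::strand(object@first))
  s2 <- as.character(BiocGenerics::strand(object@second))
  if (!all(s1 %in% c("+", "-")) || !all(s2 %in% c("+", "-")))
    return("read strands must be '+' or '-'")
  c1 <- as.character(GenomeInfoDb::seqnames(object@first))
  c2 <- as.character(GenomeInfoDb::seqnames(object@second))
  bad <- (c1 > c2) | (c1 == c2 & BiocGenerics::start(object@first) >
                        BiocGenerics::start(object@second))
  if (any(bad)) return("pairs must be stored canonically (lower end first)")
  TRUE
})

#' Construct a MatePairSet
#'
#' Ends given in either order are canonicalized: whenever the second end has
#' the lower (chromosome, start), the two ends are swapped, each keeping its
#' own strand.
#'
#' @param first,second `GRanges` of the two read alignments (strand set).
#' @param sample sample identifier (recycled).
#' @param name pair names (default `pair_1..n`).
#' @param score numeric score (recycled, default 0).
#' @return A [MatePairSet-class].
#' @export
MatePairSet <- function(first, second, sample = "sample1",
                        name = NULL, score = 0) {
  n <- length(first)
  stopifnot(length(second) == n)
  if (is.null(name)) name <- if (n) paste0("pair_", seq_len(n)) else character(0)
  sample <- rep_len(as.character(sample), n)
  score <- rep_len(as.numeric(score), n)
  if (n) {
    c1 <- as.character(GenomeInfoDb::seqnames(first))
    c2 <- as.character(GenomeInfoDb::seqnames(second))
    swap <- (c1 > c2) | (c1 == c2 & BiocGenerics::start(first) >
                           BiocGenerics::start(second))
    if (any(swap)) {
      tmp <- first[swap]
      first[swap] <- second[swap]
      second[swap] <- tmp
    }
  }
  new("MatePairSet", first = first, second = second,
      sample = sample, name = as.character(name), score = score)
}

setMethod("length", "MatePairSet", function(x) length(x@first))

setMethod("show", "MatePairSet", function(object) {
  cat(sprintf("MatePairSet: %d pair(s), %d sample(s)\n",
              length(object), length(unique(object@sample))))
  if (length(object)) {
    i <- seq_len(min(3L, length(object)))
    df <- data.frame(name = object@name[i], sample = object@sample[i],
                     end1 = sprintf("%s:%d(%s)",
                                    as.character(GenomeInfoDb::seqnames(object@first[i])),
                                    BiocGenerics::start(object@first[i]),
                                    as.character(BiocGenerics::strand(object@first[i]))),
                     end2 = sprintf("%s:%d(%s)",
                                    as.character(GenomeInfoDb::seqnames(object@second[i])),
                                    BiocGenerics::start(object@second[i]),
                                    as.character(BiocGenerics::strand(object@second[i]))))
    print(df)
    if (length(object) > 3L) cat("...\n")
  }
})

setMethod("[", "MatePairSet", function(x, i, j, ..., drop = TRUE) {
  new("MatePairSet", first = x@first[i], second = x@second[i],
      sample = x@sample[i], name = x@name[i], score = x@score[i])
})

#' @describeIn MatePairSet-class first (lower-coordinate) read alignments.
#' @param x a `MatePairSet`.
#' @export
firstRead <- function(x) { stopifnot(is(x, "MatePairSet")); x@first }

#' @describeIn MatePairSet-class second read alignments.
#' @export
secondRead <- function(x) { stopifnot(is(x, "MatePairSet")); x@second }

#' @describeIn MatePairSet-class per-pair sample identifiers.
#' @export
pairSample <- function(x) { stopifnot(is(x, "MatePairSet")); x@sample }

#' @describeIn MatePairSet-class pair names.
#' @export
pairName <- function(x) { stopifnot(is(x, "MatePairSet")); x@name }

#' @describeIn MatePairSet-class pair scores (BEDPE score column).
#' @export
pairScore <- function(x) { stopifnot(is(x, "MatePairSet")); x@score }

#' Concatenate MatePairSets
#' @param x,... `MatePairSet` objects.
#' @return A single combined `MatePairSet`.
#' @export
combineMatePairs <- function(x, ...) {
  sets <- c(list(x), list(...))
  stopifnot(all(vapply(sets, is, TRUE, "MatePairSet")))
  firsts <- do.call(.harmonizeSeqlevels, lapply(sets, firstRead))
  seconds <- do.call(.harmonizeSeqlevels, lapply(sets, secondRead))
  new("MatePairSet",
      first = do.call(c, firsts),
      second = do.call(c, seconds),
      sample = do.call(c, lapply(sets, pairSample)),
      name = do.call(c, lapply(sets, pairName)),
      score = do.call(c, lapply(sets, pairScore)))
}

#' CloneCohort: labelled clonal cell lines and their CNA calls
#'
#' Holds the case/control clone table (with a set identifier for per-set
#' permutation schemes, emulating independently derived batches of clonal
#' lines) and all copy-number aberration calls across clones.
#'
#' @slot clones data.frame with columns `clone`, `group`
#'   (`"case"`/`"control"`), `set` (integer).
#' @slot calls `GRanges` of CNA calls with metadata columns `sample`,
#'   `cna_type` (`"gain"`/`"loss"`), `copy_number`, `source`.
#' @exportClass CloneCohort
setClass("CloneCohort",
  representation(clones = "data.frame", calls = "GRanges"))

setValidity("CloneCohort", function(object) {
  cl <- object@clones
  if (!all(c("clone", "group", "set") %in% names(cl)))
    return("clones must have columns clone, group, set")
  if (anyDuplicated(cl$clone)) return("clone ids must be unique")
  if (!all(cl$group %in% c("case", "control")))
    return("group must be 'case' or 'control'")
  mc <- S4Vectors::mcols(object@calls)
  if (!all(c("sample", "cna_type") %in% names(mc)))
    return("calls need metadata columns sample and cna_type")
  if (length(object@calls) &&
      !all(mc$sample %in% cl$clone))
    return("every call's sample must be a known clone id")
  if (length(object@calls) && !all(mc$cna_type %in% c("gain", "loss")))
    return("cna_type must be 'gain' or 'loss'")
  TRUE
})

#' Construct a CloneCohort
#' @param clones data.frame with columns `clone`, `group`, `set`.
#' @param calls `GRanges` of CNA calls (mcols `sample`, `cna_type`, and
#'   optionally `copy_number`, `source`).
#' @return A [CloneCohort-class].
#' @export
CloneCohort <- function(clones, calls) {
  mc <- S4Vectors::mcols(calls)
  if (is.null(mc$copy_number)) mc$copy_number <- NA_integer_
  if (is.null(mc$source)) mc$source <- ""
  S4Vectors::mcols(calls) <- mc
  new("CloneCohort", clones = clones, calls = calls)
}

#' @describeIn CloneCohort-class the clone table.
#' @param cohort a `CloneCohort`.
#' @export
cohortClones <- function(cohort) { stopifnot(is(cohort, "CloneCohort")); cohort@clones }

#' @describeIn CloneCohort-class all CNA calls as a `GRanges`.
#' @export
cohortCalls <- function(cohort) { stopifnot(is(cohort, "CloneCohort")); cohort@calls }

setMethod("show", "CloneCohort", function(object) {
  cl <- object@clones
  cat(sprintf("CloneCohort: %d case / %d control clone(s) in %d set(s); %d CNA call(s)\n",
              sum(cl$group == "case"), sum(cl$group == "control"),
              length(unique(cl$set)), length(object@calls)))
})

#' PermutationResult: outcome of the label-permutation enrichment test
#'
#' @slot pValue Monte-Carlo P value (`nSuccess / nPerm`).
#' @slot nPerm number of label permutations drawn.
#' @slot nSuccess number of qualifying permutations (all CNA-bearing clones
#'   relabelled as cases).
#' @slot scheme `"joint"` (one shuffle over all clones) or `"per_set"`
#'   (independent shuffles within each set, preserving group sizes).
#' @slot seed RNG seed used.
#' @slot analyticP exact closed-form probability for the same configuration.
#' @slot nCase,nControl,kPositive per-set configuration the test was run on.
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(pValue = "numeric", nPerm = "integer", nSuccess = "integer",
                 scheme = "character", seed = "integer", analyticP = "numeric",
                 nCase = "integer", nControl = "integer", kPositive = "integer"))

setValidity("PermutationResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("pValue must be in [0,1]")
  if (object@analyticP < 0 || object@analyticP > 1) return("analyticP must be in [0,1]")
  if (object@nSuccess > object@nPerm) return("nSuccess cannot exceed nPerm")
  if (abs(object@pValue - object@nSuccess / object@nPerm) > 1e-12)
    return("pValue must equal nSuccess/nPerm")
  TRUE
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(paste0("PermutationResult (%s scheme): p = %.6g ",
                     "(%d/%d permutations; analytic p = %.6g)\n"),
              object@scheme, object@pValue, object@nSuccess, object@nPerm,
              object@analyticP))
  cat(sprintf("  per-set config: case %s, control %s, CNA-positive %s; seed %d\n",
              paste(object@nCase, collapse = "/"),
              paste(object@nControl, collapse = "/"),
              paste(object@kPositive, collapse = "/"), object@seed))
})

#' RunReport: summary of an end-to-end pipeline run
#'
#' @slot stageCounts record counts per pipeline stage.
#' @slot svRecovery data.frame matching planted rearrangements to SV calls.
#' @slot permutation list of [PermutationResult-class] objects by scheme.
#' @slot fragileSummary fragile-site overlap summary.
#' @slot acghSummary probe-threshold caller summary.
#' @slot configHash md5 of the serialized run configuration.
#' @slot version package version string.
#' @exportClass RunReport
setClass("RunReport",
  representation(stageCounts = "list", svRecovery = "data.frame",
                 permutation = "list", fragileSummary = "list",
                 acghSummary = "list", configHash = "character",
                 version = "character"))

setMethod("show", "RunReport", function(object) {
  cat("aneuscan RunReport (config", object@configHash, ")\n")
  cat("  stage record counts:\n")
  for (nm in names(object@stageCounts))
    cat(sprintf("    %-24s %s\n", nm, object@stageCounts[[nm]]))
  if (nrow(object@svRecovery)) {
    cat("  planted rearrangements vs calls:\n")
    print(object@svRecovery)
  }
  for (pr in object@permutation) show(pr)
  fs <- object@fragileSummary
  if (length(fs))
    cat(sprintf("  fragile-site overlap: %d/%d CNAs (fraction %.4g)\n",
                fs$nOverlap, fs$nTotal, fs$fraction))
  ac <- object@acghSummary
  if (length(ac))
    cat(sprintf("  aCGH caller: %d call(s), %d/%d truth events recovered\n",
                ac$nCalls, ac$nRecovered, ac$nTruth))
})
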