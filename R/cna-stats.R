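#' Reciprocal overlap of two genomic intervals
#'
#' `min(o/|a|, o/|b|)` where `o` is the overlap length; 0 for intervals on
#' different chromosomes or disjoint. Symmetric, and equal to 1 iff the
#' intervals are identical. Used to decide whether two CNA calls describe
#' the same underlying event.
#'
#' @param a,b `GRanges` (recycled to equal length; computed element-wise).
#' @return Numeric vector in `[0, 1]`.
#' @export
reciprocalOverlap <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n); b <- rep(b, length.out = n)
  same <- as.character(GenomeInfoDb::seqnames(a)) ==
    as.character(GenomeInfoDb::seqnames(b))
  o <- pmin(BiocGenerics::end(a), BiocGenerics::end(b)) -
    pmax(BiocGenerics::start(a), BiocGenerics::start(b)) + 1L
  o <- pmax(o, 0L)
  ro <- pmin(o / BiocGenerics::width(a), o / BiocGenerics::width(b))
  ifelse(same, ro, 0)
}

#' Filter to unique (clone-private) CNA calls
#'
#' A call is removed iff some call of the same type in a *different* clone
#' reciprocally overlaps it by at least `minRo` -- both partners of such a
#' match are removed, treating recurrent calls as shared germline/clonal
#' background rather than de novo events. Surviving calls are the unique
#' CNAs. The filter is symmetric under clone reordering and idempotent.
#'
#' Manual curation of the surviving calls (as done on real array profiles)
#' is not reproducible and is deliberately a no-op here.
#'
#' @param calls `GRanges` with mcols `sample` and `cna_type`.
#' @param minRo reciprocal-overlap threshold in `(0, 1]`; the default 0.6
#'   implements "at least 60%" (inclusive).
#' @return list with `unique` and `removed` (`GRanges` each).
#' @export
filterUniqueCnas <- function(calls, minRo = 0.6) {
  stopifnot(minRo > 0, minRo <= 1)
  if (length(calls) == 0L) return(list(unique = calls, removed = calls))
  hits <- GenomicRanges::findOverlaps(calls, calls, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  keepHit <- qi != si & calls$sample[qi] != calls$sample[si] &
    calls$cna_type[qi] == calls$cna_type[si]
  qi <- qi[keepHit]; si <- si[keepHit]
  ro <- reciprocalOverlap(calls[qi], calls[si])
  removed <- unique(c(qi[ro >= minRo], si[ro >= minRo]))
  keep <- setdiff(seq_along(calls), removed)
  list(unique = calls[sort(keep)], removed = calls[sort(removed)])
}

#' Exact probability that all CNA-bearing clones are relabelled as cases
#'
#' Closed form for the label-permutation test: drawing case labels without
#' replacement, the probability that all `k` CNA-positive clones receive a
#' case label is `prod_{i=0}^{k-1} (nCase - i) / (nCase + nControl - i)`.
#' Arguments may be per-set vectors (recycled), in which case the per-set
#' probabilities multiply -- the per-set permutation scheme. Equivalently
#' this is the hypergeometric point mass `P(X = k)` with `X` the number of
#' positives among `nCase` sampled labels, i.e.
#' `choose(n - k, nCase - k) / choose(n, nCase)`.
#'
#' @param nCase,nControl group sizes (per set where applicable).
#' @param kPositive number of CNA-bearing case clones (per set).
#' @return Probability in `[0, 1]`. `kPositive > nCase` in any set yields 0
#'   with a warning.
#' @export
exactEnrichmentProb <- function(nCase, nControl, kPositive) {
  m <- max(length(nCase), length(nControl), length(kPositive))
  nCase <- rep_len(nCase, m); nControl <- rep_len(nControl, m)
  kPositive <- rep_len(kPositive, m)
  if (any(kPositive > nCase)) {
    warning("more positive clones than case labels in a set: probability 0")
    return(0)
  }
  p <- 1
  for (s in seq_len(m)) {
    k <- kPositive[s]
    if (k > 0L) {
      i <- seq_len(k) - 1L
      p <- p * prod((nCase[s] - i) / (nCase[s] + nControl[s] - i))
    }
  }
  p
}

#' Label-permutation enrichment test for de novo CNAs
#'
#' Shuffles case/control labels (`nPerm` times) and counts permutations in
#' which every clone carrying at least one unique CNA receives a case
#' label; the P value is the qualifying fraction. `scheme = "joint"`
#' shuffles one label vector over all clones; `scheme = "per_set"` shuffles
#' independently within each clone set, preserving per-set group sizes
#' (the sets emulate independently derived batches of clonal lines). The
#' exact closed form ([exactEnrichmentProb()]) is computed alongside and
#' stored in the result. No multiple-testing correction is applied: this is
#' a single planned test.
#'
#' @param cohort a [CloneCohort-class].
#' @param uniqueCalls `GRanges` of unique CNA calls (the `unique` element of
#'   [filterUniqueCnas()]); their `sample` column defines the CNA-bearing
#'   clones.
#' @param nPerm number of permutations (>= 1).
#' @param scheme `"per_set"` (default) or `"joint"`.
#' @param seed integer RNG seed.
#' @return A [PermutationResult-class].
#' @export
permutationEnrichment <- function(cohort, uniqueCalls, nPerm = 1e6,
                                  scheme = c("per_set", "joint"), seed = 1L) {
  scheme <- match.arg(scheme)
  nPerm <- as.integer(nPerm)
  stopifnot(nPerm >= 1L)
  cl <- cohortClones(cohort)
  positive <- unique(as.character(uniqueCalls$sample))
  if (length(positive) == 0L)
    stop("undefined statistic: no clone carries a unique CNA")
  if (!all(positive %in% cl$clone))
    stop("unique calls refer to unknown clones")
  set.seed(as.integer(seed))
  if (scheme == "joint") {
    sets <- list(seq_len(nrow(cl)))
  } else {
    sets <- split(seq_len(nrow(cl)), cl$set)
  }
  nCaseS <- vapply(sets, function(ix) sum(cl$group[ix] == "case"), 1L)
  nCtlS <- vapply(sets, function(ix) sum(cl$group[ix] == "control"), 1L)
  posS <- lapply(sets, function(ix) which(cl$clone[ix] %in% positive))
  kS <- lengths(posS)
  nS <- lengths(sets)
  m <- length(sets)

  nSuccess <- 0L
  inCase <- lapply(nS, logical)
  for (r in seq_len(nPerm)) {
    ok <- TRUE
    for (s in seq_len(m)) {
      draw <- sample.int(nS[s], nCaseS[s])
      v <- inCase[[s]]
      v[draw] <- TRUE
      if (!all(v[posS[[s]]])) { ok <- FALSE; break }
    }
    if (ok) nSuccess <- nSuccess + 1L
  }
  analytic <- exactEnrichmentProb(nCaseS, nCtlS, kS)
  new("PermutationResult", pValue = nSuccess / nPerm, nPerm = nPerm,
      nSuccess = nSuccess, scheme = scheme, seed = as.integer(seed),
      analyticP = analytic, nCase = unname(nCaseS), nControl = unname(nCtlS),
      kPositive = unname(kS))
}

#' Threshold-and-run copy-number caller for probe log2-ratio profiles
#'
#' A probe is amplification-aberrant iff `log2_ratio >= ampThresh` and
#' deletion-aberrant iff `log2_ratio <= delThresh` (both inclusive).
#' Maximal runs of at least `minRun` consecutive same-direction aberrant
#' probes on one chromosome become calls spanning the first to last probe
#' position; any probe not aberrant in that direction breaks the run.
#' Defaults reproduce the printed thresholds: log2 >= 0.39 for
#' amplifications, log2 <= -0.30 for deletions, at least five consecutive
#' aberrant probes.
#'
#' @param probes data.frame with `chrom`, `position`, `log2_ratio`, sorted
#'   by (chrom, position) with strictly increasing positions per chromosome.
#' @param ampThresh,delThresh log2-ratio thresholds.
#' @param minRun minimum consecutive aberrant probes.
#' @return `GRanges` of calls with mcols `cna_type` (`gain`/`loss`) and
#'   `n_probes`.
#' @export
callAcghAberrations <- function(probes, ampThresh = 0.39, delThresh = -0.30,
                                minRun = 5L) {
  stopifnot(minRun >= 1L)
  for (ch in unique(probes$chrom)) {
    p <- probes$position[probes$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("probe profile input error: positions not strictly increasing on ", ch)
  }
  res <- list()
  scan <- function(ch, pos, aberrant, type) {
    r <- rle(aberrant)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values & r$lengths >= minRun)
    for (i in sel) {
      res[[length(res) + 1L]] <<- data.frame(
        chrom = ch, start = pos[starts[i]], end = pos[ends[i]],
        cna_type = type, n_probes = r$lengths[i])
    }
  }
  for (ch in unique(probes$chrom)) {
    sub <- probes[probes$chrom == ch, , drop = FALSE]
    scan(ch, sub$position, sub$log2_ratio >= ampThresh, "gain")
    scan(ch, sub$position, sub$log2_ratio <= delThresh, "loss")
  }
  if (!length(res)) {
    gr <- GenomicRanges::GRanges()
    gr$cna_type <- character(0); gr$n_probes <- integer(0)
    return(gr)
  }
  df <- do.call(rbind, res)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  gr$cna_type <- df$cna_type
  gr$n_probes <- df$n_probes
  gr
}

#' Annotate CNA calls with fragile-site breakpoint overlap
#'
#' Each CNA's two breakpoints (its start and end coordinates, taken as 1 bp
#' points -- the breakpoints, not the whole span) are tested for containment
#' in any fragile-site interval. The summary reports how many CNAs have at
#' least one breakpoint inside a site.
#'
#' @param cnas `GRanges` of CNA calls.
#' @param sites `GRanges` fragile-site catalog with mcol `name`.
#' @return list with `annotated` (input plus mcols `in_fragile_site`,
#'   `fragile_sites`), `nTotal`, `nOverlap`, `fraction`.
#' @export
fragileOverlap <- function(cnas, sites) {
  n <- length(cnas)
  if (n == 0L)
    return(list(annotated = cnas, nTotal = 0L, nOverlap = 0L, fraction = NaN))
  pts <- c(GenomicRanges::GRanges(GenomeInfoDb::seqnames(cnas),
             IRanges::IRanges(BiocGenerics::start(cnas), width = 1L)),
           GenomicRanges::GRanges(GenomeInfoDb::seqnames(cnas),
             IRanges::IRanges(BiocGenerics::end(cnas), width = 1L)))
  hitNames <- vector("list", n)
  if (length(sites)) {
    hm <- .harmonizeSeqlevels(pts, sites)
    hits <- GenomicRanges::findOverlaps(hm[[1L]], hm[[2L]],
                                        ignore.strand = TRUE)
    qi <- (S4Vectors::queryHits(hits) - 1L) %% n + 1L
    for (j in seq_along(qi))
      hitNames[[qi[j]]] <- c(hitNames[[qi[j]]],
                             sites$name[S4Vectors::subjectHits(hits)[j]])
  }
  hitNames <- lapply(hitNames, function(x) sort(unique(x %||% character(0))))
  inSite <- lengths(hitNames) > 0L
  out <- cnas
  out$in_fragile_site <- inSite
  out$fragile_sites <- IRanges::CharacterList(hitNames)
  list(annotated = out, nTotal = n, nOverlap = sum(inSite),
       fraction = sum(inSite) / n)
}
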