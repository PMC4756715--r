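#' Default shared copy-number variant templates
#'
#' Three clonal-background CNVs (present in every clone of every group with
#' per-clone boundary jitter), sized well above the jitter scale so that
#' jittered copies of the same CNV always reciprocally overlap far beyond
#' the uniqueness-filter threshold.
#'
#' @param genomeLengths named integer vector of chromosome lengths.
#' @return `GRanges` with mcols `cna_type`, `copy_number`.
#' @export
defaultSharedCnvs <- function(genomeLengths) {
  ch <- names(genomeLengths)
  ch <- rep_len(ch, 3L)
  sizes <- c(4e5, 8e5, 1.2e6)
  starts <- as.integer(round(genomeLengths[ch] * c(0.15, 0.45, 0.75)))
  gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(starts,
                                                    width = as.integer(sizes)))
  gr$cna_type <- c("gain", "loss", "gain")
  gr$copy_number <- ifelse(gr$cna_type == "gain", 3L, 1L)
  gr
}

#' Simulate a case/control cohort of clonal lines with CNA call tables
#'
#' Emulates the design of deriving clonal lines from single aneuploid
#' (case) and parental (control) cells, profiling each clone, and calling
#' CNAs: every clone carries every shared background CNV with independent
#' Gaussian boundary jitter (rounded to bp, truncated to keep intervals
#' valid), while de novo CNAs are planted only in a chosen number of case
#' clones. Defaults mirror the study conditions: 24 case and 24 control
#' clones in two sets, 12 de novo CNAs over exactly 8 distinct case clones,
#' sizes 105 kb to 5 Mb, and two thirds of the de novo events having a
#' breakpoint inside a fragile site. When positives are split across sets
#' they are allocated as evenly as possible (8 positives over 2 sets = 4+4).
#'
#' Exactly `round(fragileFraction * deNovoEvents)` de novo events get a
#' breakpoint placed inside a fragile-site interval; the remaining events
#' are placed with both breakpoints outside every site, so the planted
#' overlap fraction is exact. De novo events never overlap each other or a
#' shared CNV region, so the reciprocal-overlap filter has an unambiguous
#' truth.
#'
#' @param genomeLths named integer vector of chromosome lengths.
#' @param nCase,nControl clones per group.
#' @param nSets number of clone sets (batches).
#' @param sharedCnvs `GRanges` of shared CNV templates (mcols `cna_type`,
#'   `copy_number`); default [defaultSharedCnvs()].
#' @param deNovoEvents number of de novo CNAs to plant.
#' @param deNovoPositiveClones number of distinct case clones carrying them
#'   (each positive clone gets at least one event).
#' @param sizeRange de novo size range in bp.
#' @param jitterSd Gaussian boundary jitter SD for shared CNVs (bp).
#' @param fragileFraction fraction of de novo events with a breakpoint in a
#'   fragile site.
#' @param sites fragile-site catalog `GRanges` (required when
#'   `fragileFraction > 0`).
#' @param gainFraction probability a de novo event is a gain (the observed
#'   de novo spectrum was gain-poor: 5 gains vs 7 losses).
#' @param seed integer RNG seed.
#' @return list with `cohort` ([CloneCohort-class], all calls) and `truth`
#'   (`GRanges` of planted de novo events with mcols `sample`, `cna_type`,
#'   `copy_number`, `fragile`, `site`).
#' @export
simulateClonalCohort <- function(genomeLths,
                                 nCase = 24L, nControl = 24L, nSets = 2L,
                                 sharedCnvs = NULL,
                                 deNovoEvents = 12L,
                                 deNovoPositiveClones = 8L,
                                 sizeRange = c(105e3, 5e6),
                                 jitterSd = 5e3,
                                 fragileFraction = 8 / 12,
                                 sites = NULL,
                                 gainFraction = 5 / 12,
                                 seed) {
  stopifnot(!missing(seed))
  if (deNovoEvents < deNovoPositiveClones)
    stop("deNovoEvents must be >= deNovoPositiveClones")
  if (deNovoPositiveClones > nCase)
    stop("cannot have more positive clones than case clones")
  if (fragileFraction < 0 || fragileFraction > 1)
    stop("fragileFraction must be in [0,1]")
  nFragile <- as.integer(round(fragileFraction * deNovoEvents))
  if (nFragile > 0L && (is.null(sites) || length(sites) == 0L))
    stop("a fragile-site catalog is required when fragileFraction > 0")
  set.seed(as.integer(seed))
  if (is.null(sharedCnvs)) sharedCnvs <- defaultSharedCnvs(genomeLths)

  mkClones <- function(group, nn) {
    setOf <- rep(seq_len(nSets), length.out = nn)
    setOf <- sort(setOf)
    data.frame(clone = sprintf("%s_s%d_c%02d", group, setOf,
                               stats::ave(seq_len(nn), setOf, FUN = seq_along)),
               group = group, set = setOf, stringsAsFactors = FALSE)
  }
  clones <- rbind(mkClones("case", nCase), mkClones("control", nControl))

  # shared CNVs: every clone, independent boundary jitter per clone
  sharedCalls <- list()
  for (ci in seq_len(nrow(clones))) {
    for (ti in seq_along(sharedCnvs)) {
      ch <- as.character(GenomeInfoDb::seqnames(sharedCnvs)[ti])
      ln <- genomeLths[[ch]]
      s0 <- BiocGenerics::start(sharedCnvs)[ti]
      e0 <- BiocGenerics::end(sharedCnvs)[ti]
      s <- s0 + as.integer(round(stats::rnorm(1, 0, jitterSd)))
      e <- e0 + as.integer(round(stats::rnorm(1, 0, jitterSd)))
      s <- max(1L, min(s, e0 - 1L)); e <- min(ln, max(e, s + 1L))
      sharedCalls[[length(sharedCalls) + 1L]] <- data.frame(
        sample = clones$clone[ci], chrom = ch, start = s, end = e,
        cna_type = sharedCnvs$cna_type[ti],
        copy_number = sharedCnvs$copy_number[ti], source = "shared")
    }
  }

  # forbidden zones for de novo placement: shared templates (with jitter
  # margin) and previously planted events
  margin <- as.integer(ceiling(6 * jitterSd))
  forbidden <- GenomicRanges::resize(sharedCnvs,
                                     BiocGenerics::width(sharedCnvs) + 2L * margin,
                                     fix = "center")
  ptInSite <- function(ch, pos) {
    if (is.null(sites) || !length(sites)) return(FALSE)
    any(as.character(GenomeInfoDb::seqnames(sites)) == ch &
          BiocGenerics::start(sites) <= pos & BiocGenerics::end(sites) >= pos)
  }
  placed <- GenomicRanges::GRanges(seqlengths = genomeLths)
  fragFlag <- c(rep(TRUE, nFragile), rep(FALSE, deNovoEvents - nFragile))
  events <- list()
  for (i in seq_len(deNovoEvents)) {
    size <- as.integer(round(stats::runif(1, sizeRange[1L], sizeRange[2L])))
    for (try in seq_len(2000L)) {
      if (fragFlag[i]) {
        si <- sample.int(length(sites), 1L)
        ch <- as.character(GenomeInfoDb::seqnames(sites)[si])
        ln <- genomeLths[[ch]]
        s <- as.integer(floor(stats::runif(1, BiocGenerics::start(sites)[si],
                                           BiocGenerics::end(sites)[si] + 1)))
        e <- s + size - 1L
        if (e > ln) next
      } else {
        ch <- sample(names(genomeLths), 1L,
                     prob = genomeLths / sum(genomeLths))
        ln <- genomeLths[[ch]]
        if (ln <= size + 2L) next
        s <- as.integer(floor(stats::runif(1, 2, ln - size)))
        e <- s + size - 1L
        if (ptInSite(ch, s) || ptInSite(ch, e)) next
      }
      cand <- GenomicRanges::GRanges(factor(ch, names(genomeLths)),
                                     IRanges::IRanges(s, e))
      if (length(placed) &&
          length(GenomicRanges::findOverlaps(cand, placed)) > 0L) next
      if (length(GenomicRanges::findOverlaps(cand, forbidden)) > 0L) next
      placed <- c(placed, cand)
      isGain <- stats::runif(1) < gainFraction
      events[[i]] <- data.frame(chrom = ch, start = s, end = e,
                                cna_type = if (isGain) "gain" else "loss",
                                copy_number = if (isGain) 3L else 1L,
                                fragile = fragFlag[i],
                                site = if (fragFlag[i]) sites$name[si]
                                       else NA_character_)
      break
    }
    if (length(events) < i)
      stop("could not place de novo event ", i,
           " (genome too crowded for the requested configuration)")
  }
  if (deNovoEvents > 0L) {
    ev <- do.call(rbind, events)
    # distribute events over exactly deNovoPositiveClones case clones,
    # spreading positives as evenly as possible across sets
    caseBySets <- split(clones$clone[clones$group == "case"],
                        clones$set[clones$group == "case"])
    perSet <- diff(round(seq(0, deNovoPositiveClones, length.out = nSets + 1L)))
    positives <- unlist(mapply(function(cl, k) sample(cl, k),
                               caseBySets, perSet, SIMPLIFY = FALSE))
    positives <- as.character(positives)
    extra <- deNovoEvents - deNovoPositiveClones
    owner <- c(positives, if (extra > 0L)
      sample(positives, extra, replace = TRUE) else character(0))
    owner <- sample(owner)   # decorrelate clone from placement order
    ev$sample <- owner
  } else {
    ev <- data.frame(sample = character(0), chrom = character(0),
                     start = integer(0), end = integer(0),
                     cna_type = character(0), copy_number = integer(0),
                     fragile = logical(0), site = character(0))
  }

  deNovoCalls <- data.frame(sample = ev$sample, chrom = ev$chrom,
                            start = ev$start, end = ev$end,
                            cna_type = ev$cna_type,
                            copy_number = ev$copy_number,
                            source = rep("de_novo", nrow(ev)))
  allCalls <- rbind(do.call(rbind, sharedCalls),
                    if (nrow(deNovoCalls)) deNovoCalls)
  gr <- GenomicRanges::GRanges(allCalls$chrom,
          IRanges::IRanges(allCalls$start, allCalls$end))
  gr$sample <- allCalls$sample
  gr$cna_type <- allCalls$cna_type
  gr$copy_number <- as.integer(allCalls$copy_number)
  gr$source <- allCalls$source

  truth <- GenomicRanges::GRanges(ev$chrom, IRanges::IRanges(ev$start, ev$end))
  truth$sample <- ev$sample
  truth$cna_type <- ev$cna_type
  truth$copy_number <- as.integer(ev$copy_number)
  truth$fragile <- ev$fragile
  truth$site <- ev$site
  list(cohort = CloneCohort(clones, gr), truth = truth)
}

#' Simulate a probe log2-ratio profile from CNA truth
#'
#' Places a probe at every multiple of `spacing` on each chromosome; the
#' expected log2 ratio at a probe is `log2(copies / baseCopies)` with
#' `copies` determined by the truth events covering it (and `baseCopies`
#' elsewhere), plus Normal(0, `noiseSd`) noise. Profiles emulate
#' post-normalization array data; array normalization itself is out of
#' scope.
#'
#' @param truth `GRanges` of CNA events with mcols `cna_type` and
#'   optionally `copy_number`.
#' @param genomeLths named integer vector of chromosome lengths.
#' @param spacing probe spacing in bp.
#' @param noiseSd Gaussian noise SD on the log2 ratio.
#' @param baseCopies background copy number (>= 1).
#' @param seed integer RNG seed.
#' @return data.frame with `chrom`, `position`, `log2_ratio`, sorted by
#'   (chrom, position).
#' @export
simulateProbeProfile <- function(truth, genomeLths, spacing = 25e3,
                                 noiseSd = 0.1, baseCopies = 2L, seed) {
  stopifnot(!missing(seed), spacing > 0, baseCopies >= 1L)
  set.seed(as.integer(seed))
  probes <- list()
  for (ch in names(genomeLths)) {
    pos <- seq(spacing, genomeLths[[ch]], by = spacing)
    if (!length(pos)) next
    probes[[ch]] <- data.frame(chrom = ch, position = as.integer(pos))
  }
  df <- do.call(rbind, probes)
  rownames(df) <- NULL
  copies <- rep(as.numeric(baseCopies), nrow(df))
  if (length(truth)) {
    pts <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$position,
                                                             width = 1L))
    hits <- GenomicRanges::findOverlaps(pts, truth, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    cn <- truth$copy_number
    delta <- if (!is.null(cn)) cn - baseCopies else
      ifelse(truth$cna_type == "gain", 1L, -1L)
    delta[is.na(delta)] <- ifelse(truth$cna_type[is.na(delta)] == "gain",
                                  1L, -1L)
    for (j in seq_along(qi)) copies[qi[j]] <- copies[qi[j]] + delta[si[j]]
  }
  copies <- pmax(copies, 0)
  mu <- ifelse(copies > 0, log2(copies / baseCopies), -Inf)
  df$log2_ratio <- mu + stats::rnorm(nrow(df), 0, noiseSd)
  df[order(df$chrom, df$position), , drop = FALSE]
}

#' Generate a random fragile-site catalog
#'
#' Band-scale intervals (fragile sites are cytoband-sized regions prone to
#' breakage under replication stress), named `FS1..FSn` with classes
#' alternating common/rare. Sites may overlap each other but always lie
#' within their chromosome.
#'
#' @param genomeLths named integer vector of chromosome lengths.
#' @param nSites number of sites.
#' @param siteLengthRange interval length range in bp.
#' @param seed integer RNG seed.
#' @return `GRanges` with mcols `name`, `site_class`.
#' @export
makeFragileCatalog <- function(genomeLths, nSites,
                               siteLengthRange = c(1e6, 3e6), seed) {
  stopifnot(!missing(seed), nSites >= 0L)
  set.seed(as.integer(seed))
  if (nSites == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$name <- character(0); gr$site_class <- character(0)
    return(gr)
  }
  eligible <- names(genomeLths)[genomeLths > siteLengthRange[1L] + 2L]
  if (!length(eligible))
    stop("no chromosome can accommodate a fragile site of the requested size")
  rows <- lapply(seq_len(nSites), function(i) {
    ch <- sample(eligible, 1L, prob = genomeLths[eligible] /
                   sum(genomeLths[eligible]))
    ln <- genomeLths[[ch]]
    w <- as.integer(round(stats::runif(1, siteLengthRange[1L],
                                       min(siteLengthRange[2L], ln - 2L))))
    s <- as.integer(floor(stats::runif(1, 1, ln - w + 1)))
    data.frame(chrom = ch, start = s, end = s + w - 1L)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  gr$name <- paste0("FS", seq_len(nSites))
  gr$site_class <- rep_len(c("common", "rare"), nSites)
  gr
}
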