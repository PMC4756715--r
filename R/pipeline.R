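#' Default run configuration
#'
#' The default emulates the study conditions at desk scale: a two-chromosome
#' 1 Mb toy genome carrying one tandem duplication (head-to-tail), one
#' deletion (tail-to-head) and one inversion (tail-to-tail) with engineered
#' junction microhomology of 4, 2 and 0 bp; a 3 kb +/- 300 bp mate-pair
#' library at 20x fragment coverage; and a clonal cohort of 24 case and 24
#' control clones in two sets with 12 de novo CNAs over 8 positive case
#' clones, two thirds of them breaking inside fragile sites.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param outDir output directory for stage files.
#' @return A nested configuration list (YAML-serializable).
#' @export
defaultRunConfig <- function(seed = 1L, outDir = tempfile("aneuscan_run_")) {
  list(
    seed = as.integer(seed),
    outDir = outDir,
    genome = list(chromLengths = list(chrA = 500000L, chrB = 500000L),
                  gcFraction = 0.41),
    events = list(
      list(kind = "tandem_duplication", chrom = "chrA", start = 120001L,
           end = 200000L, mhLen = 4L),
      list(kind = "deletion", chrom = "chrA", start = 320001L, end = 380000L,
           mhLen = 2L),
      list(kind = "inversion", chrom = "chrB", start = 150001L, end = 230000L,
           mhLen = 0L)),
    matePairs = list(insertMean = 3000, insertSd = 300, readLen = 50L,
                     coverage = 20, k = 3, minSupport = 2L),
    junction = list(readHalf = 60L, flankLen = 200L, pad = 30L,
                    minAnchor = 15L, mhThreshold = 2L),
    cohort = list(nCase = 24L, nControl = 24L, nSets = 2L,
                  deNovoEvents = 12L, deNovoPositiveClones = 8L,
                  sizeRange = c(105e3, 5e6), jitterSd = 5e3,
                  fragileFraction = 8 / 12, gainFraction = 5 / 12,
                  chromLengths = stats::setNames(as.list(rep(60e6, 7)),
                                                 paste0("chr", 1:7)),
                  nSites = 15L, siteLengthRange = c(1e6, 3e6)),
    cna = list(minRo = 0.6),
    permutation = list(nPerm = 1e5L, schemes = c("per_set", "joint")),
    acgh = list(spacing = 25e3, noiseSd = 0.1, baseCopies = 2L,
                ampThresh = 0.39, delThresh = -0.30, minRun = 5L),
    binSize = 10e3)
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @return `readRunConfig`: the configuration list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname readRunConfig
#' @param config configuration list.
#' @return `writeRunConfig`: invisibly, `path`.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full pipeline on a configuration
#'
#' Executes simulate -> sv-call -> junction -> cna-filter -> perm-test ->
#' acgh-call -> fragile-overlap, persisting every intermediate in its
#' standard format (FASTA, BEDPE, VCF, BED, TSV) under `config$outDir`, and
#' returns a [RunReport-class] comparing calls against the planted truth.
#' Stage handoff is through plain files so partial runs are inspectable.
#' Re-running an identical configuration reproduces identical tabular
#' outputs.
#'
#' @param config configuration list (see [defaultRunConfig()]).
#' @return A [RunReport-class].
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  cfgPath <- file.path(config$outDir, "config.yaml")
  writeRunConfig(config, cfgPath)
  # hash the scientific configuration only, not where it is written
  hashPath <- tempfile(fileext = ".yaml")
  writeRunConfig(config[setdiff(names(config), "outDir")], hashPath)
  cfgHash <- unname(tools::md5sum(hashPath))
  unlink(hashPath)
  counts <- list()

  # ---- simulate -----------------------------------------------------------
  sim <- .stage("simulate", {
    lens <- unlist(config$genome$chromLengths)
    ref0 <- makeToyGenome(lens, config$genome$gcFraction,
                          seed = fanOutSeed(config$seed, "genome"))
    events <- lapply(config$events, function(e)
      RearrangementEvent(e$kind, e$chrom, e$start %||% NA, e$end %||% NA,
                         e$mhLen %||% 0L, e$insertedSeq %||% ""))
    rr <- if (length(events)) applyRearrangements(ref0, events) else
      list(genome = ref0, map = identityCoordinateMap(ref0),
           reference = ref0, junctions = data.frame(event = integer(0)))
    Biostrings::writeXStringSet(rr$reference,
                                file.path(config$outDir, "reference.fa"))
    Biostrings::writeXStringSet(rr$genome,
                                file.path(config$outDir, "derived.fa"))
    mpCfg <- config$matePairs
    gl <- sum(genomeLengths(rr$genome))
    nPairs <- max(1L, as.integer(round(mpCfg$coverage * gl / mpCfg$insertMean)))
    casePairs <- simulateMatePairs(rr$genome, rr$map, nPairs, sample = "case",
                                   insertMean = mpCfg$insertMean,
                                   insertSd = mpCfg$insertSd,
                                   readLen = mpCfg$readLen,
                                   seed = fanOutSeed(config$seed, "case_pairs"))
    idMap <- identityCoordinateMap(rr$reference)
    ctlN <- max(1L, as.integer(round(mpCfg$coverage * sum(lens) /
                                       mpCfg$insertMean)))
    controlPairs <- simulateMatePairs(rr$reference, idMap, ctlN,
                                      sample = "control",
                                      insertMean = mpCfg$insertMean,
                                      insertSd = mpCfg$insertSd,
                                      readLen = mpCfg$readLen,
                                      seed = fanOutSeed(config$seed,
                                                        "control_pairs"))
    writeBedpe(casePairs, file.path(config$outDir, "case_pairs.bedpe"))
    writeBedpe(controlPairs, file.path(config$outDir, "control_pairs.bedpe"))
    jr <- simulateJunctionReads(rr, readHalf = config$junction$readHalf,
                                flankLen = config$junction$flankLen,
                                pad = config$junction$pad)
    if (length(jr$reads))
      Biostrings::writeXStringSet(jr$reads,
                                  file.path(config$outDir, "junction_reads.fa"))
    coCfg <- config$cohort
    coLens <- unlist(coCfg$chromLengths)
    sites <- makeFragileCatalog(coLens, coCfg$nSites,
                                coCfg$siteLengthRange,
                                seed = fanOutSeed(config$seed, "fragile"))
    writeFragileSites(sites, file.path(config$outDir, "fragile_sites.bed"))
    co <- simulateClonalCohort(coLens, nCase = coCfg$nCase,
                               nControl = coCfg$nControl, nSets = coCfg$nSets,
                               deNovoEvents = coCfg$deNovoEvents,
                               deNovoPositiveClones = coCfg$deNovoPositiveClones,
                               sizeRange = coCfg$sizeRange,
                               jitterSd = coCfg$jitterSd,
                               fragileFraction = coCfg$fragileFraction,
                               sites = sites,
                               gainFraction = coCfg$gainFraction,
                               seed = fanOutSeed(config$seed, "cohort"))
    writeCnaTable(cohortCalls(co$cohort),
                  file.path(config$outDir, "cna_calls.tsv"))
    writeCohortLabels(cohortClones(co$cohort),
                      file.path(config$outDir, "clones.tsv"))
    posClone <- if (length(co$truth)) co$truth$sample[1L] else NULL
    probeTruth <- co$truth[co$truth$sample %in% posClone]
    probes <- simulateProbeProfile(probeTruth, coLens,
                                   spacing = config$acgh$spacing,
                                   noiseSd = config$acgh$noiseSd,
                                   baseCopies = config$acgh$baseCopies,
                                   seed = fanOutSeed(config$seed, "probes"))
    writeProbeProfile(probes, file.path(config$outDir, "probes.tsv"))
    list(rr = rr, casePairs = casePairs, controlPairs = controlPairs,
         junctionObs = jr$observations, cohort = co, sites = sites,
         probes = probes, probeTruth = probeTruth, lens = lens)
  })
  counts$mate_pairs_case <- length(sim$casePairs)
  counts$mate_pairs_control <- length(sim$controlPairs)
  counts$planted_rearrangements <- length(config$events)
  counts$cohort_cna_calls <- length(cohortCalls(sim$cohort$cohort))

  # ---- sv-call ------------------------------------------------------------
  sv <- .stage("sv-call", {
    mpCfg <- config$matePairs
    all <- combineMatePairs(sim$casePairs, sim$controlPairs)
    fl <- flagDiscordant(all, mpCfg$insertMean, mpCfg$insertSd, mpCfg$k)
    cl <- clusterDiscordant(fl$discordant, insertMean = mpCfg$insertMean,
                            insertSd = mpCfg$insertSd, k = mpCfg$k,
                            readLen = mpCfg$readLen)
    uq <- filterUniqueClusters(cl, mpCfg$minSupport)
    calls <- classifyClusters(uq)
    ratio <- binnedCopyRatio(sim$casePairs, sim$controlPairs,
                             config$binSize, sim$lens)
    rdf <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(ratio)),
                      start = BiocGenerics::start(ratio),
                      end = BiocGenerics::end(ratio),
                      case_count = ratio$case_count,
                      control_count = ratio$control_count,
                      log2_ratio = ratio$log2_ratio)
    write.table(rdf, file.path(config$outDir, "copy_ratio_bins.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(discordant = fl$discordant, clusters = cl, calls = calls)
  })
  counts$discordant_pairs <- length(sv$discordant)
  counts$clusters <- nrow(sv$clusters)
  counts$unique_sv_calls <- nrow(sv$calls)

  # ---- junction -----------------------------------------------------------
  jx <- .stage("junction", {
    calls <- sv$calls
    calls$mhLen <- rep(NA_integer_, nrow(calls))
    calls$mhSeq <- rep(NA_character_, nrow(calls))
    calls$mechanism <- rep(NA_character_, nrow(calls))
    jcfg <- config$junction
    for (ob in sim$junctionObs) {
      # match the read to the call with the nearest breakpoint window
      # (either window may face either junction locus)
      if (!nrow(calls)) break
      mid1 <- (calls$bp1Start + calls$bp1End) / 2
      mid2 <- (calls$bp2Start + calls$bp2End) / 2
      d <- pmin(abs(mid1 - ob$p), abs(mid2 - ob$p),
                abs(mid1 - ob$q), abs(mid2 - ob$q))
      d[calls$chrom1 != ob$chrom] <- Inf
      thresh <- 2 * (config$matePairs$insertMean +
                       config$matePairs$k * config$matePairs$insertSd)
      cand <- which(d <= thresh)
      if (!length(cand)) next
      res <- tryCatch(analyzeJunction(ob, jcfg$minAnchor, jcfg$mhThreshold),
                      error = function(e) NULL)
      if (is.null(res)) next
      # an inversion produces two reciprocal clusters for one junction;
      # annotate every cluster the read is compatible with
      calls$mhLen[cand] <- res$mhLen
      calls$mhSeq[cand] <- res$mhSeq
      calls$mechanism[cand] <- res$mechanism
    }
    calls
  })

  .stage("vcf-export", {
    if (nrow(jx)) {
      vdf <- data.frame(chrom = jx$chrom1,
                        start = pmin(jx$bp1End, jx$bp2Start),
                        end = pmax(jx$bp1End, jx$bp2Start),
                        svType = jx$svType,
                        id = paste0("sv", seq_len(nrow(jx))),
                        mhLen = jx$mhLen, mhSeq = jx$mhSeq)
      vdf <- vdf[vdf$svType != "translocation", , drop = FALSE]
      writeSvVcf(vdf, "toy_reference",
                 file.path(config$outDir, "sv_calls.vcf"))
    }
    NULL
  })

  # ---- cna-filter / perm-test --------------------------------------------
  cna <- .stage("cna-filter", {
    filterUniqueCnas(cohortCalls(sim$cohort$cohort), config$cna$minRo)
  })
  counts$unique_cnas <- length(cna$unique)

  perm <- .stage("perm-test", {
    if (length(cna$unique) == 0L) {
      .msg("permutation test skipped: no unique CNAs (undefined statistic)")
      list()
    } else {
      out <- list()
      for (sc in config$permutation$schemes)
        out[[sc]] <- permutationEnrichment(sim$cohort$cohort, cna$unique,
                                           nPerm = config$permutation$nPerm,
                                           scheme = sc,
                                           seed = fanOutSeed(config$seed,
                                                             paste0("perm_", sc)))
      out
    }
  })

  # ---- acgh-call ----------------------------------------------------------
  acgh <- .stage("acgh-call", {
    ac <- config$acgh
    calls <- callAcghAberrations(sim$probes, ac$ampThresh, ac$delThresh,
                                 ac$minRun)
    tr <- sim$probeTruth
    recovered <- 0L
    if (length(tr)) {
      for (i in seq_along(tr)) {
        hit <- GenomicRanges::findOverlaps(tr[i], calls)
        ok <- any(calls$cna_type[S4Vectors::subjectHits(hit)] ==
                    tr$cna_type[i])
        recovered <- recovered + as.integer(ok)
      }
    }
    list(nCalls = length(calls), nTruth = length(tr), nRecovered = recovered,
         calls = calls)
  })

  # ---- fragile-overlap ----------------------------------------------------
  frag <- .stage("fragile-overlap", {
    dn <- cna$unique[cna$unique$source == "de_novo"]
    fo <- fragileOverlap(dn, sim$sites)
    fo[c("nTotal", "nOverlap", "fraction")]
  })

  # ---- recovery report ----------------------------------------------------
  rec <- .stage("report", {
    jxn <- sim$rr$junctions
    if (!nrow(jxn)) data.frame() else {
      rows <- lapply(seq_len(nrow(jxn)), function(i) {
        want <- jxn$kind[i]
        hit <- which(sv$calls$svType == want &
                       sv$calls$chrom1 == jxn$chrom[i] &
                       sv$calls$bp1Start <= jxn$trueLeftBp[i] &
                       sv$calls$bp1End >= jxn$trueLeftBp[i] &
                       sv$calls$bp2Start <= jxn$trueRightBp[i] &
                       sv$calls$bp2End >= jxn$trueRightBp[i])
        data.frame(event = jxn$event[i], kind = want, chrom = jxn$chrom[i],
                   recovered = length(hit) > 0L,
                   mhPlanted = jxn$mh[i],
                   mhCalled = if (length(hit)) jx$mhLen[hit[1L]] else NA_integer_)
      })
      do.call(rbind, rows)
    }
  })

  report <- new("RunReport", stageCounts = counts, svRecovery = rec,
                permutation = perm, fragileSummary = frag,
                acghSummary = acgh[c("nCalls", "nTruth", "nRecovered")],
                configHash = cfgHash,
                version = as.character(utils::packageVersion("aneuscan")))
  saveReportTsv <- file.path(config$outDir, "report_recovery.tsv")
  if (nrow(rec))
    write.table(rec, saveReportTsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  report
}
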