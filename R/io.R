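#' @importFrom utils read.table write.table packageVersion
NULL

# On-disk conventions: BED, BEDPE and the bespoke CNA TSV are 0-based
# half-open (BED-native); in memory everything is a 1-based closed GRanges.
# The conversion happens exactly once, at the reader/writer boundary
# (rtracklayer performs it for BED).

.validateBedLines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  for (i in idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("malformed BED line %d: fewer than 3 columns", i))
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e))
      stop(sprintf("malformed BED line %d: non-integer coordinates", i))
    if (s < 0L || s >= e)
      stop(sprintf("malformed BED line %d: need 0 <= start < end", i))
  }
  length(idx)
}

#' Read genomic intervals from a BED file
#'
#' BED is 0-based half-open on disk; the returned `GRanges` is 1-based
#' closed. Name and score columns, when present, are kept as metadata
#' columns; input order is preserved.
#'
#' @param path BED file path.
#' @param extraCols named character vector of extra column types beyond
#'   BED6, passed to [rtracklayer::import()] (e.g.
#'   `c(site_class = "character")`).
#' @return A `GRanges`.
#' @export
readBedIntervals <- function(path, extraCols = character(0)) {
  if (!file.exists(path)) stop("no such file: ", path)
  n <- .validateBedLines(path)
  if (n == 0L) return(GenomicRanges::GRanges())
  rtracklayer::import(path, format = "BED", extraCols = extraCols)
}

#' Write genomic intervals to BED
#'
#' @param gr a `GRanges`; `name` and `score` metadata columns are written
#'   when present.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeBedIntervals <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a fragile-site catalog (BED4 + site class)
#'
#' Expected columns: chrom, start, end, name, site_class
#' (`"common"`/`"rare"`). Site names must be unique within a catalog;
#' intervals may overlap.
#'
#' @param path BED file path.
#' @return `GRanges` with mcols `name`, `site_class`.
#' @export
readFragileSites <- function(path) {
  gr <- readBedIntervals(path, extraCols = c(site_class = "character"))
  if (length(gr)) {
    if (anyDuplicated(gr$name)) stop("fragile-site names must be unique per catalog")
    if (!all(gr$site_class %in% c("common", "rare")))
      stop("site_class must be 'common' or 'rare'")
  }
  gr
}

#' Write a fragile-site catalog
#'
#' rtracklayer's BED exporter has no slot for custom trailing columns, so
#' the five tab-separated columns are emitted directly.
#'
#' @param sites `GRanges` with mcols `name`, `site_class`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeFragileSites <- function(sites, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(sites)),
                   start = BiocGenerics::start(sites) - 1L,
                   end = BiocGenerics::end(sites),
                   name = sites$name, site_class = sites$site_class)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.CNA_COLS <- c("sample", "chrom", "start", "end", "type", "copy_number")

#' Read a CNA call table (TSV)
#'
#' Fixed-schema stand-in for SNP-array call exports: tab-separated with a
#' header row containing at least `sample`, `chrom`, `start`, `end`, `type`
#' (`gain`/`loss`) and `copy_number`; coordinates 0-based half-open. Unknown
#' extra columns are ignored with a warning (except `source`, which is kept
#' as provenance).
#'
#' @param path TSV path.
#' @return `GRanges` with mcols `sample`, `cna_type`, `copy_number`, `source`.
#' @export
readCnaTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(.CNA_COLS, names(df))
  if (length(missing))
    stop("CNA table schema error: missing column(s) ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), c(.CNA_COLS, "source"))
  if (length(extra))
    warning("ignoring unknown CNA table column(s): ", paste(extra, collapse = ", "))
  if (nrow(df) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(sample = character(0),
      cna_type = character(0), copy_number = integer(0), source = character(0))
    return(gr)
  }
  if (!all(df$type %in% c("gain", "loss")))
    stop("CNA type must be 'gain' or 'loss'")
  if (any(df$start < 0L | df$start >= df$end))
    stop("CNA coordinates must satisfy 0 <= start < end")
  gr <- GenomicRanges::GRanges(df$chrom,
          IRanges::IRanges(df$start + 1L, df$end))
  gr$sample <- df$sample
  gr$cna_type <- df$type
  gr$copy_number <- as.integer(df$copy_number)
  gr$source <- if ("source" %in% names(df)) df$source else ""
  gr
}

#' Write a CNA call table (TSV)
#'
#' @param calls `GRanges` with mcols `sample`, `cna_type`, and optionally
#'   `copy_number`, `source`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeCnaTable <- function(calls, path) {
  cn <- calls$copy_number
  if (is.null(cn)) cn <- rep(NA_integer_, length(calls))
  src <- calls$source
  if (is.null(src)) src <- rep("", length(calls))
  df <- data.frame(sample = calls$sample %||% character(0),
                   chrom = as.character(GenomeInfoDb::seqnames(calls)),
                   start = BiocGenerics::start(calls) - 1L,
                   end = BiocGenerics::end(calls),
                   type = calls$cna_type %||% character(0),
                   copy_number = cn, source = src)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read mate pairs from a 10-column BEDPE file
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, name, score,
#' strand1, strand2 (0-based half-open on disk). Pairs are canonicalized on
#' read: the lower-coordinate end is stored first, ends swapped wholesale
#' with their strands. The sample identifier is taken from the prefix of the
#' name column up to the last `"/"` when present, else `sample` is used.
#'
#' @param path BEDPE path.
#' @param sample fallback sample id for pairs without an encoded one.
#' @return A [MatePairSet-class].
#' @export
readBedpe <- function(path, sample = "sample1") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines))
    return(MatePairSet(GenomicRanges::GRanges(), GenomicRanges::GRanges(),
                       sample = character(0), name = character(0),
                       score = numeric(0)))
  df <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 10L) stop("BEDPE must have 10 columns")
  names(df)[1:10] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                       "name", "score", "strand1", "strand2")
  if (!all(c(df$strand1, df$strand2) %in% c("+", "-")))
    stop("BEDPE strand values must be '+' or '-'")
  g1 <- GenomicRanges::GRanges(df$chrom1,
          IRanges::IRanges(df$start1 + 1L, df$end1), strand = df$strand1)
  g2 <- GenomicRanges::GRanges(df$chrom2,
          IRanges::IRanges(df$start2 + 1L, df$end2), strand = df$strand2)
  smp <- ifelse(grepl("/", df$name), sub("/[^/]*$", "", df$name), sample)
  MatePairSet(g1, g2, sample = smp, name = df$name, score = df$score)
}

#' Write mate pairs to BEDPE
#'
#' The sample id is encoded into the name column as `sample/name` so that
#' multi-sample BEDPE files round-trip.
#'
#' @param pairs a [MatePairSet-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeBedpe <- function(pairs, path) {
  f <- firstRead(pairs); s <- secondRead(pairs)
  nm <- pairName(pairs)
  enc <- ifelse(grepl("/", nm), nm, paste0(pairSample(pairs), "/", nm))
  df <- data.frame(chrom1 = as.character(GenomeInfoDb::seqnames(f)),
                   start1 = BiocGenerics::start(f) - 1L, end1 = BiocGenerics::end(f),
                   chrom2 = as.character(GenomeInfoDb::seqnames(s)),
                   start2 = BiocGenerics::start(s) - 1L, end2 = BiocGenerics::end(s),
                   name = enc, score = pairScore(pairs),
                   strand1 = as.character(BiocGenerics::strand(f)),
                   strand2 = as.character(BiocGenerics::strand(s)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a probe log2-ratio profile (TSV)
#'
#' Columns: `chrom`, `position` (1-based probe position), `log2_ratio`.
#'
#' @param path TSV path.
#' @return data.frame with those columns.
#' @export
readProbeProfile <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "position", "log2_ratio")
  if (!all(need %in% names(df)))
    stop("probe profile schema error: need columns ", paste(need, collapse = ", "))
  df[need]
}

#' Write a probe log2-ratio profile (TSV)
#' @param probes data.frame with `chrom`, `position`, `log2_ratio`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeProbeProfile <- function(probes, path) {
  write.table(probes[c("chrom", "position", "log2_ratio")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cohort clone labels (TSV)
#' @param path TSV with columns `clone`, `group`, `set`.
#' @return data.frame.
#' @export
readCohortLabels <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("clone", "group", "set") %in% names(df)))
    stop("cohort label schema error: need clone, group, set")
  df
}

#' Write cohort clone labels (TSV)
#' @param clones data.frame with `clone`, `group`, `set`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeCohortLabels <- function(clones, path) {
  write.table(clones[c("clone", "group", "set")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.SVTYPE_MAP <- c(deletion = "DEL", tandem_duplication = "DUP",
                 inversion = "INV", translocation = "BND")

#' Write structural variant calls as VCF 4.2
#'
#' Records use symbolic ALT alleles with the reserved INFO keys `SVTYPE`,
#' `END`, and, when junction analysis ran, `HOMLEN`/`HOMSEQ`. Following the
#' VCF convention for symbolic alleles, `POS` is the base *before* the first
#' affected base (internal 1-based start minus one) and `END` the last
#' affected base; this is the single place the package converts coordinates
#' for VCF. Breakpoints are reported leftmost when microhomology makes the
#' placement ambiguous.
#'
#' @param calls data.frame with columns `chrom`, `start`, `end` (1-based
#'   closed affected span), `svType` (`deletion`, `tandem_duplication`,
#'   `inversion`, `translocation`), optional `id`, `mhLen`, `mhSeq`.
#' @param referenceName name recorded in the `##reference` header line.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeSvVcf <- function(calls, referenceName, path) {
  n <- nrow(calls)
  hdr <- VariantAnnotation::VCFHeader(samples = character(0))
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2", row.names = "fileformat"),
    reference = S4Vectors::DataFrame(Value = referenceName, row.names = "reference"))
  VariantAnnotation::info(hdr) <- S4Vectors::DataFrame(
    Number = c("1", "1", "1", "1"),
    Type = c("String", "Integer", "Integer", "String"),
    Description = c("Type of structural variant",
                    "End position of the variant described in this record",
                    "Length of base pair identical micro-homology at event breakpoints",
                    "Sequence of base pair identical micro-homology at event breakpoints"),
    row.names = c("SVTYPE", "END", "HOMLEN", "HOMSEQ"))
  if (n == 0L) {
    gr <- GenomicRanges::GRanges()
    fx <- S4Vectors::DataFrame(REF = Biostrings::DNAStringSet(),
                               ALT = IRanges::CharacterList(),
                               QUAL = numeric(0), FILTER = character(0))
    inf <- S4Vectors::DataFrame(SVTYPE = character(0), END = integer(0),
                                HOMLEN = integer(0), HOMSEQ = character(0))
  } else {
    if (any(is.na(calls$start) | is.na(calls$end)))
      stop("every call must have resolved breakpoints")
    svtype <- .SVTYPE_MAP[calls$svType]
    if (anyNA(svtype)) stop("unknown svType in calls")
    pos <- pmax(1L, as.integer(calls$start) - 1L)
    gr <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(pos, width = 1L))
    names(gr) <- if (!is.null(calls$id)) calls$id else paste0("sv", seq_len(n))
    fx <- S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(rep("N", n)),
      ALT = IRanges::CharacterList(as.list(paste0("<", svtype, ">"))),
      QUAL = rep(NA_real_, n), FILTER = rep(".", n))
    mh <- if (!is.null(calls$mhLen)) as.integer(calls$mhLen) else rep(NA_integer_, n)
    mhseq <- if (!is.null(calls$mhSeq)) {
      x <- as.character(calls$mhSeq); x[!is.na(x) & !nzchar(x)] <- NA_character_; x
    } else rep(NA_character_, n)
    inf <- S4Vectors::DataFrame(SVTYPE = unname(svtype),
                                END = as.integer(calls$end),
                                HOMLEN = mh, HOMSEQ = mhseq)
  }
  vcf <- VariantAnnotation::VCF(rowRanges = gr, fixed = fx, info = inf,
                                collapsed = TRUE)
  S4Vectors::metadata(vcf)$header <- hdr
  VariantAnnotation::writeVcf(vcf, path)
  if (n == 0L) {
    # writeVcf emits an invalid nameless contig line for empty call sets
    lines <- readLines(path)
    writeLines(lines[!grepl("^##contig=<ID=>$", lines)], path)
  }
  invisible(path)
}
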