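#' @importFrom Biostrings DNAString DNAStringSet subseq reverseComplement xscat width
NULL

# ---- microhomology engineering -------------------------------------------
#
# A junction with m bp of microhomology is one whose two source loci share m
# identical junction-adjacent bases, so that the derived sequence around the
# junction is compatible with m+1 breakpoint placements. The generator edits
# the reference BEFORE rearranging: it copies the m bases adjacent to one
# junction side onto the other locus, and then forces a mismatch at the two
# bases just beyond the shared window (one per side) so the realized
# microhomology is exactly m -- also for m = 0, where chance homology must
# be broken. With a non-templated insertion the same boundary-breaking keeps
# the insertion cleanly delimited.
.engineerJunction <- function(chromSeq, kind, s, e, m, ins) {
  n <- nchar(chromSeq)
  getb <- function(p) substr(chromSeq, p, p)
  setb <- function(p, b) {
    substr(chromSeq, p, p) <- b
    chromSeq <<- chromSeq
  }
  if (m > 0L) {
    if (kind %in% c("tandem_duplication", "deletion")) {
      if (s - m < 1L) stop("event too close to chromosome start for engineered mh")
      substr(chromSeq, s - m, s - 1L) <- substr(chromSeq, e - m + 1L, e)
    } else if (kind == "inversion") {
      if (e + m > n || s - m < 1L)
        stop("event too close to chromosome edge for engineered mh")
      for (j in seq_len(m)) setb(e + j, .compBase(getb(s - j)))
    }
  }
  hasIns <- nzchar(ins)
  # constraint A: the left flank's continuation past its junction base must
  # differ from the first base the read actually continues with
  contA <- switch(kind,
    tandem_duplication = list(pos = e + 1L,
      avoid = if (hasIns) substr(ins, 1L, 1L) else getb(s)),
    deletion = list(pos = s,
      avoid = if (hasIns) substr(ins, 1L, 1L) else getb(e + 1L)),
    inversion = list(pos = s,
      avoid = if (hasIns) substr(ins, 1L, 1L) else .compBase(getb(e))))
  # constraint B: the right flank's context just before the shared window
  # must differ from the read base preceding it
  if (hasIns) {
    lastIns <- substr(ins, nchar(ins), nchar(ins))
    contB <- switch(kind,
      tandem_duplication = list(pos = s - 1L, avoid = lastIns),
      deletion = list(pos = e, avoid = lastIns),
      inversion = list(pos = e + 1L, avoid = .compBase(lastIns)))
  } else {
    contB <- switch(kind,
      tandem_duplication = list(pos = s - m - 1L, avoid = getb(e - m)),
      deletion = list(pos = e - m, avoid = getb(s - m - 1L)),
      inversion = list(pos = e + m + 1L, avoid = .compBase(getb(s - m - 1L))))
  }
  for (con in list(contA, contB)) {
    if (is.null(con)) next
    if (con$pos < 1L || con$pos > n) next
    if (getb(con$pos) == con$avoid)
      setb(con$pos, .pickDifferentBase(con$avoid, getb(con$pos)))
  }
  chromSeq
}

.validateEvents <- function(genome, events) {
  lens <- genomeLengths(genome)
  for (ev in events) {
    if (!ev@chrom %in% names(lens))
      stop("event chromosome not in genome: ", ev@chrom)
    if (ev@kind == "whole_chromosome_gain") next
    ln <- lens[[ev@chrom]]
    if (ev@start < 2L || ev@end > ln - 1L)
      stop("segmental events must leave at least one flanking base on each side")
  }
  segm <- Filter(function(ev) ev@kind != "whole_chromosome_gain", events)
  if (length(segm) > 1L) {
    df <- data.frame(chrom = vapply(segm, slot, "", "chrom"),
                     s = vapply(segm, slot, 1L, "start"),
                     e = vapply(segm, slot, 1L, "end"))
    for (ch in unique(df$chrom)) {
      dd <- df[df$chrom == ch, , drop = FALSE]
      dd <- dd[order(dd$s), , drop = FALSE]
      if (nrow(dd) > 1L && any(dd$s[-1L] <= dd$e[-nrow(dd)]))
        stop("unsupported configuration: overlapping events on one chromosome; ",
             "apply them sequentially instead")
    }
  }
  invisible(TRUE)
}

#' Apply rearrangements to a genome
#'
#' Edits the reference first where junction microhomology (or a clean
#' insertion boundary) is engineered, then rearranges mechanically: a
#' deletion removes its span, a tandem duplication inserts a second copy of
#' its span immediately after the first, an inversion reverse-complements
#' its span in place, and a whole-chromosome gain appends a full chromosome
#' copy under a `"<chrom>_gain"` name (no novel junction: it is visible only
#' to read-depth analysis, not to junction analysis). Events on one
#' chromosome must not overlap; overlapping configurations must be applied
#' in separate sequential calls.
#'
#' @param genome named `DNAStringSet` reference.
#' @param events list of [RearrangementEvent-class] objects (a single event
#'   may be given unwrapped).
#' @return A list with elements
#' \describe{
#'   \item{genome}{derived `DNAStringSet`;}
#'   \item{map}{[CoordinateMap-class] from derived to reference coordinates
#'     (non-templated insertion bases map to nothing);}
#'   \item{reference}{the (possibly microhomology-edited) reference the
#'     derivative was built from -- flanks and junction reads must be taken
#'     from this sequence;}
#'   \item{junctions}{data.frame describing each novel junction: `event`,
#'     `kind`, `chrom`, left-locus junction base `p`, right-locus junction
#'     base `q`, `qStrand`, engineered `mh`, `insertedSeq`, and the true
#'     breakpoint coordinates `trueLeftBp`/`trueRightBp` used for
#'     window-containment checks.}
#' }
#' @export
applyRearrangements <- function(genome, events) {
  if (is(events, "RearrangementEvent")) events <- list(events)
  stopifnot(length(events) >= 1L)
  .validateEvents(genome, events)
  ref <- as.character(genome)

  for (ev in events) {
    if (ev@kind == "whole_chromosome_gain") next
    ref[[ev@chrom]] <- .engineerJunction(ref[[ev@chrom]], ev@kind,
                                         ev@start, ev@end, ev@mhLen,
                                         ev@insertedSeq)
  }

  jx <- list()
  pieces <- list()   # per derived chromosome: data.frame of segments
  dnames <- character(0)

  for (ch in names(ref)) {
    ln <- nchar(ref[[ch]])
    evs <- Filter(function(ev) ev@chrom == ch &&
                    ev@kind != "whole_chromosome_gain", events)
    if (length(evs))
      evs <- evs[order(vapply(evs, slot, 1L, "start"))]
    seg <- data.frame(rstart = integer(0), rend = integer(0),
                      strand = character(0), ins = character(0))
    addSeg <- function(rs, re, st) {
      if (re >= rs)
        seg <<- rbind(seg, data.frame(rstart = rs, rend = re, strand = st,
                                      ins = ""))
    }
    addIns <- function(x) {
      if (nzchar(x))
        seg <<- rbind(seg, data.frame(rstart = NA_integer_, rend = NA_integer_,
                                      strand = "+", ins = x))
    }
    cur <- 1L
    for (ev in evs) {
      s <- ev@start; e <- ev@end
      addSeg(cur, s - 1L, "+")
      if (ev@kind == "deletion") {
        addIns(ev@insertedSeq)
      } else if (ev@kind == "tandem_duplication") {
        addSeg(s, e, "+")
        addIns(ev@insertedSeq)
        addSeg(s, e, "+")
      } else if (ev@kind == "inversion") {
        addIns(ev@insertedSeq)
        addSeg(s, e, "-")
      }
      cur <- e + 1L
      iev <- which(vapply(events, identical, TRUE, ev))[1L]
      jx[[length(jx) + 1L]] <- data.frame(
        event = iev, kind = ev@kind, chrom = ch,
        p = switch(ev@kind, deletion = s - 1L, tandem_duplication = e,
                   inversion = s - 1L),
        q = switch(ev@kind, deletion = e + 1L, tandem_duplication = s,
                   inversion = e),
        qStrand = if (ev@kind == "inversion") "-" else "+",
        mh = ev@mhLen, insertedSeq = ev@insertedSeq,
        trueLeftBp = switch(ev@kind, deletion = s - 1L,
                            tandem_duplication = s, inversion = s - 1L),
        trueRightBp = switch(ev@kind, deletion = e + 1L,
                             tandem_duplication = e, inversion = e))
    }
    addSeg(cur, ln, "+")
    pieces[[ch]] <- seg
    dnames <- c(dnames, ch)
  }

  for (ev in events) {
    if (ev@kind != "whole_chromosome_gain") next
    nm <- make.unique(c(dnames, paste0(ev@chrom, "_gain")))[length(dnames) + 1L]
    pieces[[nm]] <- data.frame(rstart = 1L, rend = nchar(ref[[ev@chrom]]),
                               strand = "+", ins = "")
    attr(pieces[[nm]], "rchrom") <- ev@chrom
    dnames <- c(dnames, nm)
  }

  dseqs <- character(0)
  blocks <- list()
  for (nm in dnames) {
    seg <- pieces[[nm]]
    rch <- attr(seg, "rchrom") %||% nm
    parts <- character(nrow(seg))
    w <- integer(nrow(seg))
    for (i in seq_len(nrow(seg))) {
      if (nzchar(seg$ins[i])) {
        parts[i] <- seg$ins[i]
      } else {
        x <- substr(ref[[rch]], seg$rstart[i], seg$rend[i])
        if (seg$strand[i] == "-") x <- .revcomp(x)
        parts[i] <- x
      }
      w[i] <- nchar(parts[i])
    }
    dstart <- cumsum(c(1L, w[-length(w)]))
    blocks[[nm]] <- data.frame(dchrom = nm, dstart = dstart,
                               dend = dstart + w - 1L,
                               rchrom = ifelse(nzchar(seg$ins), NA_character_, rch),
                               rstart = seg$rstart, rend = seg$rend,
                               strand = seg$strand)
    dseqs[[nm]] <- paste(parts, collapse = "")
  }
  blocks <- do.call(rbind, blocks)
  rownames(blocks) <- NULL
  derived <- Biostrings::DNAStringSet(dseqs)
  map <- new("CoordinateMap", blocks = blocks,
             derivedLengths = genomeLengths(derived))
  junctions <- if (length(jx)) do.call(rbind, jx) else
    data.frame(event = integer(0))
  list(genome = derived, map = map,
       reference = Biostrings::DNAStringSet(ref), junctions = junctions)
}

#' Identity coordinate map over a reference genome
#'
#' The map of an unrearranged genome onto itself: one forward block per
#' chromosome. Useful for simulating a parental control library with
#' [simulateMatePairs()].
#'
#' @param genome named `DNAStringSet`, or a named integer vector of
#'   chromosome lengths.
#' @return A [CoordinateMap-class].
#' @export
identityCoordinateMap <- function(genome) {
  lens <- if (is.numeric(genome)) {
    stats::setNames(as.integer(genome), names(genome))
  } else genomeLengths(genome)
  stopifnot(length(lens) >= 1L, !is.null(names(lens)))
  new("CoordinateMap",
      blocks = data.frame(dchrom = names(lens), dstart = 1L,
                          dend = unname(lens), rchrom = names(lens),
                          rstart = 1L, rend = unname(lens), strand = "+"),
      derivedLengths = lens)
}

# ---- coordinate lifting ---------------------------------------------------

#' Lift derived-genome positions to the reference
#'
#' @param map a [CoordinateMap-class].
#' @param chrom,pos parallel vectors of derived chromosome names and 1-based
#'   positions.
#' @return data.frame with columns `chrom`, `pos`, `strand`; `NA` rows for
#'   positions falling in non-templated insertion blocks.
#' @export
liftToReference <- function(map, chrom, pos) {
  chrom <- rep_len(as.character(chrom), length(pos))
  b <- map@blocks
  out <- data.frame(chrom = rep(NA_character_, length(pos)),
                    pos = rep(NA_integer_, length(pos)),
                    strand = rep(NA_character_, length(pos)))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    bb <- b[b$dchrom == ch, , drop = FALSE]
    if (!nrow(bb)) stop("derived chromosome not in map: ", ch)
    bb <- bb[order(bb$dstart), , drop = FALSE]
    idx <- findInterval(pos[sel], bb$dstart)
    bad <- idx < 1L | pos[sel] > bb$dend[pmax(idx, 1L)]
    if (any(bad)) stop("position outside derived chromosome ", ch)
    fwd <- bb$strand[idx] == "+"
    rp <- ifelse(fwd, bb$rstart[idx] + (pos[sel] - bb$dstart[idx]),
                 bb$rend[idx] - (pos[sel] - bb$dstart[idx]))
    out$chrom[sel] <- bb$rchrom[idx]
    out$pos[sel] <- ifelse(is.na(bb$rchrom[idx]), NA_integer_, as.integer(rp))
    out$strand[sel] <- ifelse(is.na(bb$rchrom[idx]), NA_character_, bb$strand[idx])
  }
  out
}

#' Lift derived-genome intervals to the reference
#'
#' An interval lifts cleanly only when it lies entirely within one map
#' block; intervals straddling a junction (or touching an insertion block)
#' come back as `NA` rows, mirroring how junction-crossing reads are dropped
#' rather than split-mapped.
#'
#' @param map a [CoordinateMap-class].
#' @param chrom,start,end parallel vectors describing derived intervals.
#' @return data.frame with `chrom`, `start`, `end`, `strand` (`NA` rows for
#'   non-liftable intervals).
#' @export
liftRangeToReference <- function(map, chrom, start, end) {
  n <- length(start)
  chrom <- rep_len(as.character(chrom), n)
  b <- map@blocks
  out <- data.frame(chrom = rep(NA_character_, n), start = rep(NA_integer_, n),
                    end = rep(NA_integer_, n), strand = rep(NA_character_, n))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    bb <- b[b$dchrom == ch, , drop = FALSE]
    if (!nrow(bb)) stop("derived chromosome not in map: ", ch)
    bb <- bb[order(bb$dstart), , drop = FALSE]
    idx <- findInterval(start[sel], bb$dstart)
    ok <- idx >= 1L & end[sel] <= bb$dend[pmax(idx, 1L)] &
      start[sel] >= bb$dstart[pmax(idx, 1L)] & !is.na(bb$rchrom[pmax(idx, 1L)])
    fwd <- bb$strand[idx] == "+"
    rs <- ifelse(fwd, bb$rstart[idx] + (start[sel] - bb$dstart[idx]),
                 bb$rend[idx] - (end[sel] - bb$dstart[idx]))
    re <- ifelse(fwd, bb$rstart[idx] + (end[sel] - bb$dstart[idx]),
                 bb$rend[idx] - (start[sel] - bb$dstart[idx]))
    out$chrom[sel] <- ifelse(ok, bb$rchrom[idx], NA_character_)
    out$start[sel] <- ifelse(ok, as.integer(rs), NA_integer_)
    out$end[sel] <- ifelse(ok, as.integer(re), NA_integer_)
    out$strand[sel] <- ifelse(ok, bb$strand[idx], NA_character_)
  }
  out
}

#' Locate reference positions in the derived genome
#'
#' Inverse lookup: all derived positions mapping to a given reference
#' position (a tandem duplication yields two).
#'
#' @param map a [CoordinateMap-class].
#' @param chrom,pos parallel reference chromosome/position vectors.
#' @return data.frame with `query` (input index), `dchrom`, `dpos`.
#' @export
mapToDerived <- function(map, chrom, pos) {
  chrom <- rep_len(as.character(chrom), length(pos))
  b <- map@blocks[!is.na(map@blocks$rchrom), , drop = FALSE]
  res <- list()
  for (i in seq_along(pos)) {
    hit <- b[b$rchrom == chrom[i] & b$rstart <= pos[i] & b$rend >= pos[i], ,
             drop = FALSE]
    if (nrow(hit)) {
      dpos <- ifelse(hit$strand == "+", hit$dstart + (pos[i] - hit$rstart),
                     hit$dstart + (hit$rend - pos[i]))
      res[[length(res) + 1L]] <- data.frame(query = i, dchrom = hit$dchrom,
                                            dpos = as.integer(dpos))
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(query = integer(0), dchrom = character(0), dpos = integer(0))
}

# ---- junction read synthesis ---------------------------------------------

#' Synthesize a junction-spanning read and its two reference flanks
#'
#' Emulates a Sanger consensus read across a rearrangement junction
#' (noise-free; chromatogram parsing and sequencing error are out of scope).
#' Flanks are taken from the engineered reference around the two junction
#' loci and pre-oriented so each flank's junction-adjacent end faces the
#' split, extended `pad` bases past the junction so that shared
#' (microhomologous) bases are visible on both sides.
#'
#' @param reference the engineered reference `DNAStringSet` (the
#'   `reference` element returned by [applyRearrangements()]).
#' @param jxn one junction: a single row of the `junctions` data.frame from
#'   [applyRearrangements()] (or any list with `chrom`, `p`, `q`, `qStrand`,
#'   `insertedSeq`).
#' @param readHalf bases contributed by each locus to the read.
#' @param flankLen flank length on the junction-distal side.
#' @param pad flank extension past the junction (must exceed the largest
#'   microhomology of interest).
#' @return list with `read`, `leftFlank`, `rightFlank` (character), plus the
#'   anchoring info `chrom`, `p`, `q`, `qStrand`.
#' @export
makeJunctionObservation <- function(reference, jxn, readHalf = 60,
                                    flankLen = 200, pad = 30) {
  ch <- as.character(jxn$chrom)
  p <- as.integer(jxn$p); q <- as.integer(jxn$q)
  qStrand <- as.character(jxn$qStrand)
  ins <- if (!is.null(jxn$insertedSeq)) as.character(jxn$insertedSeq) else ""
  refSeq <- as.character(reference[[ch]])
  n <- nchar(refSeq)
  clamp <- function(x) pmin(pmax(x, 1L), n)
  leftPart <- substr(refSeq, clamp(p - readHalf + 1L), p)
  rightPart <- if (qStrand == "+") substr(refSeq, q, clamp(q + readHalf - 1L))
               else .revcomp(substr(refSeq, clamp(q - readHalf + 1L), q))
  leftFlank <- substr(refSeq, clamp(p - flankLen + 1L), clamp(p + pad))
  rightFlank <- if (qStrand == "+")
    substr(refSeq, clamp(q - pad), clamp(q + flankLen - 1L))
  else .revcomp(substr(refSeq, clamp(q - flankLen + 1L), clamp(q + pad)))
  list(read = paste0(leftPart, ins, rightPart),
       leftFlank = leftFlank, rightFlank = rightFlank,
       chrom = ch, p = p, q = q, qStrand = qStrand)
}
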