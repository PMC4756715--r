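#' Derive a per-operation RNG seed from a master seed
#'
#' One master seed fans out to independent per-operation streams through a
#' fixed label hash, so that adding or reordering stages does not perturb the
#' randomness of unrelated stages. Always < 2^31.
#'
#' @param seed master integer seed.
#' @param label short operation label, e.g. `"mate_pairs"`.
#' @return An integer seed.
#' @export
fanOutSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v)) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 1048573 * 48271 + h * 1103 + 17) %% 2147483647)
}

.msg <- function(...) message("[aneuscan] ", sprintf(...))

# deterministic replacement base differing from `avoid` (and from `current`
# when possible) -- used to break chance microhomology at junction boundaries
.pickDifferentBase <- function(avoid, current = NULL) {
  for (b in c("A", "C", "G", "T"))
    if (b != avoid && (is.null(current) || b != current)) return(b)
  "A"
}

.compBase <- function(b) chartr("ACGT", "TGCA", b)

# give a list of GRanges a common seqlevel universe so that combining or
# overlapping them does not trigger merge warnings
.harmonizeSeqlevels <- function(...) {
  grs <- list(...)
  lv <- unique(unlist(lapply(grs, GenomeInfoDb::seqlevels)))
  lapply(grs, function(g) {
    GenomeInfoDb::seqlevels(g) <- lv
    g
  })
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
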