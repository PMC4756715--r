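#' Generate a toy genome of i.i.d. bases
#'
#' Bases are drawn independently with `P(G) + P(C) = gcFraction` (split
#' evenly between G and C, and between A and T). Reproducible for a fixed
#' seed.
#'
#' @param chromLengths named integer vector of chromosome lengths (>= 1;
#'   10 kb or more recommended so that read anchors are unique).
#' @param gcFraction GC content in `[0, 1]`.
#' @param seed integer RNG seed (mandatory).
#' @return A named [Biostrings::DNAStringSet].
#' @examples
#' g <- makeToyGenome(c(chrA = 1000), gcFraction = 0.5, seed = 7)
#' @export
makeToyGenome <- function(chromLengths, gcFraction = 0.41, seed) {
  stopifnot(!missing(seed), length(chromLengths) >= 1L,
            !is.null(names(chromLengths)), all(nzchar(names(chromLengths))))
  if (any(chromLengths <= 0)) stop("chromosome lengths must be positive")
  if (gcFraction < 0 || gcFraction > 1) stop("gcFraction must be in [0,1]")
  set.seed(as.integer(seed))
  p <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
         G = gcFraction / 2, T = (1 - gcFraction) / 2)
  seqs <- vapply(chromLengths, function(n) {
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  }, character(1L))
  Biostrings::DNAStringSet(seqs)
}

#' Chromosome lengths of a genome
#' @param genome a named `DNAStringSet`.
#' @return Named integer vector.
#' @export
genomeLengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}
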