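#' @importFrom stats dhyper p.adjust rbinom rmultinom rnorm rpois runif
#'   setNames wilcox.test median qlogis
#' @importFrom utils head tail
#' @import methods
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Reverse-complement a character vector of DNA strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that accepts and
#' returns plain character vectors (N and other IUPAC letters allowed).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Strand-aware mirroring utilities: reflecting every coordinate through the
## contig midpoint and reverse-complementing the sequence must leave every
## stage of the pipeline invariant (up to the mirrored coordinates).

#' Mirror a genome (reverse-complement every contig)
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @return a `DNAStringSet` with each contig reverse-complemented.
#' @export
mirror_genome <- function(genome) {
  out <- Biostrings::reverseComplement(genome)
  names(out) <- names(genome)
  out
}

#' Mirror genomic positions through the contig midpoint
#'
#' Maps 1-based position `p` on a contig of length `L` to `L - p + 1`, the
#' coordinate it occupies after the contig is reverse-complemented.
#'
#' @param pos integer vector of 1-based positions.
#' @param contig_length integer vector (recycled) of contig lengths.
#' @return integer vector of mirrored positions.
#' @export
mirror_position <- function(pos, contig_length) {
  as.integer(contig_length - pos + 1L)
}

#' Mirror a set of read records
#'
#' Reflects read intervals through the contig midpoint and flips their
#' strand, producing the read set that aligning to the mirrored genome
#' would yield.
#'
#' @param reads a [GenomicRanges::GRanges] of read records.
#' @param contig_lengths named integer vector of contig lengths.
#' @return a `GRanges` with mirrored coordinates and flipped strands.
#' @export
mirror_reads <- function(reads, contig_lengths) {
  L <- contig_lengths[as.character(GenomicRanges::seqnames(reads))]
  new_start <- mirror_position(GenomicRanges::end(reads), L)
  new_end <- mirror_position(GenomicRanges::start(reads), L)
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(reads),
    ranges = IRanges::IRanges(start = new_start, end = new_end),
    strand = ifelse(as.character(GenomicRanges::strand(reads)) == "+", "-", "+")
  )
  S4Vectors::mcols(out) <- S4Vectors::mcols(reads)
  out
}

## deterministic local RNG scope: run expr under a seed without disturbing
## the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## modal value of an integer vector; ties broken towards the transcript
## 3'-most coordinate (max on "+", min on "-")
modal_position <- function(pos, strand) {
  tab <- table(pos)
  cand <- as.integer(names(tab)[tab == max(tab)])
  if (strand == "-") min(cand) else max(cand)
}
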