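## Targeted 3'UTR-lengthening index from RNA-seq read coverage: the mean
## per-base depth over a user-defined extension segment (unique to the long
## 3'UTR isoform) divided by the mean depth over the common segment (shared
## by both isoforms). Values near 1 indicate predominant use of the long
## isoform; near 0, the short one.

#' Define the common / extension segments of a 3'UTR
#'
#' @param gene_id gene identifier.
#' @param chrom contig name.
#' @param strand `"+"` or `"-"`.
#' @param common,extension integer pairs `(start, end)` (1-based
#'   inclusive): the segment shared by short and long isoforms, and the
#'   segment unique to the long isoform. Must not overlap, and the
#'   extension must lie 3' of the common segment in transcript
#'   orientation.
#' @return list of class `utr_segments`.
#' @export
utr_segments <- function(gene_id, chrom, strand, common, extension) {
  stop_if(!strand %in% c("+", "-"), "strand must be + or -")
  stop_if(length(common) != 2L || length(extension) != 2L ||
            common[1] > common[2] || extension[1] > extension[2],
          "segments must be (start, end) pairs with start <= end")
  stop_if(common[1] <= extension[2] && extension[1] <= common[2],
          "segments must not overlap")
  three_prime <- if (strand == "+") extension[1] > common[2] else
    extension[2] < common[1]
  stop_if(!three_prime,
          "extension must lie 3' of the common segment in transcript ",
          "orientation")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 common = as.integer(common),
                 extension = as.integer(extension)),
            class = "utr_segments")
}

#' Per-base coverage from read records
#'
#' @param reads a `GRanges` of read records.
#' @return an [IRanges::RleList] of per-base depths (one element per
#'   contig), ignoring strand.
#' @export
coverage_track <- function(reads) {
  GenomicRanges::coverage(reads)
}

#' Read a bedGraph file into a coverage track
#'
#' @param path bedGraph file (`chrom  start0  end  value`).
#' @param contig_lengths named integer vector of contig lengths.
#' @return an [IRanges::RleList] of per-base depths.
#' @export
read_bedgraph <- function(path, contig_lengths) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  out <- lapply(names(contig_lengths), function(ch) {
    v <- numeric(contig_lengths[[ch]])
    sub <- dt[dt$chrom == ch, ]
    for (i in seq_len(nrow(sub))) {
      v[(sub$start[i] + 1L):sub$end[i]] <- sub$value[i]
    }
    methods::as(v, "Rle")
  })
  names(out) <- names(contig_lengths)
  methods::as(out, "RleList")
}

segment_mean <- function(coverage, chrom, seg) {
  stop_if(!chrom %in% names(coverage), "contig absent from coverage: ", chrom)
  v <- coverage[[chrom]]
  stop_if(seg[2] > length(v), "segment extends past the coverage track")
  mean(as.numeric(v[seg[1]:seg[2]]))
}

#' 3'UTR lengthening index from coverage
#'
#' `mean coverage(extension) / mean coverage(common)`; `NA` (flagged by
#' attribute `undefined`) when the common segment has zero mean coverage.
#' The index is scale-invariant: multiplying all coverage by a constant
#' leaves it unchanged.
#'
#' @param coverage an `RleList` ([coverage_track()] / [read_bedgraph()]).
#' @param segments a [utr_segments()].
#' @return the index (numeric scalar).
#' @export
lengthening_index <- function(coverage, segments) {
  stopifnot(inherits(segments, "utr_segments"))
  stop_if(diff(segments$common) < 0 || diff(segments$extension) < 0,
          "zero-length segment")
  cm <- segment_mean(coverage, segments$chrom, segments$common)
  em <- segment_mean(coverage, segments$chrom, segments$extension)
  if (cm == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  em / cm
}

#' Compare lengthening indices between two sample groups
#'
#' Two-sided Mann-Whitney test plus group medians.
#'
#' @param indices_a,indices_b numeric index vectors (both non-empty).
#' @param labels group names.
#' @return list: `statistic`, `p_value`, `medians`, `n`, `labels`.
#' @export
compare_index_groups <- function(indices_a, indices_b,
                                 labels = c("group_a", "group_b")) {
  stop_if(length(indices_a) == 0L || length(indices_b) == 0L,
          "both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(indices_a, indices_b,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       medians = c(stats::median(indices_a), stats::median(indices_b)),
       n = c(length(indices_a), length(indices_b)), labels = labels)
}
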