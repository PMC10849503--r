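## PolyA-site calling from aligned 3'-end reads: read-end extraction,
## internal-priming (mis-priming) removal, single-linkage clustering of
## cleavage positions, replicate-reproducibility filtering, PAS hexamer
## detection and novelty annotation against a known-site set.

#' Canonical human PAS hexamer variants
#'
#' The twelve hexamers commonly accepted as functional polyadenylation
#' signals, strongest first.
#' @export
CANONICAL_PAS_HEXAMERS <- c(
  "AATAAA", "ATTAAA", "AGTAAA", "TATAAA", "CATAAA", "GATAAA",
  "AATATA", "AATACA", "AATAGA", "AAAAAG", "ACTAAA", "AATGAA")

#' Extract transcript-sense cleavage positions from aligned reads
#'
#' For a 3'-end protocol each read marks a cleavage/polyadenylation
#' position: the transcript-3'-most aligned base. With
#' `orientation = "sense"` the read's mapped strand equals the transcript
#' strand (cleavage at the interval end on `+`, start on `-`); with
#' `"antisense"` (e.g. reads sequenced from the reverse strand) the mapped
#' strand is flipped first.
#'
#' @param reads a [GenomicRanges::GRanges] of read records with a `sample`
#'   metadata column.
#' @param orientation `"sense"` or `"antisense"`.
#' @return a [data.table::data.table] of read ends with columns `chrom`,
#'   `strand` (transcript strand), `pos` (1-based cleavage coordinate),
#'   `sample`, `read_id`.
#' @export
extract_read_ends <- function(reads, orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  map_strand <- as.character(GenomicRanges::strand(reads))
  stop_if(any(!map_strand %in% c("+", "-")),
          "reads must be stranded (+/-)")
  tx_strand <- if (orientation == "sense") map_strand else
    ifelse(map_strand == "+", "-", "+")
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(reads)),
    strand = tx_strand,
    pos = ifelse(tx_strand == "+", GenomicRanges::end(reads),
                 GenomicRanges::start(reads)),
    sample = S4Vectors::mcols(reads)$sample %||%
      rep("sample1", length(reads)),
    read_id = S4Vectors::mcols(reads)$read_id %||%
      sprintf("read%07d", seq_along(reads))
  )
}

## transcript-sense downstream window (the sequence an oligo-dT primer could
## have annealed to), as a character vector; bases past the contig end
## become "N" and never count as A
downstream_window <- function(chrom, pos, strand, genome, window = 10L) {
  chrom <- rep_len(chrom, length(pos))
  strand <- rep_len(strand, length(pos))
  seqs <- as.character(genome)
  lens <- nchar(seqs)
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    s <- seqs[[ch]]
    L <- lens[[ch]]
    plus <- idx[strand[idx] == "+"]
    if (length(plus)) {
      lo <- pos[plus] + 1L
      hi <- pmin(pos[plus] + window, L)
      out[plus] <- substring(s, lo, hi)
    }
    minus <- idx[strand[idx] == "-"]
    if (length(minus)) {
      lo <- pmax(pos[minus] - window, 1L)
      hi <- pos[minus] - 1L
      w <- substring(s, lo, hi)
      ok <- nchar(w) > 0L
      w[ok] <- revcomp(w[ok])
      out[minus] <- w
    }
  }
  ## right-pad truncated windows with N so positional tests stay aligned
  short <- nchar(out) < window
  if (any(short)) {
    out[short] <- vapply(out[short], function(x) {
      paste0(x, strrep("N", window - nchar(x)))
    }, "")
  }
  out
}

#' Internal-priming (mis-priming) test for read ends
#'
#' A read end is flagged as mis-primed when the transcript-sense genomic
#' sequence immediately 3' of its cleavage position begins with at least
#' `min_run` consecutive `A`, or when the first `window` nt of that sequence
#' contain at least `min_a` `A` (default: 6 consecutive A, or >= 6 A in
#' 10 nt, i.e. >= 60% A). The window starts at the first genomic base 3' of
#' the cleavage base; on the minus strand the genomic window is
#' reverse-complemented before testing. Bases beyond the contig end count as
#' non-A.
#'
#' @param chrom,pos,strand parallel vectors describing read ends (1-based
#'   cleavage coordinates, transcript strand).
#' @param genome a [Biostrings::DNAStringSet].
#' @param min_run minimum leading A-run length.
#' @param window window length (nt) for the A-content clause.
#' @param min_a minimum number of A within `window`.
#' @return logical vector, `TRUE` where mis-primed.
#' @export
is_misprimed <- function(chrom, pos, strand, genome,
                         min_run = 6L, window = 10L, min_a = 6L) {
  stop_if(!all(chrom %in% names(genome)),
          "read ends on contigs absent from the genome")
  chrom <- rep_len(chrom, length(pos))
  strand <- rep_len(strand, length(pos))
  w <- downstream_window(chrom, pos, strand, genome, window = window)
  lead_run <- substr(w, 1L, min_run) == strrep("A", min_run)
  n_a <- nchar(w) - nchar(gsub("A", "", w, fixed = TRUE))
  lead_run | (n_a >= min_a)
}

#' Remove mis-primed read ends
#'
#' @param ends a read-end table from [extract_read_ends()].
#' @inheritParams is_misprimed
#' @return list with `ends` (retained read-end table), `removed` (the
#'   mis-primed rows) and `n_removed`.
#' @export
filter_misprimed <- function(ends, genome, min_run = 6L, window = 10L,
                             min_a = 6L) {
  bad <- is_misprimed(ends$chrom, ends$pos, ends$strand, genome,
                      min_run = min_run, window = window, min_a = min_a)
  list(ends = ends[!bad], removed = ends[bad], n_removed = sum(bad))
}

#' Cluster read ends into polyA sites
#'
#' Single-linkage clustering of same-contig, same-strand cleavage positions:
#' a new cluster starts whenever the gap to the previous position exceeds
#' `max_gap`. The representative position is the modal terminus (ties broken
#' towards the transcript 3' end); clusters with fewer than `min_reads`
#' total reads are discarded.
#'
#' @param ends a read-end table ([extract_read_ends()]), already
#'   mis-priming-filtered.
#' @param max_gap maximum intra-cluster gap between adjacent termini (nt).
#' @param min_reads minimum total reads per retained site.
#' @param samples character vector fixing the sample (column) order of the
#'   count matrix; defaults to the sorted samples present.
#' @return a [GenomicRanges::GRanges] of sites (cluster intervals) with
#'   metadata `site_id`, `rep_pos`, `n_reads` and a site-by-sample matrix
#'   column `counts`.
#' @export
cluster_ends <- function(ends, max_gap = 25L, min_reads = 3L,
                         samples = NULL) {
  stop_if(min_reads < 1L, "min_reads must be >= 1")
  stop_if(max_gap < 0L, "max_gap must be >= 0")
  if (is.null(samples)) samples <- sort(unique(ends$sample))
  dt <- data.table::as.data.table(ends)
  data.table::setorderv(dt, c("chrom", "strand", "pos"))
  dt[, grp := paste(chrom, strand)]
  dt[, new_cluster := c(TRUE, diff(pos) > max_gap), by = grp]
  dt[, cluster := cumsum(new_cluster)]

  cl <- dt[, {
    rp <- modal_position(pos, strand[1])
    c(list(chrom = chrom[1], strand = strand[1],
           cluster_start = min(pos), cluster_end = max(pos),
           rep_pos = rp, n_reads = .N),
      as.list(tabulate(factor(sample, levels = samples),
                       nbins = length(samples))))
  }, by = cluster]
  data.table::setnames(cl, c("cluster", "chrom", "strand", "cluster_start",
                             "cluster_end", "rep_pos", "n_reads", samples))
  cl <- cl[cl$n_reads >= min_reads, ]
  ## stable genomic order
  data.table::setorderv(cl, c("chrom", "cluster_start", "strand"))
  counts <- as.matrix(cl[, samples, with = FALSE])
  rownames(counts) <- NULL
  sites <- GenomicRanges::GRanges(
    seqnames = cl$chrom,
    ranges = IRanges::IRanges(start = cl$cluster_start,
                              end = cl$cluster_end),
    strand = cl$strand,
    site_id = sprintf("site_%s_%d_%s", cl$chrom, cl$rep_pos, cl$strand),
    rep_pos = cl$rep_pos,
    n_reads = cl$n_reads
  )
  S4Vectors::mcols(sites)$counts <- counts
  sites
}

#' Replicate-reproducibility filter for called sites
#'
#' A site is "detected" in a sample when its count is at least
#' `detection_min_reads`. The replication rate is the detected fraction of
#' replicates, computed per condition (`scope = "per_condition"`, the site's
#' best-supported condition) or across all samples (`scope = "overall"`).
#' Sites with rate below `min_rate` are removed.
#'
#' @param sites a sites `GRanges` from [cluster_ends()].
#' @param sample_sheet data.frame with `sample` and `condition` columns.
#' @param min_rate minimum replication rate in (0, 1].
#' @param detection_min_reads reads needed to count a sample as detecting
#'   the site.
#' @param scope `"per_condition"` (max over conditions) or `"overall"`.
#' @return the filtered `GRanges`, with a `replication_rate` metadata
#'   column.
#' @export
replication_filter <- function(sites, sample_sheet, min_rate = 0.75,
                               detection_min_reads = 1L,
                               scope = c("per_condition", "overall")) {
  scope <- match.arg(scope)
  stop_if(min_rate <= 0 || min_rate > 1, "min_rate must be in (0, 1]")
  cnt <- S4Vectors::mcols(sites)$counts
  stop_if(is.null(cnt), "sites carry no count matrix")
  cond <- sample_sheet$condition[match(colnames(cnt), sample_sheet$sample)]
  stop_if(anyNA(cond), "count columns missing from the sample sheet")
  det <- cnt >= detection_min_reads
  rate <- if (scope == "overall") {
    rowMeans(det)
  } else {
    apply(vapply(unique(cond), function(cc) {
      rowMeans(det[, cond == cc, drop = FALSE])
    }, numeric(nrow(det))), 1, max)
  }
  S4Vectors::mcols(sites)$replication_rate <- rate
  sites[rate >= min_rate]
}

#' Detect the polyadenylation signal (PAS) upstream of each site
#'
#' Scans the transcript-sense sequence for hexamer matches whose start lies
#' `search_window[1]`..`search_window[2]` nt upstream of the representative
#' cleavage position and keeps the hit closest to the canonical offset
#' (21 nt). Adds `pas_hexamer` / `pas_offset` metadata (`NA` when absent).
#'
#' @param sites a sites `GRanges`.
#' @param genome a [Biostrings::DNAStringSet].
#' @param search_window integer pair: upstream offset range (nt) of the
#'   hexamer start relative to `rep_pos`.
#' @param hexamers candidate PAS hexamers, in priority order for exact-offset
#'   ties.
#' @param canonical_offset preferred upstream offset (nt).
#' @return the `GRanges` with PAS metadata added.
#' @export
detect_pas <- function(sites, genome, search_window = c(10L, 40L),
                       hexamers = CANONICAL_PAS_HEXAMERS,
                       canonical_offset = 21L) {
  stop_if(length(search_window) != 2L || diff(search_window) < 0,
          "search_window must be an increasing pair")
  n <- length(sites)
  hex <- rep(NA_character_, n)
  off <- rep(NA_integer_, n)
  if (n > 0L) {
    chrom <- as.character(GenomicRanges::seqnames(sites))
    strand <- as.character(GenomicRanges::strand(sites))
    rp <- S4Vectors::mcols(sites)$rep_pos
    span <- search_window[2] - search_window[1] + 6L
    ## sense window covering all candidate hexamer starts
    win <- upstream_window(chrom, rp, strand, genome,
                           from = search_window[2], len = span)
    for (i in seq_len(n)) {
      best <- NULL
      for (h in hexamers) {
        starts <- gregexpr(h, win[i], fixed = TRUE)[[1]]
        if (starts[1] == -1L) next
        ## window index j corresponds to upstream offset
        offs <- search_window[2] - (starts - 1L)
        offs <- offs[offs >= search_window[1] & offs <= search_window[2]]
        for (o in offs) {
          d <- abs(o - canonical_offset)
          if (is.null(best) || d < best$d) best <- list(h = h, o = o, d = d)
        }
      }
      if (!is.null(best)) {
        hex[i] <- best$h
        off[i] <- best$o
      }
    }
  }
  S4Vectors::mcols(sites)$pas_hexamer <- hex
  S4Vectors::mcols(sites)$pas_offset <- off
  sites
}

## transcript-sense window whose first base is `from` nt upstream of pos,
## of length `len`; N-padded at contig edges
upstream_window <- function(chrom, pos, strand, genome, from, len) {
  seqs <- as.character(genome)
  lens <- nchar(seqs)
  out <- character(length(pos))
  for (i in seq_along(pos)) {
    s <- seqs[[chrom[i]]]
    L <- lens[[chrom[i]]]
    if (strand[i] == "+") {
      lo <- pos[i] - from
      hi <- lo + len - 1L
      w <- substr(s, max(lo, 1L), min(hi, L))
      pad_l <- max(0L, 1L - lo)
      pad_r <- max(0L, hi - L)
    } else {
      hi <- pos[i] + from
      lo <- hi - len + 1L
      w <- substr(s, max(lo, 1L), min(hi, L))
      if (nchar(w) > 0L) w <- revcomp(w)
      pad_l <- max(0L, hi - L)
      pad_r <- max(0L, 1L - lo)
    }
    out[i] <- paste0(strrep("N", pad_l), w, strrep("N", pad_r))
  }
  out
}

#' Flag sites absent from a known polyA-site annotation
#'
#' A site is novel iff no known site on the same strand lies within
#' `tolerance` nt of its representative position.
#'
#' @param sites a sites `GRanges`.
#' @param known_sites a `GRanges` of known sites (e.g. from [read_bed6()]);
#'   may be empty.
#' @param tolerance maximum distance (nt) for a match.
#' @return the `GRanges` with an `is_novel` logical metadata column.
#' @export
annotate_novel <- function(sites, known_sites, tolerance = 10L) {
  if (length(known_sites) == 0L) {
    S4Vectors::mcols(sites)$is_novel <- rep(TRUE, length(sites))
    return(sites)
  }
  pts <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(sites),
    ranges = IRanges::IRanges(start = S4Vectors::mcols(sites)$rep_pos,
                              width = 1L),
    strand = GenomicRanges::strand(sites))
  wide <- suppressWarnings(GenomicRanges::resize(
    GenomicRanges::shift(known_sites, -tolerance),
    GenomicRanges::width(known_sites) + 2L * tolerance))
  hits <- GenomicRanges::findOverlaps(pts, wide, ignore.strand = FALSE)
  novel <- rep(TRUE, length(sites))
  novel[unique(S4Vectors::queryHits(hits))] <- FALSE
  S4Vectors::mcols(sites)$is_novel <- novel
  sites
}

#' Call polyA sites from aligned 3'-end reads
#'
#' End-to-end site calling: extract read ends, remove mis-primed reads,
#' cluster, apply the replication filter, detect PAS hexamers and
#' (optionally) flag novel sites against a known-site annotation.
#'
#' @param reads a `GRanges` of read records with `sample` metadata.
#' @param genome a [Biostrings::DNAStringSet].
#' @param sample_sheet data.frame with `sample` and `condition`.
#' @param orientation protocol orientation, see [extract_read_ends()].
#' @param max_gap,min_reads clustering parameters ([cluster_ends()]).
#' @param min_replication,detection_min_reads,replication_scope replication
#'   filter parameters ([replication_filter()]).
#' @param pas_window,hexamers PAS scan parameters ([detect_pas()]).
#' @param known_sites optional known-site `GRanges` for novelty annotation.
#' @param novel_tolerance matching tolerance (nt) for novelty.
#' @return list of class `apa_sites`: `sites` (annotated `GRanges`) and
#'   `stats` (read/site attrition counts).
#' @export
call_polya_sites <- function(reads, genome, sample_sheet,
                             orientation = "sense",
                             max_gap = 25L, min_reads = 3L,
                             min_replication = 0.75,
                             detection_min_reads = 1L,
                             replication_scope = "per_condition",
                             pas_window = c(10L, 40L),
                             hexamers = CANONICAL_PAS_HEXAMERS,
                             known_sites = NULL, novel_tolerance = 10L) {
  ends <- extract_read_ends(reads, orientation)
  flt <- filter_misprimed(ends, genome)
  sites <- cluster_ends(flt$ends, max_gap = max_gap, min_reads = min_reads,
                        samples = sample_sheet$sample)
  n_clustered <- length(sites)
  sites <- replication_filter(sites, sample_sheet, min_rate = min_replication,
                              detection_min_reads = detection_min_reads,
                              scope = replication_scope)
  sites <- detect_pas(sites, genome, search_window = pas_window,
                      hexamers = hexamers)
  if (!is.null(known_sites)) {
    sites <- annotate_novel(sites, known_sites, tolerance = novel_tolerance)
  }
  out <- list(
    sites = sites,
    stats = list(
      n_reads = nrow(ends),
      n_misprimed_removed = flt$n_removed,
      n_sites_clustered = n_clustered,
      n_sites_replicated = length(sites)
    ),
    removed_ends = flt$removed
  )
  class(out) <- "apa_sites"
  out
}
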