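## Cryptic polyA-site classification: sites essentially silent in control
## (usage <= 5%) that become used upon knockdown (>= 10%, increase >= 10%),
## classified by genomic region (premature / 3'UTR-internal / downstream of
## the annotated gene end), optionally coupled with cryptic splice
## junctions, plus a binding-site overlap summary for APA genes.

#' Flag cryptic polyA sites from condition usages
#'
#' A site is cryptic iff `control <= control_max` AND
#' `knockdown >= knockdown_min` AND the increase is `>= increase_min`
#' (all boundaries inclusive). Defaults: 0.05 / 0.10 / 0.10.
#'
#' @param usage_control,usage_knockdown condition usage fractions
#'   (vectorised).
#' @param control_max,knockdown_min,increase_min rule thresholds.
#' @return logical vector.
#' @export
call_cryptic <- function(usage_control, usage_knockdown,
                         control_max = 0.05, knockdown_min = 0.10,
                         increase_min = 0.10) {
  eps <- 1e-12  # boundary-inclusive under floating-point arithmetic
  !is.na(usage_control) & !is.na(usage_knockdown) &
    usage_control <= control_max + eps &
    usage_knockdown >= knockdown_min - eps &
    (usage_knockdown - usage_control) >= increase_min - eps
}

#' Classify a site's genomic region within its gene
#'
#' Strand-aware, mutually exclusive and exhaustive for assigned sites:
#' `downstream_of_annotated_end` when the position is 3' of the gene's most
#' distal annotated transcription end; `premature` when it is 5' of the
#' stop codon (within the CDS or an upstream intron), truncating the
#' transcript; `utr_internal` otherwise (between stop codon and annotated
#' end). Genes without CDS records are classified against the annotated
#' end only (never `premature`), with a warning.
#'
#' @param pos,strand,gene_id parallel vectors of site representative
#'   positions, strands and assigned genes.
#' @param gene_models gene-model data.frame with `tes` and `stop_pos`.
#' @return character vector of categories.
#' @export
classify_region <- function(pos, strand, gene_id, gene_models) {
  i <- match(gene_id, gene_models$gene_id)
  stop_if(anyNA(i), "sites assigned to genes absent from the models")
  tes <- gene_models$tes[i]
  stop_pos <- gene_models$stop_pos[i]
  if (anyNA(stop_pos)) {
    warning("gene model(s) lack a CDS; classifying against the annotated ",
            "3' end only")
  }
  plus <- strand == "+"
  downstream <- ifelse(plus, pos > tes, pos < tes)
  premature <- !is.na(stop_pos) &
    ifelse(plus, pos <= stop_pos, pos >= stop_pos)
  ifelse(downstream, "downstream_of_annotated_end",
         ifelse(premature, "premature", "utr_internal"))
}

#' Cryptic polyA events for a usage table
#'
#' Applies [call_cryptic()] to every assigned site and classifies each
#' event's region with [classify_region()].
#'
#' @param usage an `apa_usage` from [compute_usage()].
#' @param gene_models gene-model data.frame.
#' @inheritParams call_cryptic
#' @return data.table of cryptic events: gene, site, condition usages,
#'   increase and `category`.
#' @export
cryptic_events <- function(usage, gene_models, control_max = 0.05,
                           knockdown_min = 0.10, increase_min = 0.10) {
  dt <- usage$per_condition
  flag <- call_cryptic(dt$usage_control, dt$usage_knockdown,
                       control_max = control_max,
                       knockdown_min = knockdown_min,
                       increase_min = increase_min)
  ev <- dt[flag, c("gene_id", "site_id", "chrom", "strand", "rep_pos",
                   "usage_control", "usage_knockdown"), with = FALSE]
  ev$usage_increase <- ev$usage_knockdown - ev$usage_control
  ev$category <- if (nrow(ev)) {
    classify_region(ev$rep_pos, ev$strand, ev$gene_id, gene_models)
  } else {
    character(0)
  }
  ev
}

#' Couple premature cryptic polyA events with cryptic splice junctions
#'
#' A premature cryptic event is coupled to a junction when both belong to
#' the same gene and the site lies inside the junction's intron (the
#' coupling window extends through the remainder of the intron 3' of a
#' cryptic 3' splice site).
#'
#' @param events cryptic events ([cryptic_events()]).
#' @param junctions data.frame of cryptic junctions: `chrom`, `start`,
#'   `end` (intron, 1-based inclusive), `strand`, `gene_id`; `NULL` or
#'   empty for none.
#' @return the events with `coupled`, `junction_start`, `junction_end`
#'   columns.
#' @export
couple_with_splicing <- function(events, junctions = NULL) {
  events$coupled <- FALSE
  events$junction_start <- NA_integer_
  events$junction_end <- NA_integer_
  if (is.null(junctions) || nrow(junctions) == 0L || nrow(events) == 0L) {
    return(events)
  }
  for (i in seq_len(nrow(events))) {
    if (events$category[i] != "premature") next
    j <- junctions[junctions$gene_id == events$gene_id[i] &
                     junctions$strand == events$strand[i] &
                     junctions$start <= events$rep_pos[i] &
                     junctions$end >= events$rep_pos[i], , drop = FALSE]
    if (nrow(j) > 0L) {
      events$coupled[i] <- TRUE
      events$junction_start[i] <- j$start[1]
      events$junction_end[i] <- j$end[1]
    }
  }
  events
}

#' Fraction of APA genes overlapped by binding intervals
#'
#' A gene counts as overlapping when any binding interval intersects its
#' span plus the downstream extension (half-open abutment is not overlap).
#'
#' @param apa_gene_ids gene ids of genes with APA events.
#' @param gene_models gene-model data.frame.
#' @param binding a `GRanges` of binding intervals (e.g. [read_bed6()]);
#'   may be empty.
#' @param downstream_extension nt added past the annotated TES.
#' @param ignore_strand treat binding intervals as strand-agnostic
#'   (default TRUE, typical for CLIP peak sets).
#' @return list: `fraction`, `n_overlapping`, `n_genes` and per-gene
#'   `flags`.
#' @export
binding_overlap_summary <- function(apa_gene_ids, gene_models, binding,
                                    downstream_extension = 5000L,
                                    ignore_strand = TRUE) {
  gm <- gene_models[match(apa_gene_ids, gene_models$gene_id), , drop = FALSE]
  stop_if(anyNA(gm$gene_id), "APA gene ids absent from the gene models")
  if (length(binding) == 0L || nrow(gm) == 0L) {
    return(list(fraction = 0, n_overlapping = 0L, n_genes = nrow(gm),
                flags = stats::setNames(rep(FALSE, nrow(gm)), apa_gene_ids)))
  }
  lo <- ifelse(gm$strand == "+", gm$start,
               pmax(1L, gm$tes - downstream_extension))
  hi <- ifelse(gm$strand == "+", gm$tes + downstream_extension, gm$end)
  spans <- GenomicRanges::GRanges(
    seqnames = gm$chrom,
    ranges = IRanges::IRanges(start = lo, end = hi),
    strand = gm$strand)
  hits <- GenomicRanges::findOverlaps(spans, binding,
                                      ignore.strand = ignore_strand)
  flags <- rep(FALSE, nrow(gm))
  flags[unique(S4Vectors::queryHits(hits))] <- TRUE
  list(fraction = mean(flags), n_overlapping = sum(flags),
       n_genes = nrow(gm), flags = stats::setNames(flags, apa_gene_ids))
}
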