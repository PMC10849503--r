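## Differential polyA-site usage: gene assignment, usage fractions, the
## polyA usage index change (delta PUI), per-site exact tests with BH
## adjustment, gene-level site-pair selection and lengthening/shortening
## direction calls. A gene is tested only if it has at least two sites; the
## reported pair is the two sites with the largest usage changes; the call
## requires |delta PUI| > 0.10 and adjusted p < 0.05.

#' Assign called sites to genes
#'
#' A site belongs to a gene iff it lies on the gene's strand within the gene
#' span extended `downstream_extension` nt past the annotated transcription
#' end (so cryptic sites downstream of the annotated 3' end stay
#' attributable). A site matching several genes goes to the gene with the
#' nearest annotated 3' end.
#'
#' @param sites a sites `GRanges` (from [call_polya_sites()]).
#' @param gene_models gene-model data.frame ([read_gene_models()]).
#' @param downstream_extension nt of slack past the annotated TES.
#' @return the `GRanges` restricted to assigned sites, with a `gene_id`
#'   metadata column.
#' @export
assign_sites_to_genes <- function(sites, gene_models,
                                  downstream_extension = 5000L) {
  gm <- gene_models
  win_lo <- ifelse(gm$strand == "+", gm$start,
                   pmax(1L, gm$tes - downstream_extension))
  win_hi <- ifelse(gm$strand == "+", gm$tes + downstream_extension, gm$end)
  genes_gr <- GenomicRanges::GRanges(
    seqnames = gm$chrom,
    ranges = IRanges::IRanges(start = win_lo, end = win_hi),
    strand = gm$strand)
  pts <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(sites),
    ranges = IRanges::IRanges(start = S4Vectors::mcols(sites)$rep_pos,
                              width = 1L),
    strand = GenomicRanges::strand(sites))
  hits <- GenomicRanges::findOverlaps(pts, genes_gr, ignore.strand = FALSE)
  if (length(hits) == 0L) {
    S4Vectors::mcols(sites)$gene_id <- character(0)
    return(sites[0])
  }
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  d_tes <- abs(S4Vectors::mcols(sites)$rep_pos[q] - gm$tes[s])
  ord <- order(q, d_tes, s)
  q <- q[ord]; s <- s[ord]
  keep <- !duplicated(q)
  assigned <- sites[q[keep]]
  S4Vectors::mcols(assigned)$gene_id <- gm$gene_id[s[keep]]
  assigned
}

#' Per-gene polyA-site usage table
#'
#' Computes usage fractions per sample (count / gene total in that sample)
#' and per condition (replicate counts pooled before normalising), orders
#' each gene's sites proximal to distal in transcript orientation and
#' reports the condition usage change per site (`delta_usage`, knockdown
#' minus control). Gene-samples with zero total count have undefined
#' (`NaN`) per-sample usage.
#'
#' @param assigned_sites a `GRanges` with `gene_id` metadata
#'   ([assign_sites_to_genes()]).
#' @param sample_sheet data.frame with `sample` and `condition`
#'   (`control` / `knockdown`).
#' @return list of class `apa_usage`: `per_condition` (data.table: one row
#'   per gene x site with pooled counts, condition usages, `delta_usage`
#'   and `site_rank` proximal=1), `per_sample` (long data.table of
#'   per-sample usages) and `sample_sheet`.
#' @export
compute_usage <- function(assigned_sites, sample_sheet) {
  cnt <- S4Vectors::mcols(assigned_sites)$counts
  stop_if(is.null(cnt), "sites carry no count matrix")
  cond <- sample_sheet$condition[match(colnames(cnt), sample_sheet$sample)]
  stop_if(!all(cond %in% c("control", "knockdown")),
          "conditions must be 'control' and 'knockdown'")
  dt <- data.table::data.table(
    gene_id = S4Vectors::mcols(assigned_sites)$gene_id,
    site_id = S4Vectors::mcols(assigned_sites)$site_id,
    chrom = as.character(GenomicRanges::seqnames(assigned_sites)),
    strand = as.character(GenomicRanges::strand(assigned_sites)),
    rep_pos = S4Vectors::mcols(assigned_sites)$rep_pos,
    count_control = rowSums(cnt[, cond == "control", drop = FALSE]),
    count_knockdown = rowSums(cnt[, cond == "knockdown", drop = FALSE])
  )
  ## proximal -> distal: ascending genomic position on +, descending on -
  dt[, txpos := ifelse(strand == "+", rep_pos, -rep_pos)]
  data.table::setorderv(dt, c("gene_id", "txpos"))
  dt[, site_rank := seq_len(.N), by = gene_id]
  dt[, usage_control := count_control / sum(count_control), by = gene_id]
  dt[, usage_knockdown := count_knockdown / sum(count_knockdown),
     by = gene_id]
  dt[, delta_usage := usage_knockdown - usage_control]
  dt[, txpos := NULL]

  persamp <- data.table::data.table(
    gene_id = rep(dt$gene_id, each = ncol(cnt)),
    site_id = rep(dt$site_id, each = ncol(cnt)),
    sample = rep(colnames(cnt), nrow(dt)),
    condition = rep(cond, nrow(dt)),
    count = as.vector(t(cnt[match(dt$site_id,
                                  S4Vectors::mcols(assigned_sites)$site_id),
                            , drop = FALSE]))
  )
  persamp[, usage := count / sum(count), by = c("gene_id", "sample")]
  out <- list(per_condition = dt, per_sample = persamp,
              sample_sheet = sample_sheet)
  class(out) <- "apa_usage"
  out
}

#' Exact conditional test for a 2x2 count table (vectorised)
#'
#' Two-sided Fisher exact p-value for tables `[[a, b], [c, d]]`
#' (site vs rest-of-gene counts, control vs knockdown): the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' that are no more probable than the observed one (relative slack 1e-7, as
#' is conventional). Degenerate tables (a zero margin) return p = 1.
#'
#' @param a,b,c,d parallel integer vectors: `a`,`b` are the site and
#'   rest-of-gene counts in control, `c`,`d` the same in knockdown.
#' @return numeric vector of two-sided p-values.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  stop_if(any(c(a, b, c, d) < 0), "counts must be non-negative")
  k <- a + b            # control margin
  m <- a + c            # site margin
  n <- b + d            # rest margin
  p <- numeric(length(a))
  key <- paste(m, n, k)
  for (grp in split(seq_along(a), key)) {
    mi <- m[grp[1]]; ni <- n[grp[1]]; ki <- k[grp[1]]
    lo <- max(0L, ki - ni)
    hi <- min(ki, mi)
    if (lo >= hi) {
      p[grp] <- 1
      next
    }
    probs <- stats::dhyper(lo:hi, mi, ni, ki)
    obs <- probs[a[grp] - lo + 1L]
    p[grp] <- vapply(obs, function(o) sum(probs[probs <= o * (1 + 1e-7)]),
                     numeric(1))
  }
  pmin(p, 1)
}

#' Per-site differential-usage test
#'
#' For every site of every gene with at least two sites, tests the 2x2
#' table (site vs rest-of-gene) x (control vs knockdown) on
#' replicate-pooled counts with [fisher_exact_p()], then applies
#' Benjamini-Hochberg adjustment across all tested sites. Degenerate
#' tables are flagged and get p = 1.
#'
#' @param usage an `apa_usage` from [compute_usage()].
#' @return the `apa_usage` with `p_value`, `adj_p` and `degenerate` columns
#'   added to `per_condition` (NA for sites of single-site genes).
#' @export
test_site_usage <- function(usage) {
  dt <- usage$per_condition
  dt[, n_sites := .N, by = gene_id]
  dt[, gene_control := sum(count_control), by = gene_id]
  dt[, gene_knockdown := sum(count_knockdown), by = gene_id]
  testable <- dt$n_sites >= 2L
  a <- dt$count_control[testable]
  b <- dt$gene_control[testable] - a
  cc <- dt$count_knockdown[testable]
  d <- dt$gene_knockdown[testable] - cc
  dt$p_value <- NA_real_
  dt$degenerate <- NA
  if (any(testable)) {
    dt$p_value[testable] <- fisher_exact_p(a, b, cc, d)
    dt$degenerate[testable] <- (a + b == 0L) | (cc + d == 0L) |
      (a + cc == 0L) | (b + d == 0L)
  }
  dt$adj_p <- NA_real_
  dt$adj_p[testable] <- stats::p.adjust(dt$p_value[testable], method = "BH")
  usage$per_condition <- dt
  usage
}

#' Select the reporting site pair for one gene
#'
#' With exactly two sites, both; otherwise the two sites with the largest
#' absolute condition usage change. Ties break towards the larger pooled
#' count, then the 5'-most (most proximal) position. The pair is returned
#' proximal first.
#'
#' @param gene_dt the `per_condition` rows of one gene.
#' @return the two selected rows, ordered proximal then distal.
#' @export
select_gene_pair <- function(gene_dt) {
  stop_if(nrow(gene_dt) < 2L, "gene has fewer than two sites")
  if (nrow(gene_dt) == 2L) {
    sel <- gene_dt
  } else {
    pooled <- gene_dt$count_control + gene_dt$count_knockdown
    ord <- order(-abs(gene_dt$delta_usage), -pooled, gene_dt$site_rank)
    sel <- gene_dt[ord[1:2], ]
  }
  sel[order(sel$site_rank), ]
}

#' Direction call for a proximal/distal site pair
#'
#' The polyA usage index change (delta PUI) is the distal site's condition
#' usage change (knockdown minus control), so positive values mean a shift
#' to the distal site, i.e. 3'UTR lengthening. A direction is called only
#' when `|delta PUI|` strictly exceeds `pui_threshold` and the adjusted p
#' is below `alpha`.
#'
#' @param delta_pui signed usage change of the distal site.
#' @param adjusted_p BH-adjusted p-value for the pair.
#' @param pui_threshold minimum absolute usage change (default 0.10).
#' @param alpha significance level (default 0.05).
#' @return `"lengthening"`, `"shortening"` or `"none"` (vectorised).
#' @export
call_direction <- function(delta_pui, adjusted_p, pui_threshold = 0.10,
                           alpha = 0.05) {
  out <- rep("none", length(delta_pui))
  sig <- !is.na(adjusted_p) & adjusted_p < alpha &
    abs(delta_pui) > pui_threshold
  out[sig & delta_pui > 0] <- "lengthening"
  out[sig & delta_pui < 0] <- "shortening"
  out
}

#' Gene-level expression fold change from 3'-end totals
#'
#' @param gene_control,gene_knockdown pooled gene counts per condition.
#' @param pseudocount added to both totals before the ratio.
#' @param fc_threshold absolute fold change that sets the flag.
#' @return data.frame with `expression_log2fc` and `expression_flag`
#'   (`TRUE` when the fold change is at least `fc_threshold` in either
#'   direction).
#' @export
associate_expression <- function(gene_control, gene_knockdown,
                                 pseudocount = 1, fc_threshold = 1.5) {
  l2 <- log2((gene_knockdown + pseudocount) / (gene_control + pseudocount))
  data.frame(expression_log2fc = l2,
             expression_flag = abs(l2) >= log2(fc_threshold))
}

#' Gene-level differential APA results
#'
#' Runs the per-site tests, selects each tested gene's reporting pair,
#' computes delta PUI (distal site, knockdown minus control), calls the
#' direction at the given thresholds and attaches the expression fold
#' change.
#'
#' @param usage an `apa_usage` from [compute_usage()].
#' @param pui_threshold,alpha direction-call thresholds
#'   ([call_direction()]).
#' @param pseudocount,fc_threshold expression parameters
#'   ([associate_expression()]).
#' @return data.table of class `apa_results`: one row per tested gene with
#'   the pair's site ids and positions, `delta_pui`, `p_value`, `adj_p`,
#'   `direction`, `expression_log2fc` and `expression_flag`.
#' @export
apa_gene_results <- function(usage, pui_threshold = 0.10, alpha = 0.05,
                             pseudocount = 1, fc_threshold = 1.5) {
  usage <- test_site_usage(usage)
  dt <- usage$per_condition
  genes <- unique(dt$gene_id[dt$n_sites >= 2L &
                               dt$gene_control > 0 & dt$gene_knockdown > 0])
  rows <- lapply(genes, function(g) {
    gd <- dt[dt$gene_id == g, ]
    pair <- select_gene_pair(gd)
    prox <- pair[1, ]
    dist <- pair[2, ]
    data.table::data.table(
      gene_id = g, chrom = prox$chrom, strand = prox$strand,
      proximal_site = prox$site_id, proximal_pos = prox$rep_pos,
      distal_site = dist$site_id, distal_pos = dist$rep_pos,
      delta_pui = dist$delta_usage,
      p_value = dist$p_value, adj_p = dist$adj_p,
      gene_control = prox$gene_control,
      gene_knockdown = prox$gene_knockdown
    )
  })
  res <- data.table::rbindlist(rows)
  if (nrow(res) == 0L) {
    res <- data.table::data.table(
      gene_id = character(0), chrom = character(0), strand = character(0),
      proximal_site = character(0), proximal_pos = integer(0),
      distal_site = character(0), distal_pos = integer(0),
      delta_pui = numeric(0), p_value = numeric(0), adj_p = numeric(0),
      gene_control = numeric(0), gene_knockdown = numeric(0))
  }
  res$direction <- call_direction(res$delta_pui, res$adj_p,
                                  pui_threshold = pui_threshold,
                                  alpha = alpha)
  expr <- associate_expression(res$gene_control, res$gene_knockdown,
                               pseudocount = pseudocount,
                               fc_threshold = fc_threshold)
  res$expression_log2fc <- expr$expression_log2fc
  res$expression_flag <- expr$expression_flag
  class(res) <- c("apa_results", class(res))
  res
}
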