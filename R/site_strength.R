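## PolyA-site strength: a 205-nt transcript-sense window centered on the
## cleavage position is scored on a log-odds scale, by default with a
## transparent sequence heuristic (PAS hexamer quality in the -40..-10
## region, U/GU content of the downstream sequence element, an A-run
## penalty). The scorer is pluggable: any function mapping windows to
## scores, or an externally computed score table, can stand behind the same
## interface. Score distributions between site groups are compared with a
## two-sided Mann-Whitney rank test and ECDF tables.

#' Extract the strength window around each site
#'
#' 102 nt upstream + the cleavage base + 102 nt downstream (205 nt total)
#' in transcript orientation; minus-strand windows are
#' reverse-complemented. Windows truncated by a contig edge are N-padded
#' and flagged.
#'
#' @param sites a sites `GRanges` with `rep_pos` metadata.
#' @param genome a [Biostrings::DNAStringSet].
#' @param flank nt on each side of the cleavage base (window length is
#'   `2 * flank + 1`).
#' @return data.table: `site_id`, `window`, `edge_padded`.
#' @export
extract_window <- function(sites, genome, flank = 102L) {
  chrom <- as.character(GenomicRanges::seqnames(sites))
  strand <- as.character(GenomicRanges::strand(sites))
  rp <- S4Vectors::mcols(sites)$rep_pos
  win <- upstream_window(chrom, rp, strand, genome,
                         from = flank, len = 2L * flank + 1L)
  data.table::data.table(
    site_id = S4Vectors::mcols(sites)$site_id,
    window = win,
    edge_padded = grepl("N", win, fixed = TRUE)
  )
}

## heuristic scorer weights: ordinal by design, not calibrated
.strength_weights <- list(
  hexamer = c(AATAAA = 1, ATTAAA = 0.75, AGTAAA = 0.45, TATAAA = 0.45,
              CATAAA = 0.4, GATAAA = 0.4, AATATA = 0.4, AATACA = 0.4,
              AATAGA = 0.4, AAAAAG = 0.3, ACTAAA = 0.4, AATGAA = 0.4),
  intercept = -3, w_pas = 4, w_dse = 4, w_arun = 0.3
)

#' Heuristic polyA-site strength scorer
#'
#' Scores a 205-nt window as
#' `intercept + w_pas * pas + w_dse * dse - w_arun * max(0, longest A run - 5)`
#' where `pas` is the best PAS hexamer weight found with its start in the
#' -40..-10 region upstream of the center base, `dse` the U plus GU
#' dinucleotide content of the +5..+40 downstream region, and the A-run
#' penalty discourages internal-priming-like contexts. The linear predictor
#' is the log odds of a logistic site probability, so the score is already
#' on a log-odds scale (0 corresponds to p = 0.5); it is monotone in PAS
#' quality and DSE content. All-N windows get the minimum score
#' (the intercept).
#'
#' @param windows character vector of odd-length A/C/G/T/N windows.
#' @return numeric log-odds scores.
#' @export
heuristic_strength_scorer <- function(windows) {
  stop_if(any(grepl("[^ACGTN]", windows)),
          "windows must contain only A, C, G, T or N")
  w <- .strength_weights
  vapply(windows, function(win) {
    L <- nchar(win)
    ctr <- (L + 1L) %/% 2L
    ## PAS region: hexamer start in [center-40, center-10]
    lo <- max(1L, ctr - 40L)
    hi <- min(L, ctr - 10L + 5L)
    pas_region <- substr(win, lo, hi)
    pas <- 0
    for (h in names(w$hexamer)) {
      if (grepl(h, pas_region, fixed = TRUE)) {
        pas <- max(pas, w$hexamer[[h]])
      }
    }
    ## DSE: U + GU content of [center+5, center+40]
    dse_region <- substr(win, min(L, ctr + 5L), min(L, ctr + 40L))
    nlen <- nchar(dse_region)
    dse <- 0
    if (nlen > 0L) {
      n_t <- nlen - nchar(gsub("T", "", dse_region, fixed = TRUE))
      n_gt <- length(gregexpr("GT", dse_region, fixed = TRUE)[[1]])
      if (gregexpr("GT", dse_region, fixed = TRUE)[[1]][1] == -1L) n_gt <- 0L
      dse <- (n_t + n_gt) / nlen
    }
    ## longest A run anywhere in the window
    runs <- rle(strsplit(win, "")[[1]] == "A")
    arun <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    unname(w$intercept + w$w_pas * pas + w$w_dse * min(dse, 1) -
             w$w_arun * max(0L, arun - 5L))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Score polyA sites
#'
#' Extracts each site's strength window and applies a scorer: the built-in
#' heuristic ([heuristic_strength_scorer()]), any function mapping a
#' character vector of windows to numeric scores, or an external score
#' table (data.frame `site_id`, `score`, e.g. imported from a published
#' model's output).
#'
#' @param sites a sites `GRanges`.
#' @param genome a [Biostrings::DNAStringSet].
#' @param scorer a function, or a data.frame of external scores.
#' @param scorer_id label recorded with the scores.
#' @param flank window half-width (default 102, a 205-nt window).
#' @return data.table: `site_id`, `window`, `edge_padded`, `score`,
#'   `scorer_id`.
#' @export
score_sites <- function(sites, genome, scorer = heuristic_strength_scorer,
                        scorer_id = NULL, flank = 102L) {
  win <- extract_window(sites, genome, flank = flank)
  if (is.data.frame(scorer)) {
    stop_if(!all(c("site_id", "score") %in% names(scorer)),
            "external score table needs site_id and score columns")
    win$score <- scorer$score[match(win$site_id, scorer$site_id)]
    stop_if(anyNA(win$score), "external scores missing for some sites")
    win$scorer_id <- scorer_id %||% "external"
  } else {
    win$score <- scorer(win$window)
    stop_if(any(!is.finite(win$score)), "scorer produced non-finite scores")
    win$scorer_id <- scorer_id %||% "heuristic"
  }
  win
}

#' Compare score distributions between two site groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test — exact for small
#' untied samples, normal approximation with tie correction otherwise —
#' plus ECDF tables for plotting.
#'
#' @param scores_a,scores_b numeric score vectors (both non-empty).
#' @param labels length-2 character vector naming the groups.
#' @return list: `statistic` (the Mann-Whitney U for group a), `p_value`,
#'   `medians`, `n`, and `ecdf` (data.frame `group`, `value`, `ecdf`).
#' @export
compare_groups <- function(scores_a, scores_b,
                           labels = c("group_a", "group_b")) {
  stop_if(length(scores_a) == 0L || length(scores_b) == 0L,
          "both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(scores_a, scores_b,
                                            alternative = "two.sided"))
  ecdf_tab <- function(x, g) {
    xs <- sort(unique(x))
    data.frame(group = g, value = xs,
               ecdf = vapply(xs, function(v) mean(x <= v), numeric(1)))
  }
  list(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    medians = c(stats::median(scores_a), stats::median(scores_b)),
    n = c(length(scores_a), length(scores_b)),
    labels = labels,
    ecdf = rbind(ecdf_tab(scores_a, labels[1]), ecdf_tab(scores_b, labels[2]))
  )
}

#' Area under the ROC curve for scores against binary labels
#'
#' Computed from the rank-sum identity `AUC = (R1 - n1 (n1 + 1) / 2) /
#' (n1 n0)` with midranks for ties.
#'
#' @param scores numeric scores.
#' @param positive logical vector, `TRUE` for the positive class.
#' @return AUC in \[0, 1\].
#' @export
auroc <- function(scores, positive) {
  stop_if(length(scores) != length(positive), "length mismatch")
  n1 <- sum(positive)
  n0 <- sum(!positive)
  stop_if(n1 == 0L || n0 == 0L, "both classes must be present")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
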