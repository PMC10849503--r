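## Validation utilities: independent oracle sweeps for the statistical
## primitives and ground-truth benchmarking of a pipeline run against the
## simulator's planted architecture. The oracles deliberately use different
## computational routes than the implementation (explicit character
## arithmetic for the mis-priming rule, binomial-coefficient enumeration
## for the exact test, permutation enumeration for the rank-sum test).

#' Mis-priming rule agreement with a brute-force scan
#'
#' Generates random A-biased sequences and compares [is_misprimed()] at
#' every position on both strands with an independent reference scan that
#' implements the rule directly on character vectors (leading run of >= 6
#' A, or >= 6 A among the first 10 downstream bases, transcript-sense).
#'
#' @param n_sequences number of random sequences.
#' @param seq_length length of each (nt).
#' @param seed RNG seed for the sequences.
#' @return list: `agreement` (fraction of positions where the two routes
#'   agree), `n` (positions tested).
#' @export
misprime_oracle_agreement <- function(n_sequences = 50, seq_length = 2000,
                                      seed = 1) {
  n_total <- 0L
  n_agree <- 0L
  with_seed(seed, {
    for (i in seq_len(n_sequences)) {
      chars <- sample(c("A", "C", "G", "T"), seq_length, replace = TRUE,
                      prob = c(0.35, 0.2, 0.2, 0.25))
      genome <- Biostrings::DNAStringSet(
        stats::setNames(paste(chars, collapse = ""), "chrO"))
      pos <- seq_len(seq_length)
      ## reference: windowed character counts from cumulative sums
      cA <- c(0L, cumsum(chars == "A"))
      cT <- c(0L, cumsum(chars == "T"))
      winsum <- function(cs, lo, hi) {
        lo <- pmax(lo, 1L)
        hi <- pmin(hi, seq_length)
        ifelse(hi >= lo, cs[hi + 1L] - cs[lo], 0L)
      }
      ## plus strand: window is chars pos+1 .. pos+10
      run6_p <- winsum(cA, pos + 1L, pos + 6L) == 6L & pos + 6L <= seq_length
      tenA_p <- winsum(cA, pos + 1L, pos + 10L) >= 6L
      ## minus strand: window is the reverse complement of pos-10 .. pos-1,
      ## so A in the window are T on the forward strand
      run6_m <- winsum(cT, pos - 6L, pos - 1L) == 6L & pos - 6L >= 1L
      tenA_m <- winsum(cT, pos - 10L, pos - 1L) >= 6L
      for (strand in c("+", "-")) {
        got <- is_misprimed(rep("chrO", seq_length), pos, strand, genome)
        want <- if (strand == "+") run6_p | tenA_p else run6_m | tenA_m
        n_total <- n_total + seq_length
        n_agree <- n_agree + sum(got == want)
      }
    }
  })
  list(agreement = n_agree / n_total, n = n_total)
}

#' Exact-test oracle sweep over all small 2x2 tables
#'
#' Enumerates every 2x2 table whose four margins are all at most
#' `max_margin` and compares [fisher_exact_p()] with an independent
#' hypergeometric enumeration built from binomial coefficients.
#'
#' @param max_margin largest allowed margin.
#' @return list: `max_abs_diff` (largest absolute p-value difference) and
#'   `n_tables`.
#' @export
exact_test_oracle_sweep <- function(max_margin = 30L) {
  worst <- 0
  n_tables <- 0L
  for (m in 0:max_margin) {         # column margin a + c
    for (n in 0:max_margin) {       # column margin b + d
      ks <- max(0L, m + n - max_margin):min(max_margin, m + n)
      for (k in ks) {               # row margin a + b
        lo <- max(0L, k - n)
        hi <- min(k, m)
        xs <- lo:hi
        got <- fisher_exact_p(xs, k - xs, m - xs, n - k + xs)
        ## oracle: explicit table probabilities from lchoose
        logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
        probs <- exp(logp)
        want <- vapply(probs, function(o) {
          min(1, sum(probs[probs <= o * (1 + 1e-7)]))
        }, numeric(1))
        worst <- max(worst, max(abs(got - want)))
        n_tables <- n_tables + length(xs)
      }
    }
  }
  list(max_abs_diff = worst, n_tables = n_tables)
}

#' Rank-sum oracle sweep over all small group sizes
#'
#' For every pair of group sizes up to `max_n`, draws tie-free values and
#' compares the [compare_groups()] p-value with exhaustive enumeration of
#' all assignments of the pooled observations to the first group.
#'
#' @param max_n largest group size per side.
#' @param seed RNG seed for the group values.
#' @return list: `max_abs_diff`, `n_cases`.
#' @export
ranksum_oracle_sweep <- function(max_n = 6L, seed = 1) {
  worst <- 0
  n_cases <- 0L
  with_seed(seed, {
    for (n1 in 1:max_n) {
      for (n2 in 1:max_n) {
        a <- runif(n1)
        b <- runif(n2) + 0.1
        got <- compare_groups(a, b)$p_value
        pooled <- c(a, b)
        r <- rank(pooled)
        mu <- n1 * n2 / 2
        u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
        combs <- utils::combn(n1 + n2, n1)
        us <- apply(combs, 2, function(ix) {
          sum(r[ix]) - n1 * (n1 + 1) / 2
        })
        want <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
        worst <- max(worst, abs(got - want))
        n_cases <- n_cases + 1L
      }
    }
  })
  list(max_abs_diff = worst, n_cases = n_cases)
}

## match called sites to true sites by position proximity (same contig and
## strand, |rep_pos - true pos| <= tol); returns the truth row index per
## called site (NA when unmatched)
match_sites_to_truth <- function(sites, truth, tol = 5L) {
  ch <- as.character(GenomicRanges::seqnames(sites))
  st <- as.character(GenomicRanges::strand(sites))
  rp <- S4Vectors::mcols(sites)$rep_pos
  vapply(seq_along(sites), function(i) {
    j <- which(truth$chrom == ch[i] & truth$strand == st[i] &
                 abs(truth$pos - rp[i]) <= tol)
    if (length(j) == 0L) NA_integer_ else
      j[which.min(abs(truth$pos[j] - rp[i]))]
  }, integer(1))
}

#' Benchmark a pipeline run against the simulator's ground truth
#'
#' Measures, from an [run_apa_pipeline()] result on simulated data: true
#' polyA-site recovery within `tol` nt; internal-priming filter performance
#' (artifact reads removed, true-site reads lost); delta PUI accuracy and
#' direction calls on genes with planted lengthening/shortening shifts;
#' false direction calls on null genes; cryptic-site sensitivity and false
#' cryptic calls on null genes; the strength scorer's AUROC against the
#' planted strong/weak labels; and the distal-vs-proximal strength
#' comparison p-value.
#'
#' @param run an `apa_run` from [run_apa_pipeline()].
#' @param tol position tolerance (nt) for matching called to true sites.
#' @return named list of metrics (fractions unless stated otherwise).
#' @export
benchmark_apa_run <- function(run, tol = 5L) {
  sim <- run$sim
  truth <- sim$sites
  gm <- sim$gene_models

  ## site recovery
  sites <- run$called$sites
  ch <- as.character(GenomicRanges::seqnames(sites))
  st <- as.character(GenomicRanges::strand(sites))
  rp <- S4Vectors::mcols(sites)$rep_pos
  recovered <- vapply(seq_len(nrow(truth)), function(i) {
    any(ch == truth$chrom[i] & st == truth$strand[i] &
          abs(rp - truth$pos[i]) <= tol)
  }, logical(1))

  ## mis-priming filter performance on the raw read ends
  ends <- extract_read_ends(sim$reads, sim$orientation)
  mis <- is_misprimed(ends$chrom, ends$pos, ends$strand, sim$genome)
  is_art <- sim$read_truth$origin[match(ends$read_id,
                                        sim$read_truth$read_id)] ==
    "artifact"

  ## delta PUI and direction on planted shifts
  res <- run$results
  cls <- gm$class[match(res$gene_id, gm$gene_id)]
  aff <- which(cls %in% c("lengthening", "shortening"))
  true_dpui <- ifelse(cls[aff] == "lengthening",
                      sim$config$lengthening_shift,
                      -sim$config$lengthening_shift)
  nul <- which(cls == "null")

  ## cryptic sensitivity / specificity
  planted <- truth[truth$is_cryptic, , drop = FALSE]
  cry <- run$cryptic
  cry_hit <- vapply(seq_len(nrow(planted)), function(i) {
    any(cry$gene_id == planted$gene_id[i] &
          abs(cry$rep_pos - planted$pos[i]) <= tol)
  }, logical(1))
  null_site_ids <- run$usage$per_condition$site_id[
    run$usage$per_condition$gene_id %in% gm$gene_id[gm$class == "null"]]
  cry_null_rate <- if (length(null_site_ids)) {
    sum(cry$site_id %in% null_site_ids) / length(null_site_ids)
  } else {
    0
  }

  ## strength scorer vs planted labels
  sc <- run$strength$scores
  lab_idx <- match_sites_to_truth(
    sites[match(sc$site_id, S4Vectors::mcols(sites)$site_id)], truth, tol)
  ok <- !is.na(lab_idx)
  auc <- if (any(ok) &&
               length(unique(truth$strength_label[lab_idx[ok]])) == 2L) {
    auroc(sc$score[ok], truth$strength_label[lab_idx[ok]] == "strong")
  } else {
    NA_real_
  }

  list(
    site_recovery = mean(recovered),
    n_true_sites = nrow(truth),
    artifact_removal = if (any(is_art)) mean(mis[is_art]) else NA_real_,
    true_read_loss = mean(mis[!is_art]),
    dpui_within_tol = mean(abs(res$delta_pui[aff] - true_dpui) <= 0.05),
    dpui_mean_abs_error = mean(abs(res$delta_pui[aff] - true_dpui)),
    direction_correct = mean(res$direction[aff] == cls[aff]),
    n_affected_genes = length(aff),
    null_false_direction = if (length(nul)) {
      mean(res$direction[nul] != "none")
    } else {
      NA_real_
    },
    n_null_genes = length(nul),
    cryptic_sensitivity = if (nrow(planted)) mean(cry_hit) else NA_real_,
    n_cryptic_planted = nrow(planted),
    cryptic_null_rate = cry_null_rate,
    strength_auroc = auc,
    distal_vs_proximal_p = run$strength$comparison$p_value
  )
}

## mirror gene models onto the reverse-complemented genome
mirror_gene_models <- function(gm, contig_lengths) {
  L <- contig_lengths[gm$chrom]
  out <- gm
  out$strand <- ifelse(gm$strand == "+", "-", "+")
  out$start <- mirror_position(gm$end, L)
  out$end <- mirror_position(gm$start, L)
  out$cds_start <- mirror_position(gm$cds_end, L)
  out$cds_end <- mirror_position(gm$cds_start, L)
  out$tes <- mirror_position(gm$tes, L)
  out$stop_pos <- mirror_position(gm$stop_pos, L)
  out
}

#' Strand-symmetry check across the pipeline stages
#'
#' Reverse-complements the simulated genome, mirrors all read records and
#' gene models, reruns site calling, usage, differential APA, cryptic
#' classification and strength scoring, and verifies the outputs are the
#' mirror image of the originals: mirrored site positions with identical
#' counts and PAS hits, identical per-gene delta PUI, identical cryptic
#' categories, identical strength scores.
#'
#' @param sim an `apa_simulation`.
#' @param config an [apa_run_config()] whose `simulation` produced `sim`.
#' @return list of logicals, one per compared aspect, plus `all_identical`.
#' @export
strand_symmetry_check <- function(sim, config = apa_run_config()) {
  lens <- stats::setNames(Biostrings::width(sim$genome), names(sim$genome))
  fwd <- call_polya_sites(
    sim$reads, sim$genome, sim$sample_sheet,
    orientation = config$orientation, max_gap = config$max_gap,
    min_reads = config$min_reads,
    min_replication = config$min_replication,
    detection_min_reads = config$detection_min_reads,
    replication_scope = config$replication_scope)
  mgenome <- mirror_genome(sim$genome)
  mreads <- mirror_reads(sim$reads, lens)
  rev_ <- call_polya_sites(
    mreads, mgenome, sim$sample_sheet,
    orientation = config$orientation, max_gap = config$max_gap,
    min_reads = config$min_reads,
    min_replication = config$min_replication,
    detection_min_reads = config$detection_min_reads,
    replication_scope = config$replication_scope)

  key <- function(sites, mirror = FALSE) {
    rp <- S4Vectors::mcols(sites)$rep_pos
    ch <- as.character(GenomicRanges::seqnames(sites))
    st <- as.character(GenomicRanges::strand(sites))
    if (mirror) {
      rp <- mirror_position(rp, lens[ch])
      st <- ifelse(st == "+", "-", "+")
    }
    paste(ch, rp, st)
  }
  kf <- key(fwd$sites)
  kr <- key(rev_$sites, mirror = TRUE)
  sites_ok <- setequal(kf, kr) && length(kf) == length(kr)
  m <- match(kf, kr)
  counts_ok <- sites_ok && !anyNA(m) &&
    identical(unname(S4Vectors::mcols(fwd$sites)$counts),
              unname(S4Vectors::mcols(rev_$sites)$counts[m, , drop = FALSE]))
  pas_ok <- sites_ok &&
    identical(S4Vectors::mcols(fwd$sites)$pas_hexamer,
              S4Vectors::mcols(rev_$sites)$pas_hexamer[m])

  mgm <- mirror_gene_models(sim$gene_models, lens)
  fa <- assign_sites_to_genes(fwd$sites, sim$gene_models,
                              config$downstream_extension)
  ra <- assign_sites_to_genes(rev_$sites, mgm, config$downstream_extension)
  fu <- compute_usage(fa, sim$sample_sheet)
  ru <- compute_usage(ra, sim$sample_sheet)
  fres <- apa_gene_results(fu, config$pui_threshold, config$alpha)
  rres <- apa_gene_results(ru, config$pui_threshold, config$alpha)
  mm <- match(fres$gene_id, rres$gene_id)
  dpui_ok <- !anyNA(mm) &&
    isTRUE(all.equal(fres$delta_pui, rres$delta_pui[mm])) &&
    identical(fres$direction, rres$direction[mm])

  fcry <- cryptic_events(fu, sim$gene_models)
  rcry <- cryptic_events(ru, mgm)
  ko <- order(fcry$gene_id, fcry$usage_knockdown)
  ko2 <- order(rcry$gene_id, rcry$usage_knockdown)
  cryptic_ok <- identical(fcry$category[ko], rcry$category[ko2]) &&
    identical(fcry$gene_id[ko], rcry$gene_id[ko2])

  fsc <- score_sites(fwd$sites, sim$genome)
  rsc <- score_sites(rev_$sites, mgenome)
  scores_ok <- sites_ok && isTRUE(all.equal(fsc$score, rsc$score[m]))

  out <- list(sites = sites_ok, counts = counts_ok, pas = pas_ok,
              delta_pui = dpui_ok, cryptic = cryptic_ok,
              scores = scores_ok)
  out$all_identical <- all(unlist(out))
  out
}
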