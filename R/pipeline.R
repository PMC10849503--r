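## End-to-end orchestration: simulate -> call sites -> differential APA ->
## cryptic classification -> site strength, with one resolved configuration,
## per-stage attrition logging and byte-deterministic TSV outputs.

#' Pipeline run configuration
#'
#' All module parameters in one place, defaulting to the pipeline's
#' standard thresholds: replication rate 0.75, |delta PUI| > 0.10 with
#' adjusted p < 0.05, cryptic rule 0.05 / 0.10 / 0.10, 205-nt strength
#' window. Unknown parameter names are rejected.
#'
#' @param simulation a [simulation_config()] (the input generator).
#' @param ... overrides for any run parameter: `orientation`, `max_gap`,
#'   `min_reads`, `min_replication`, `detection_min_reads`,
#'   `replication_scope`, `pas_window`, `novel_tolerance`,
#'   `downstream_extension`, `pui_threshold`, `alpha`,
#'   `cryptic_control_max`, `cryptic_knockdown_min`,
#'   `cryptic_increase_min`, `strength_flank`, `expression_pseudocount`,
#'   `expression_fc_threshold`.
#' @return list of class `apa_run_config`.
#' @export
apa_run_config <- function(simulation = simulation_config(), ...) {
  cfg <- list(
    simulation = simulation,
    orientation = "sense",
    max_gap = 25L,
    min_reads = 3L,
    min_replication = 0.75,
    detection_min_reads = 1L,
    replication_scope = "per_condition",
    pas_window = c(10L, 40L),
    novel_tolerance = 10L,
    downstream_extension = 5000L,
    pui_threshold = 0.10,
    alpha = 0.05,
    cryptic_control_max = 0.05,
    cryptic_knockdown_min = 0.10,
    cryptic_increase_min = 0.10,
    strength_flank = 102L,
    expression_pseudocount = 1,
    expression_fc_threshold = 1.5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  stop_if(length(unknown) > 0L,
          "unknown run-config parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "apa_run_config"
  cfg
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
}

#' Run the full pipeline on a simulated experiment
#'
#' Simulates a 3'-end-seq experiment, calls polyA sites (mis-priming and
#' replication filters, PAS detection, novelty against the simulator's own
#' true sites), computes usage and differential APA, classifies cryptic
#' events, and scores site strength with the distal-vs-proximal group
#' comparison. When `outdir` is given, every stage's table is written as
#' TSV together with the resolved configuration and a summary; re-running
#' with the same configuration reproduces identical files.
#'
#' @param config an [apa_run_config()].
#' @param outdir optional output directory.
#' @return list of class `apa_run`: `sim`, `called` (site-calling result),
#'   `usage`, `results` (gene-level APA), `cryptic`, `strength` (scores and
#'   the distal-vs-proximal comparison), `summary` (named counts) and
#'   `config`.
#' @export
run_apa_pipeline <- function(config = apa_run_config(), outdir = NULL) {
  stopifnot(inherits(config, "apa_run_config"))

  sim <- simulate_apa_experiment(config$simulation)

  known <- GenomicRanges::GRanges(
    seqnames = sim$sites$chrom,
    ranges = IRanges::IRanges(start = sim$sites$pos, width = 1L),
    strand = sim$sites$strand, name = sim$sites$site_id)

  called <- call_polya_sites(
    sim$reads, sim$genome, sim$sample_sheet,
    orientation = config$orientation,
    max_gap = config$max_gap, min_reads = config$min_reads,
    min_replication = config$min_replication,
    detection_min_reads = config$detection_min_reads,
    replication_scope = config$replication_scope,
    pas_window = config$pas_window,
    known_sites = known, novel_tolerance = config$novel_tolerance)

  assigned <- assign_sites_to_genes(
    called$sites, sim$gene_models,
    downstream_extension = config$downstream_extension)
  usage <- compute_usage(assigned, sim$sample_sheet)
  results <- apa_gene_results(
    usage, pui_threshold = config$pui_threshold, alpha = config$alpha,
    pseudocount = config$expression_pseudocount,
    fc_threshold = config$expression_fc_threshold)
  cryptic <- cryptic_events(
    usage, sim$gene_models,
    control_max = config$cryptic_control_max,
    knockdown_min = config$cryptic_knockdown_min,
    increase_min = config$cryptic_increase_min)
  cryptic <- couple_with_splicing(cryptic, junctions = NULL)

  scores <- score_sites(assigned, sim$genome, flank = config$strength_flank)
  ## proximal-most vs distal-most site of every multi-site gene
  uc <- data.table::as.data.table(usage$per_condition)
  multi <- uc[, list(n = .N), by = gene_id]
  ucm <- uc[uc$gene_id %in% multi$gene_id[multi$n >= 2L], ]
  prox_ids <- ucm[, list(site_id = site_id[which.min(site_rank)]),
                  by = gene_id]$site_id
  dist_ids <- ucm[, list(site_id = site_id[which.max(site_rank)]),
                  by = gene_id]$site_id
  strength_cmp <- if (length(prox_ids) && length(dist_ids)) {
    compare_groups(scores$score[match(dist_ids, scores$site_id)],
                   scores$score[match(prox_ids, scores$site_id)],
                   labels = c("distal", "proximal"))
  } else {
    NULL
  }

  summary <- list(
    n_reads = called$stats$n_reads,
    n_misprimed_removed = called$stats$n_misprimed_removed,
    n_sites_clustered = called$stats$n_sites_clustered,
    n_sites_called = called$stats$n_sites_replicated,
    n_sites_assigned = length(assigned),
    n_genes_tested = nrow(results),
    n_lengthening = sum(results$direction == "lengthening"),
    n_shortening = sum(results$direction == "shortening"),
    n_cryptic_events = nrow(cryptic),
    strength_distal_vs_proximal_p =
      if (is.null(strength_cmp)) NA_real_ else strength_cmp$p_value
  )

  run <- list(sim = sim, called = called, usage = usage, results = results,
              cryptic = cryptic, strength = list(scores = scores,
                                                 comparison = strength_cmp),
              summary = summary, config = config)
  class(run) <- "apa_run"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_simulation(sim, file.path(outdir, "sim"))
    write_sites(called$sites, file.path(outdir, "sites"))
    write_tsv(usage$per_condition, file.path(outdir, "usage.tsv"))
    write_tsv(usage$per_sample, file.path(outdir, "usage_per_sample.tsv"))
    write_tsv(results, file.path(outdir, "apa_results.tsv"))
    write_tsv(cryptic, file.path(outdir, "cryptic_events.tsv"))
    write_tsv(scores[, c("site_id", "score", "scorer_id", "edge_padded")],
              file.path(outdir, "strength_scores.tsv"))
    if (!is.null(strength_cmp)) {
      write_tsv(data.table::as.data.table(strength_cmp$ecdf),
                file.path(outdir, "strength_ecdf.tsv"))
    }
    smry <- data.table::data.table(metric = names(summary),
                                   value = unlist(lapply(summary, format)))
    write_tsv(smry, file.path(outdir, "summary.tsv"))
    resolved <- c(unclass(config$simulation),
                  config[setdiff(names(config), "simulation")])
    write_config_file(resolved, file.path(outdir, "config_resolved.txt"))
  }
  run
}

#' @export
print.apa_run <- function(x, ...) {
  cat("apa3seq pipeline run\n")
  for (k in names(x$summary)) {
    cat(sprintf("  %-32s %s\n", k, format(x$summary[[k]])))
  }
  invisible(x)
}
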