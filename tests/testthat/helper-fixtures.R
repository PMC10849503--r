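## Shared fixtures, built in code. The small simulation is memoised per
## session so several test files can reuse it.

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_apa_experiment(simulation_config(
        n_genes = 24, reads_per_gene = 400, misprime_rate = 0.1,
        cleavage_jitter_sd = 2, seed = 7))
    }
    cache
  }
})

## the bundled smoke-test fixture: a small, fast end-to-end configuration
fixture_config <- function(seed = 17) {
  apa_run_config(simulation = simulation_config(
    n_genes = 16, reads_per_gene = 250, misprime_rate = 0.1, seed = seed))
}

## hand-built sites GRanges with a count matrix, for unit tests of the
## downstream stages
make_sites <- function(chrom, pos, strand, counts, site_id = NULL) {
  counts <- as.matrix(counts)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos, width = 1L),
    strand = strand,
    site_id = site_id %||% sprintf("s%02d", seq_along(pos)),
    rep_pos = pos,
    n_reads = rowSums(counts))
  S4Vectors::mcols(gr)$counts <- counts
  gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## standard 3+3 sample sheet
sheet33 <- data.frame(
  sample = c("ctrl_1", "ctrl_2", "ctrl_3", "kd_1", "kd_2", "kd_3"),
  condition = rep(c("control", "knockdown"), each = 3),
  replicate = rep(1:3, 2))

## one-gene gene-model row for region classification tests
one_gene_model <- function(strand = "+", start = 1000L, tes = 5000L,
                           stop_pos = 3000L, gene_id = "g1",
                           chrom = "chr1") {
  if (strand == "+") {
    data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
               start = start, end = tes, cds_start = start + 50L,
               cds_end = stop_pos, tes = tes, stop_pos = stop_pos)
  } else {
    data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
               start = tes, end = start, cds_start = stop_pos,
               cds_end = start - 50L, tes = tes, stop_pos = stop_pos)
  }
}

contig_lengths_of <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}
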