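#' Simulation configuration
#'
#' Parameters of the synthetic 3'-end-seq experiment: a small multi-contig
#' genome carrying genes with 2-4 polyA sites in their 3'UTRs, a knockdown
#' condition that shifts site usage (3'UTR lengthening, shortening, cryptic
#' activation, or no change), replicate structure, cleavage-position jitter
#' and internal-priming artifacts at planted A-rich stretches.
#'
#' @param n_genes number of genes to simulate.
#' @param genome_length_per_gene length (nt) of the genomic slot allotted to
#'   each gene, including intergenic flanks.
#' @param sites_per_gene_range integer pair: min and max number of 3'UTR
#'   polyA sites per gene.
#' @param fraction_lengthening,fraction_shortening,fraction_cryptic,fraction_null
#'   proportions of genes in each usage class; must sum to 1.
#' @param reads_per_gene mean sequencing depth per gene per replicate.
#' @param n_replicates_per_condition replicates per condition (control and
#'   knockdown).
#' @param misprime_rate fraction of reads redirected to internal-priming
#'   artifacts at planted A-rich stretches.
#' @param cleavage_jitter_sd standard deviation (nt) of the discretised
#'   Gaussian jitter applied to each read's cleavage position.
#' @param lengthening_shift usage mass (fraction) moved from the proximal to
#'   the distal site in lengthening genes (reversed in shortening genes).
#' @param cryptic_usage numeric pair: true usage of a planted cryptic site
#'   under control and knockdown.
#' @param read_length length (nt) of simulated aligned read records.
#' @param seed integer seed; fully determines the simulation output.
#' @return a validated list of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(n_genes = 10, seed = 1)
#' @export
simulation_config <- function(n_genes = 50,
                              genome_length_per_gene = 6000L,
                              sites_per_gene_range = c(2L, 4L),
                              fraction_lengthening = 0.3,
                              fraction_shortening = 0.2,
                              fraction_cryptic = 0.2,
                              fraction_null = 0.3,
                              reads_per_gene = 500L,
                              n_replicates_per_condition = 3L,
                              misprime_rate = 0.1,
                              cleavage_jitter_sd = 2,
                              lengthening_shift = 0.30,
                              cryptic_usage = c(0.02, 0.25),
                              read_length = 50L,
                              seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    genome_length_per_gene = as.integer(genome_length_per_gene),
    sites_per_gene_range = as.integer(sites_per_gene_range),
    fraction_lengthening = fraction_lengthening,
    fraction_shortening = fraction_shortening,
    fraction_cryptic = fraction_cryptic,
    fraction_null = fraction_null,
    reads_per_gene = as.integer(reads_per_gene),
    n_replicates_per_condition = as.integer(n_replicates_per_condition),
    misprime_rate = misprime_rate,
    cleavage_jitter_sd = cleavage_jitter_sd,
    lengthening_shift = lengthening_shift,
    cryptic_usage = cryptic_usage,
    read_length = as.integer(read_length),
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  fr <- cfg$fraction_lengthening + cfg$fraction_shortening +
    cfg$fraction_cryptic + cfg$fraction_null
  stop_if(abs(fr - 1) > 1e-9, "usage-class fractions must sum to 1 (got ",
          format(fr, digits = 12), ")")
  stop_if(any(c(cfg$fraction_lengthening, cfg$fraction_shortening,
                cfg$fraction_cryptic, cfg$fraction_null) < 0),
          "usage-class fractions must be non-negative")
  stop_if(cfg$n_genes < 1L, "n_genes must be positive")
  stop_if(cfg$genome_length_per_gene < 4500L,
          "genome_length_per_gene too small for the fixed gene architecture")
  stop_if(length(cfg$sites_per_gene_range) != 2L ||
            cfg$sites_per_gene_range[1] < 2L ||
            cfg$sites_per_gene_range[2] > 4L ||
            diff(cfg$sites_per_gene_range) < 0,
          "sites_per_gene_range must be an increasing pair within [2, 4]")
  stop_if(cfg$reads_per_gene < 1L, "reads_per_gene must be positive")
  stop_if(cfg$n_replicates_per_condition < 1L,
          "n_replicates_per_condition must be positive")
  stop_if(cfg$misprime_rate < 0 || cfg$misprime_rate >= 1,
          "misprime_rate must be in [0, 1)")
  stop_if(cfg$cleavage_jitter_sd < 0, "cleavage_jitter_sd must be >= 0")
  stop_if(cfg$lengthening_shift <= 0 || cfg$lengthening_shift > 0.4,
          "lengthening_shift must be in (0, 0.4]")
  stop_if(length(cfg$cryptic_usage) != 2L ||
            cfg$cryptic_usage[1] > 0.05 || cfg$cryptic_usage[2] < 0.15 ||
            diff(cfg$cryptic_usage) < 0.10,
          "cryptic_usage must plant a site moving from <=0.05 to >=0.15")
  stop_if(cfg$read_length < 20L, "read_length must be >= 20")
  stop_if(is.na(cfg$seed), "seed must be an integer")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:\n")
  for (k in names(x)) {
    cat(sprintf("  %-28s %s\n", k, paste(x[[k]], collapse = ", ")))
  }
  invisible(x)
}

#' Write / read a simulation or run configuration as key=value text
#'
#' @param cfg a named list (e.g. a `simulation_config`).
#' @param path file path.
#' @return `write_config_file` returns `path` invisibly; `read_config_file`
#'   returns a named list with numeric fields coerced back.
#' @export
write_config_file <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    sprintf("%s=%s", k, paste(cfg[[k]], collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config_file
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- lapply(kv, function(p) {
    vals <- strsplit(p[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    if (!anyNA(num)) num else vals
  })
  names(out) <- vapply(kv, `[[`, "", 1L)
  out
}
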