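## Synthetic 3'-end-seq experiment with known ground truth.
##
## Fixed gene architecture inside a per-gene genomic slot, laid out in
## transcript-sense coordinates (1-based within the slot) and
## reverse-complemented wholesale for minus-strand genes:
##
##   1 .. 300          5' intergenic flank
##   301 .. 600        exon 1 (CDS from 351)
##   601 .. 1600       intron    (cryptic intronic site at 1100,
##                                A-rich artifact stretch at 1350..1357)
##   1601 .. 3500      exon 2 (CDS to 2000; 3'UTR 2001..3500; TES 3500)
##   3900              cryptic downstream site (past the annotated end)
##
## Regular polyA sites sit at evenly spaced 3'UTR positions between 2350 and
## 3450, each with a PAS hexamer planted 21 nt upstream of the cleavage base
## and a controlled, A-free 40-nt downstream block (U/GU-rich for "strong"
## sites, neutral for "weak" ones) so the internal-priming filter can be
## evaluated unambiguously.

GENES_PER_CONTIG <- 25L

## sense-space layout constants
.layout <- list(
  gene_start = 301L, exon1_end = 600L, cds_start = 351L,
  intron_end = 1600L, cds_end = 2000L, tes = 3500L,
  utr_site_lo = 2350L, utr_site_hi = 3450L,
  cryptic_intronic = 1100L, cryptic_downstream = 3900L,
  artifact_start = 1350L, artifact_len = 8L
)

## upstream block planted at pos-30 .. pos-10 (hexamer at pos-21 .. pos-16)
.pas_block <- function(hexamer) paste0("CGTCGCTGC", hexamer, "CTGCGC")
## downstream blocks planted at pos+1 .. pos+40 (no A anywhere)
.dse_strong <- "GTCTTTGTGTTTTGTTGTGTTTGTTTTGTGTTTGTTGTGT"
.dse_weak   <- "GTCTGCCTGCGCTCGCCTGCGCTCGCCTGCGCTCGCCTGC"

sense_to_genomic <- function(pos, strand, slot_offset, slot_len) {
  n <- max(length(pos), length(strand))
  pos <- rep_len(as.integer(pos), n)
  slot_offset <- rep_len(as.integer(slot_offset), n)
  slot_len <- rep_len(as.integer(slot_len), n)
  out <- slot_offset + pos
  minus <- rep_len(strand, n) == "-"
  out[minus] <- slot_offset[minus] + slot_len[minus] - pos[minus] + 1L
  out
}

## replace the middle base of any A-run of length >= 5 until none remain,
## protecting planted intervals (a 2-column matrix of sense start/end)
break_a_runs <- function(seq_chars, protected = NULL) {
  repeat {
    r <- rle(seq_chars == "A")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bad <- which(r$values & r$lengths >= 5L)
    if (length(bad) == 0L) break
    fixed_any <- FALSE
    for (i in bad) {
      mid <- starts[i] + r$lengths[i] %/% 2L
      if (!is.null(protected) &&
          any(mid >= protected[, 1] & mid <= protected[, 2])) next
      seq_chars[mid] <- "G"
      fixed_any <- TRUE
    }
    if (!fixed_any) break
  }
  seq_chars
}

#' Build the synthetic reference: genome, gene models and site skeleton
#'
#' Places genes on alternating strands in non-overlapping slots (25 genes per
#' contig), gives each gene two exons, a CDS and a 3'UTR carrying 2-4 polyA
#' sites with planted PAS hexamers and controlled downstream sequence, adds a
#' cryptic (intronic or downstream-of-TES) site to genes of the cryptic
#' class, and plants one A-rich stretch (8 consecutive A on the sense
#' strand) inside each gene's intron as an internal-priming decoy.
#'
#' @param config a [simulation_config()].
#' @return a list of class `apa_reference` with elements `genome`
#'   ([Biostrings::DNAStringSet]), `gene_models` (data.frame; one row per
#'   gene with genomic CDS/TES/3'UTR coordinates, usage class and artifact
#'   position), `sites` (data.frame; the true-site skeleton with genomic
#'   positions, region kind and planted strength labels) and `config`.
#' @export
build_reference <- function(config) {
  validate_simulation_config(config)
  L <- config$genome_length_per_gene
  n <- config$n_genes
  ly <- .layout

  with_seed(config$seed %% 2147483096L, {
    ## usage classes, shuffled so classes interleave across contigs
    n_len <- round(config$fraction_lengthening * n)
    n_sho <- round(config$fraction_shortening * n)
    n_cry <- round(config$fraction_cryptic * n)
    n_nul <- n - n_len - n_sho - n_cry
    stop_if(n_nul < 0, "class fractions round to more genes than n_genes")
    classes <- sample(rep(c("lengthening", "shortening", "cryptic", "null"),
                          c(n_len, n_sho, n_cry, n_nul)))

    gene_ids <- sprintf("gene%03d", seq_len(n))
    strands <- rep(c("+", "-"), length.out = n)
    contig_idx <- ((seq_len(n) - 1L) %/% GENES_PER_CONTIG) + 1L
    slot_in_contig <- ((seq_len(n) - 1L) %% GENES_PER_CONTIG)
    chrom <- sprintf("chr%d", contig_idx)
    slot_offset <- slot_in_contig * L

    n_sites <- sample(seq(config$sites_per_gene_range[1],
                          config$sites_per_gene_range[2]),
                      n, replace = TRUE)
    cryptic_kind <- ifelse(seq_len(n) %% 2L == 0L, "intronic", "downstream")

    seqs <- character(n)
    site_rows <- vector("list", n)

    for (g in seq_len(n)) {
      chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                      prob = c(0.18, 0.28, 0.27, 0.27))

      ## true 3'UTR site positions, proximal -> distal in sense space
      k <- n_sites[g]
      upos <- as.integer(round(seq(ly$utr_site_lo, ly$utr_site_hi,
                                   length.out = k)))
      kind <- rep("utr", k)
      pos <- upos
      if (classes[g] == "cryptic") {
        cp <- if (cryptic_kind[g] == "intronic") ly$cryptic_intronic else
          ly$cryptic_downstream
        pos <- c(pos, cp)
        kind <- c(kind, paste0("cryptic_", cryptic_kind[g]))
      }
      ord <- order(pos)
      pos <- pos[ord]
      kind <- kind[ord]

      ## planted strength: the distal-most site of every gene is strong
      ## (canonical AATAAA + U/GU-rich DSE), all others weak
      strength <- rep("weak", length(pos))
      strength[which.max(pos)] <- "strong"

      protected <- matrix(integer(0), ncol = 2)
      for (i in seq_along(pos)) {
        p <- pos[i]
        hex <- if (strength[i] == "strong") "AATAAA" else "ATTAAA"
        up <- strsplit(.pas_block(hex), "")[[1]]
        chars[(p - 30L):(p - 10L)] <- up
        dn <- strsplit(if (strength[i] == "strong") .dse_strong else
          .dse_weak, "")[[1]]
        chars[(p + 1L):(p + 40L)] <- dn
        protected <- rbind(protected, c(p - 30L, p + 40L))
      }

      ## internal-priming decoy: 8 consecutive sense-strand As in the intron
      as_ <- ly$artifact_start
      chars[as_:(as_ + ly$artifact_len - 1L)] <- "A"
      chars[as_ - 1L] <- "C"  # anchor the run start precisely
      chars[as_ + ly$artifact_len] <- "C"
      protected <- rbind(protected, c(as_ - 1L, as_ + ly$artifact_len))

      chars <- break_a_runs(chars, protected)
      sense_seq <- paste(chars, collapse = "")
      seqs[g] <- if (strands[g] == "+") sense_seq else revcomp(sense_seq)

      site_rows[[g]] <- data.frame(
        gene_id = gene_ids[g],
        site_id = sprintf("%s_s%d", gene_ids[g], seq_along(pos)),
        chrom = chrom[g], strand = strands[g],
        sense_pos = pos,
        pos = sense_to_genomic(pos, strands[g], slot_offset[g], L),
        kind = kind, strength_label = strength,
        is_cryptic = startsWith(kind, "cryptic"),
        stringsAsFactors = FALSE
      )
    }

    ## assemble contigs
    genome <- Biostrings::DNAStringSet(vapply(
      split(seqs, contig_idx), paste, "", collapse = ""))
    names(genome) <- sprintf("chr%d", sort(unique(contig_idx)))

    g2 <- function(p) sense_to_genomic(rep(p, n), strands, slot_offset, L)
    gm <- data.frame(
      gene_id = gene_ids, chrom = chrom, strand = strands,
      slot_offset = slot_offset, slot_len = L,
      start = pmin(g2(ly$gene_start), g2(ly$tes)),
      end = pmax(g2(ly$gene_start), g2(ly$tes)),
      cds_start = pmin(g2(ly$cds_start), g2(ly$cds_end)),
      cds_end = pmax(g2(ly$cds_start), g2(ly$cds_end)),
      tes = g2(ly$tes),
      stop_pos = g2(ly$cds_end),
      exon1_lo = pmin(g2(ly$gene_start), g2(ly$exon1_end)),
      exon1_hi = pmax(g2(ly$gene_start), g2(ly$exon1_end)),
      exon2_lo = pmin(g2(ly$intron_end + 1L), g2(ly$tes)),
      exon2_hi = pmax(g2(ly$intron_end + 1L), g2(ly$tes)),
      class = classes,
      artifact_cleavage = g2(ly$artifact_start - 1L),
      stringsAsFactors = FALSE
    )

    ref <- list(genome = genome, gene_models = gm,
                sites = do.call(rbind, site_rows), config = config)
    class(ref) <- "apa_reference"
    ref
  })
}

#' Assign per-condition true usage fractions to the site skeleton
#'
#' Lengthening genes move `lengthening_shift` usage mass from the
#' proximal-most to the distal-most 3'UTR site between control and knockdown;
#' shortening genes the reverse; null genes are identical across conditions;
#' cryptic genes move the planted cryptic site from `cryptic_usage[1]` to
#' `cryptic_usage[2]` with the regular sites rescaled proportionally.
#'
#' @param ref an `apa_reference` from [build_reference()].
#' @return the reference with `sites` gaining `usage_control` and
#'   `usage_knockdown` columns (class `apa_truth`).
#' @export
assign_usage <- function(ref) {
  stopifnot(inherits(ref, "apa_reference"))
  cfg <- ref$config
  sites <- ref$sites
  sites$usage_control <- NA_real_
  sites$usage_knockdown <- NA_real_

  with_seed((cfg$seed + 1L) %% 2147483096L, {
    for (g in unique(sites$gene_id)) {
      idx <- which(sites$gene_id == g)
      ## proximal -> distal order in transcript orientation
      ord <- idx[order(sites$sense_pos[idx])]
      cls <- ref$gene_models$class[ref$gene_models$gene_id == g]
      k <- length(ord)
      if (cls == "lengthening" || cls == "shortening") {
        sh <- cfg$lengthening_shift
        if (k == 2L) {
          a <- c(0.5 + sh / 2, 0.5 - sh / 2)
          b <- c(0.5 - sh / 2, 0.5 + sh / 2)
        } else {
          mid <- rep(0.20 / (k - 2L), k - 2L)
          a <- c(0.55, mid, 0.55 - sh)
          b <- c(0.55 - sh, mid, 0.55)
        }
        if (cls == "lengthening") {
          u_ctrl <- a; u_kd <- b
        } else {
          u_ctrl <- b; u_kd <- a
        }
      } else if (cls == "null") {
        w <- 0.25 + runif(k)
        u_ctrl <- u_kd <- w / sum(w)
      } else { # cryptic
        cr <- which(sites$is_cryptic[ord])
        w <- 0.25 + runif(k - 1L)
        base <- w / sum(w)
        u_ctrl <- u_kd <- numeric(k)
        u_ctrl[cr] <- cfg$cryptic_usage[1]
        u_kd[cr] <- cfg$cryptic_usage[2]
        u_ctrl[-cr] <- base * (1 - cfg$cryptic_usage[1])
        u_kd[-cr] <- base * (1 - cfg$cryptic_usage[2])
      }
      sites$usage_control[ord] <- u_ctrl
      sites$usage_knockdown[ord] <- u_kd
    }
  })
  ref$sites <- sites
  class(ref) <- c("apa_truth", "apa_reference")
  ref
}

#' Sample sheet for a simulated experiment
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns `sample`, `condition`, `replicate`.
#' @export
simulation_sample_sheet <- function(config) {
  r <- config$n_replicates_per_condition
  data.frame(
    sample = c(sprintf("ctrl_%d", seq_len(r)), sprintf("kd_%d", seq_len(r))),
    condition = rep(c("control", "knockdown"), each = r),
    replicate = rep(seq_len(r), 2L),
    stringsAsFactors = FALSE
  )
}

#' Simulate aligned 3'-end read records
#'
#' Each read's cleavage position is drawn from one of the gene's true sites
#' (per-condition multinomial over the true usage fractions) with discretised
#' Gaussian jitter; a `misprime_rate` fraction of reads instead terminate
#' immediately upstream of the gene's planted A-rich stretch (internal
#' priming). Replicate depths are Poisson around `reads_per_gene`. Reads are
#' emitted in transcript-sense orientation (`orientation = "sense"`).
#'
#' @param truth an `apa_truth` from [assign_usage()].
#' @return a list of class `apa_simulation`: `reads` (a
#'   [GenomicRanges::GRanges] of read records with `sample` and `read_id`
#'   metadata), `read_truth` (data.frame mapping each read to its originating
#'   site id or `"artifact"`), `sample_sheet`, `orientation`, plus the
#'   reference components.
#' @export
simulate_reads <- function(truth) {
  stopifnot(inherits(truth, "apa_truth"))
  cfg <- truth$config
  stop_if(cfg$reads_per_gene <= 0L, "zero-depth configuration")
  gm <- truth$gene_models
  sheet <- simulation_sample_sheet(cfg)
  L <- cfg$genome_length_per_gene
  rl <- cfg$read_length

  with_seed((cfg$seed + 2L) %% 2147483096L, {
    rows <- vector("list", nrow(gm) * nrow(sheet))
    ri <- 0L
    for (g in seq_len(nrow(gm))) {
      gsites <- truth$sites[truth$sites$gene_id == gm$gene_id[g], ]
      gsites <- gsites[order(gsites$sense_pos), ]
      for (s in seq_len(nrow(sheet))) {
        depth <- rpois(1L, cfg$reads_per_gene)
        if (depth == 0L) next
        n_mis <- rbinom(1L, depth, cfg$misprime_rate)
        n_true <- depth - n_mis
        u <- if (sheet$condition[s] == "control") gsites$usage_control else
          gsites$usage_knockdown
        cnt <- if (n_true > 0L) as.integer(rmultinom(1L, n_true, u)) else
          integer(nrow(gsites))
        sense_pos <- rep(gsites$sense_pos, cnt)
        origin <- rep(gsites$site_id, cnt)
        if (n_true > 0L && cfg$cleavage_jitter_sd > 0) {
          sense_pos <- sense_pos +
            as.integer(round(rnorm(n_true, 0, cfg$cleavage_jitter_sd)))
        }
        if (n_mis > 0L) {
          sense_pos <- c(sense_pos, rep(.layout$artifact_start - 1L, n_mis))
          origin <- c(origin, rep("artifact", n_mis))
        }
        sense_pos <- pmin(pmax(sense_pos, rl + 1L), L - 45L)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          gene_id = gm$gene_id[g], chrom = gm$chrom[g],
          strand = gm$strand[g], slot_offset = gm$slot_offset[g],
          sample = sheet$sample[s], sense_pos = sense_pos, origin = origin,
          stringsAsFactors = FALSE
        )
      }
    }
    rd <- do.call(rbind, rows[seq_len(ri)])
    rd$read_id <- sprintf("%s_%s_r%06d", rd$gene_id, rd$sample,
                          seq_len(nrow(rd)))
    cleav <- sense_to_genomic(rd$sense_pos, rd$strand, rd$slot_offset, L)
    start5 <- sense_to_genomic(rd$sense_pos - rl + 1L, rd$strand,
                               rd$slot_offset, L)
    reads <- GenomicRanges::GRanges(
      seqnames = rd$chrom,
      ranges = IRanges::IRanges(start = pmin(cleav, start5),
                                end = pmax(cleav, start5)),
      strand = rd$strand,
      sample = rd$sample, read_id = rd$read_id
    )
    reads <- GenomeInfoDb_safe_seqlengths(reads, truth$genome)
    sim <- list(
      genome = truth$genome, gene_models = truth$gene_models,
      sites = truth$sites, config = cfg,
      reads = reads,
      read_truth = data.frame(read_id = rd$read_id, sample = rd$sample,
                              gene_id = rd$gene_id, origin = rd$origin,
                              cleavage_pos = cleav,
                              stringsAsFactors = FALSE),
      sample_sheet = sheet, orientation = "sense"
    )
    class(sim) <- c("apa_simulation", "apa_truth", "apa_reference")
    sim
  })
}

## seqlengths are informative only; never fail on them
GenomeInfoDb_safe_seqlengths <- function(gr, genome) {
  tryCatch({
    sl <- stats::setNames(Biostrings::width(genome), names(genome))
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
    gr
  }, error = function(e) gr)
}

#' Simulate a complete synthetic 3'-end-seq experiment
#'
#' Convenience wrapper: [build_reference()] then [assign_usage()] then
#' [simulate_reads()].
#'
#' @param config a [simulation_config()].
#' @return an `apa_simulation`; see [simulate_reads()].
#' @examples
#' sim <- simulate_apa_experiment(simulation_config(n_genes = 6, seed = 1))
#' length(sim$reads)
#' @export
simulate_apa_experiment <- function(config) {
  simulate_reads(assign_usage(build_reference(config)))
}
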