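## Readers and writers for the plain-text interchange formats the pipeline
## speaks: FASTA (genome), GTF (annotation, 1-based inclusive), BED6 (read
## records and known sites, 0-based half-open) and TSV result tables.
## BED6 round-trips are byte-deterministic by construction.

#' Write / read aligned read records as BED6
#'
#' BED columns are `chrom, start (0-based), end (half-open), name, score,
#' strand`; the read name carries the read id and the score column the
#' constant 0. The transcript-sense cleavage position of a read is its
#' 3'-most aligned base (interval end on `+`, start on `-` for a
#' sense-oriented protocol).
#'
#' @param reads a [GenomicRanges::GRanges] with `read_id` metadata.
#' @param path output file.
#' @return `write_reads_bed` returns `path` invisibly; `read_reads_bed`
#'   returns a `GRanges` with `read_id` (and `sample`, if given) metadata.
#' @export
write_reads_bed <- function(reads, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(reads)),
    start = GenomicRanges::start(reads) - 1L,
    end = GenomicRanges::end(reads),
    name = S4Vectors::mcols(reads)$read_id %||%
      sprintf("read%07d", seq_along(reads)),
    score = 0L,
    strand = as.character(GenomicRanges::strand(reads))
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reads_bed
#' @param sample optional sample id attached to every read.
#' @export
read_reads_bed <- function(path, sample = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"))
  stop_if(nrow(dt) == 0L, "empty BED file: ", path)
  stop_if(!all(dt$strand %in% c("+", "-")),
          "malformed BED (bad strand) in ", path)
  gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = dt$strand, read_id = dt$name
  )
  if (!is.null(sample)) S4Vectors::mcols(gr)$sample <- sample
  gr
}

#' Read aligned read records from a BAM file
#'
#' Consumes primary, non-duplicate alignments (optionally restricted to
#' proper pairs / a given mate) via Rsamtools and returns the same `GRanges`
#' shape as [read_reads_bed()].
#'
#' @param path BAM file path.
#' @param sample optional sample id attached to every read.
#' @return a [GenomicRanges::GRanges] of read records.
#' @export
read_reads_bam <- function(path, sample = NULL) {
  stop_if(!requireNamespace("Rsamtools", quietly = TRUE),
          "Rsamtools is required to read BAM input")
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE,
                                 isDuplicate = FALSE,
                                 isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    flag = flag, what = c("qname", "rname", "pos", "strand", "qwidth", "cigar"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos)
  w <- GenomicAlignments_width(b$cigar[keep], b$qwidth[keep])
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(b$rname[keep]),
    ranges = IRanges::IRanges(start = b$pos[keep], width = w),
    strand = as.character(b$strand[keep]),
    read_id = b$qname[keep]
  )
  if (!is.null(sample)) S4Vectors::mcols(gr)$sample <- sample
  gr
}

## reference-space width from CIGAR (M/D/N/=/X consume reference); falls
## back to query width for absent CIGARs
GenomicAlignments_width <- function(cigar, qwidth) {
  vapply(seq_along(cigar), function(i) {
    cg <- cigar[i]
    if (is.na(cg)) return(as.integer(qwidth[i]))
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

#' Write the synthetic annotation as GTF
#'
#' Emits `gene`, `transcript`, `exon` and `CDS` records (1-based inclusive
#' coordinates) for the two-exon gene models of an [build_reference()]
#' reference.
#'
#' @param ref an `apa_reference`.
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ref, path) {
  gm <- ref$gene_models
  lines <- character(0)
  for (g in seq_len(nrow(gm))) {
    r <- gm[g, ]
    attr_g <- sprintf('gene_id "%s";', r$gene_id)
    attr_t <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                      r$gene_id, r$gene_id)
    feat <- function(type, lo, hi, attrs) {
      sprintf("%s\tapa3seq_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
              r$chrom, type, lo, hi, r$strand, attrs)
    }
    ex <- rbind(c(r$exon1_lo, r$exon1_hi), c(r$exon2_lo, r$exon2_hi))
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    cds1 <- c(max(r$cds_start, r$exon1_lo), min(r$cds_end, r$exon1_hi))
    cds2 <- c(max(r$cds_start, r$exon2_lo), min(r$cds_end, r$exon2_hi))
    cds <- rbind(cds1, cds2)
    cds <- cds[cds[, 1] <= cds[, 2], , drop = FALSE]
    cds <- cds[order(cds[, 1]), , drop = FALSE]
    lines <- c(lines,
               feat("gene", r$start, r$end, attr_g),
               feat("transcript", r$start, r$end, attr_t),
               feat("exon", ex[1, 1], ex[1, 2], attr_t),
               feat("exon", ex[2, 1], ex[2, 2], attr_t),
               apply(cds, 1, function(x) feat("CDS", x[1], x[2], attr_t)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Builds the flat gene-model table the downstream stages use: per gene the
#' span, genomic CDS extent, annotated transcription end (TES, strand-aware
#' 3' end of the gene span) and the genomic position of the stop codon's 3'
#' boundary. Genes lacking CDS records get `NA` there and are classified
#' against the annotated end only.
#'
#' @param path GTF file (1-based inclusive, `gene_id` attributes required).
#' @return data.frame with one row per gene.
#' @export
read_gene_models <- function(path) {
  stop_if(!requireNamespace("rtracklayer", quietly = TRUE),
          "rtracklayer is required to read GTF input")
  gr <- rtracklayer::import(path, format = "gtf")
  stop_if(is.null(gr$gene_id) || anyNA(gr$gene_id),
          "GTF records missing gene_id")
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gr$gene_id
  )
  span <- dt[dt$type %in% c("gene", "transcript", "exon"), ]
  gm <- span[, list(chrom = chrom[1], strand = strand[1],
                    start = min(start), end = max(end)), by = "gene_id"]
  cds <- dt[dt$type == "CDS",
            list(cds_start = min(start), cds_end = max(end)), by = "gene_id"]
  gm <- merge(gm, cds, by = "gene_id", all.x = TRUE, sort = FALSE)
  gm$tes <- ifelse(gm$strand == "+", gm$end, gm$start)
  gm$stop_pos <- ifelse(gm$strand == "+", gm$cds_end, gm$cds_start)
  data.table::setDF(gm)
  gm[order(gm$gene_id), , drop = FALSE]
}

#' Read a BED6 file of known polyA sites (or other stranded intervals)
#'
#' @param path BED6 file.
#' @return a [GenomicRanges::GRanges] (1-based internally).
#' @export
read_bed6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges())
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 6L)
  stop_if(length(bad) > 0L,
          "malformed BED (fewer than 6 columns) at line ", bad[1])
  st <- vapply(f, `[[`, "", 6L)
  bad <- which(!st %in% c("+", "-"))
  stop_if(length(bad) > 0L, "malformed BED (bad strand) at line ", bad[1])
  GenomicRanges::GRanges(
    seqnames = vapply(f, `[[`, "", 1L),
    ranges = IRanges::IRanges(
      start = as.integer(vapply(f, `[[`, "", 2L)) + 1L,
      end = as.integer(vapply(f, `[[`, "", 3L))),
    strand = st,
    name = vapply(f, `[[`, "", 4L)
  )
}

#' Write called polyA sites as BED6+ and a TSV mirror
#'
#' The BED interval is the cluster span (0-based half-open); extra columns
#' carry the representative position, per-sample counts, PAS hit,
#' replication rate and novelty flag.
#'
#' @param sites a sites `GRanges` from [call_polya_sites()] /
#'   [cluster_ends()].
#' @param prefix output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.tsv`.
#' @return the TSV path, invisibly.
#' @export
write_sites <- function(sites, prefix) {
  dt <- sites_as_table(sites)
  bed <- dt[, c("chrom", "cluster_start0", "cluster_end", "site_id",
                "n_reads", "strand"), with = FALSE]
  data.table::fwrite(bed, paste0(prefix, ".bed"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  tsv <- dt[, setdiff(names(dt), "cluster_start0"), with = FALSE]
  data.table::fwrite(tsv, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE)
  invisible(paste0(prefix, ".tsv"))
}

## flatten a sites GRanges (matrix `counts` mcol) into a data.table
sites_as_table <- function(sites) {
  cnt <- S4Vectors::mcols(sites)$counts
  dt <- data.table::data.table(
    site_id = S4Vectors::mcols(sites)$site_id,
    chrom = as.character(GenomicRanges::seqnames(sites)),
    strand = as.character(GenomicRanges::strand(sites)),
    cluster_start0 = GenomicRanges::start(sites) - 1L,
    cluster_start = GenomicRanges::start(sites),
    cluster_end = GenomicRanges::end(sites),
    rep_pos = S4Vectors::mcols(sites)$rep_pos,
    n_reads = S4Vectors::mcols(sites)$n_reads
  )
  if (!is.null(cnt)) {
    cnt_dt <- data.table::as.data.table(as.matrix(cnt))
    names(cnt_dt) <- paste0("count_", colnames(cnt))
    dt <- cbind(dt, cnt_dt)
  }
  for (col in c("replication_rate", "pas_hexamer", "pas_offset", "is_novel",
                "gene_id")) {
    v <- S4Vectors::mcols(sites)[[col]]
    if (!is.null(v)) dt[[col]] <- v
  }
  dt
}

#' Write a complete simulated experiment to a directory
#'
#' Emits `genome.fa`, `annotation.gtf`, one BED6 read file per sample under
#' `reads/`, `sample_sheet.tsv`, truth tables (`truth_sites.tsv`,
#' `truth_genes.tsv`, `truth_reads.tsv`), the resolved `config.txt` and a
#' `metadata.txt` declaring the protocol orientation. The alignment files
#' never carry truth tags; those live only in the TSVs.
#'
#' @param sim an `apa_simulation` from [simulate_apa_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "apa_simulation"))
  dir.create(file.path(dir, "reads"), recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_gtf(sim, file.path(dir, "annotation.gtf"))
  for (s in sim$sample_sheet$sample) {
    sel <- S4Vectors::mcols(sim$reads)$sample == s
    write_reads_bed(sim$reads[sel],
                    file.path(dir, "reads", paste0(s, ".bed")))
  }
  data.table::fwrite(sim$sample_sheet, file.path(dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(sim$sites, file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(sim$gene_models, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(sim$read_truth, file.path(dir, "truth_reads.tsv"),
                     sep = "\t", quote = FALSE)
  write_config_file(unclass(sim$config), file.path(dir, "config.txt"))
  writeLines(c("orientation=sense", "format=bed6"),
             file.path(dir, "metadata.txt"))
  invisible(dir)
}
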