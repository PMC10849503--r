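test_that("read-end extraction picks the transcript-3'-most aligned base", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 174),
                               strand = c("+", "-"),
                               sample = c("a", "a"),
                               read_id = c("r1", "r2"))
  ends <- extract_read_ends(gr, "sense")
  expect_identical(ends$pos, c(174L, 101L))
  expect_identical(ends$strand, c("+", "-"))
  ## antisense protocol: mapped strand opposes the transcript strand
  ends <- extract_read_ends(gr, "antisense")
  expect_identical(ends$strand, c("-", "+"))
  expect_identical(ends$pos, c(101L, 174L))
  expect_error(extract_read_ends(gr, "upside-down"))
})

test_that("extracted ends on synthetic reads match the simulator's truth", {
  sim <- small_sim()
  ends <- extract_read_ends(sim$reads, sim$orientation)
  rt <- sim$read_truth
  expect_identical(ends$pos[match(rt$read_id, ends$read_id)],
                   rt$cleavage_pos)
})

test_that("mis-priming rule matches its definition on crafted sequences", {
  genome <- Biostrings::DNAStringSet(c(
    chrA = paste0("GGGGGGGGGG", "AAAAAAGCTT", "TTTTTTTTTT",
                  "AATAATAGCA", "CCCCCCCCCC")))
  ## downstream windows start at pos+1 on the plus strand
  expect_true(is_misprimed("chrA", 10L, "+", genome))   # AAAAAAGCTT
  expect_false(is_misprimed("chrA", 20L, "+", genome))  # TTTTTTTTTT
  expect_true(is_misprimed("chrA", 30L, "+", genome))   # 6 A of 10 = 60%
  ## minus strand reads the reverse complement: TTTTTTTTTT -> AAAAAAAAAA
  expect_true(is_misprimed("chrA", 31L, "-", genome))
  ## window past the contig end: missing bases are non-A
  expect_false(is_misprimed("chrA", 50L, "+", genome))
})

test_that("mis-priming agrees with a brute-force scan on random sequence", {
  set.seed(421)
  for (rep in 1:3) {
    seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE,
                        prob = c(0.35, 0.2, 0.2, 0.25)), collapse = "")
    genome <- Biostrings::DNAStringSet(c(chrR = seq))
    chars <- strsplit(seq, "")[[1]]
    for (strand in c("+", "-")) {
      pos <- 1:2000
      got <- is_misprimed(rep("chrR", 2000), pos, strand, genome)
      want <- vapply(pos, function(p) {
        win <- if (strand == "+") {
          ix <- (p + 1):(p + 10)
          chars[ix[ix <= 2000]]
        } else {
          ix <- (p - 10):(p - 1)
          w <- chars[ix[ix >= 1]]
          rev(chartr("ACGT", "TGCA", w))
        }
        run6 <- length(win) >= 6 && all(win[1:6] == "A")
        run6 || sum(win == "A") >= 6
      }, logical(1))
      expect_identical(got, want)
    }
  }
})

test_that("single-linkage clustering groups termini by gap and mode", {
  ends <- data.table::data.table(
    chrom = "chr1", strand = "+",
    pos = c(rep(100L, 5), rep(101L, 3)),
    sample = "s1", read_id = sprintf("r%d", 1:8))
  sites <- cluster_ends(ends, max_gap = 25L, min_reads = 3L)
  expect_length(sites, 1L)
  expect_identical(S4Vectors::mcols(sites)$rep_pos, 100L)
  expect_identical(S4Vectors::mcols(sites)$n_reads, 8L)

  ends$pos <- c(rep(100L, 5), rep(200L, 3))
  sites <- cluster_ends(ends, max_gap = 25L, min_reads = 3L)
  expect_length(sites, 2L)

  ## modal tie breaks towards the transcript 3' end
  tie <- data.table::data.table(chrom = "chr1", strand = c("+", "+"),
                                pos = c(300L, 305L), sample = "s1",
                                read_id = c("a", "b"))
  tie <- rbind(tie, tie)
  expect_identical(
    S4Vectors::mcols(cluster_ends(tie, 25L, 1L))$rep_pos, 305L)
  tie$strand <- "-"
  expect_identical(
    S4Vectors::mcols(cluster_ends(tie, 25L, 1L))$rep_pos, 300L)

  ## min_reads discards thin clusters; counts are conserved otherwise
  ends <- data.table::data.table(
    chrom = "chr1", strand = "+", pos = c(rep(100L, 5), 500L),
    sample = "s1", read_id = sprintf("r%d", 1:6))
  sites <- cluster_ends(ends, 25L, 3L)
  expect_length(sites, 1L)
  expect_identical(sum(S4Vectors::mcols(sites)$n_reads), 5L)
})

test_that("clustered counts conserve the retained termini", {
  sim <- small_sim()
  ends <- extract_read_ends(sim$reads, sim$orientation)
  kept <- filter_misprimed(ends, sim$genome)$ends
  sites <- cluster_ends(kept, 25L, 1L, samples = sim$sample_sheet$sample)
  expect_identical(sum(S4Vectors::mcols(sites)$n_reads), nrow(kept))
  expect_identical(sum(S4Vectors::mcols(sites)$counts), nrow(kept))
  expect_true(all(S4Vectors::mcols(sites)$n_reads > 0))
})

test_that("replication filter applies the 0.75 cutoff per condition", {
  counts <- rbind(
    c(5, 5, 5, 0, 0, 0),   # 3/3 control -> rate 1, kept
    c(5, 5, 0, 0, 2, 0),   # best condition 2/3 -> removed
    c(1, 1, 1, 1, 1, 1),   # all detected -> rate 1
    c(0, 0, 0, 5, 5, 5))   # 3/3 knockdown -> kept
  colnames(counts) <- sheet33$sample
  sites <- make_sites("chr1", c(100L, 200L, 300L, 400L), "+", counts)
  kept <- replication_filter(sites, sheet33, min_rate = 0.75)
  expect_identical(S4Vectors::mcols(kept)$rep_pos, c(100L, 300L, 400L))
  expect_equal(S4Vectors::mcols(kept)$replication_rate, c(1, 1, 1))
  ## overall scope counts across all six samples
  kept <- replication_filter(sites, sheet33, min_rate = 0.75,
                             scope = "overall")
  expect_identical(S4Vectors::mcols(kept)$rep_pos, 300L)
  expect_error(replication_filter(sites, sheet33, min_rate = 0),
               "min_rate")
})

test_that("kept/removed status matches the cutoff over all 3+3 patterns", {
  pats <- expand.grid(rep(list(c(0L, 5L)), 6))
  colnames(pats) <- sheet33$sample
  sites <- make_sites("chr1", seq_len(nrow(pats)) * 100L, "+",
                      as.matrix(pats))
  kept <- replication_filter(sites, sheet33, min_rate = 0.75,
                             detection_min_reads = 1L)
  det <- as.matrix(pats) >= 1L
  best <- pmax(rowMeans(det[, 1:3]), rowMeans(det[, 4:6]))
  expect_identical(S4Vectors::mcols(sites)$rep_pos[best >= 0.75],
                   S4Vectors::mcols(kept)$rep_pos)
  ## under per-condition scope that is exactly "3/3 in some condition"
  expect_identical(best >= 0.75, rowSums(det[, 1:3]) == 3L |
                     rowSums(det[, 4:6]) == 3L)
})

test_that("PAS detection finds the hexamer nearest the canonical offset", {
  pre <- strrep("C", 100)
  ## AATAAA starting 21 nt upstream of the cleavage base at position 122
  seq <- paste0(pre, "AATAAA", strrep("G", 15), "T", strrep("C", 80))
  genome <- Biostrings::DNAStringSet(c(chrP = seq))
  site <- make_sites("chrP", 122L, "+", matrix(5, 1, 1,
                                               dimnames = list(NULL, "s1")))
  out <- detect_pas(site, genome)
  expect_identical(S4Vectors::mcols(out)$pas_hexamer, "AATAAA")
  expect_identical(S4Vectors::mcols(out)$pas_offset, 21L)
  ## no hexamer in the window -> none
  site2 <- make_sites("chrP", 60L, "+", matrix(5, 1, 1,
                                               dimnames = list(NULL, "s1")))
  expect_true(is.na(S4Vectors::mcols(detect_pas(site2, genome))$pas_hexamer))
  ## minus strand: genomic TTTATT mirrors to AATAAA
  seqm <- paste0(strrep("C", 100), "TTTATT", strrep("C", 100))
  genm <- Biostrings::DNAStringSet(c(chrM = seqm))
  sitem <- make_sites("chrM", 85L, "-", matrix(5, 1, 1,
                                               dimnames = list(NULL, "s1")))
  out <- detect_pas(sitem, genm)
  expect_identical(S4Vectors::mcols(out)$pas_hexamer, "AATAAA")
  expect_identical(S4Vectors::mcols(out)$pas_offset, 21L)
})

test_that("planted PAS hexamers are recovered on simulated data", {
  sim <- small_sim()
  called <- call_polya_sites(sim$reads, sim$genome, sim$sample_sheet)
  pas <- S4Vectors::mcols(called$sites)$pas_hexamer
  expect_gte(mean(!is.na(pas)), 0.95)
  expect_true(all(pas[!is.na(pas)] %in% c("AATAAA", "ATTAAA")))
})

test_that("novelty annotation respects strand and tolerance", {
  site <- make_sites("chr1", 1000L, "+",
                     matrix(5, 1, 1, dimnames = list(NULL, "s1")))
  known <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1003, 1003),
                                  strand = "+")
  expect_false(S4Vectors::mcols(
    annotate_novel(site, known, tolerance = 10L))$is_novel)
  expect_true(S4Vectors::mcols(
    annotate_novel(site, known, tolerance = 1L))$is_novel)
  ## same position on the other strand does not match
  GenomicRanges::strand(known) <- "-"
  expect_true(S4Vectors::mcols(
    annotate_novel(site, known, tolerance = 10L))$is_novel)
  ## empty known set -> all novel; exact match at tolerance 0 -> known
  expect_true(S4Vectors::mcols(
    annotate_novel(site, GenomicRanges::GRanges()))$is_novel)
  known0 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1000),
                                   strand = "+")
  expect_false(S4Vectors::mcols(
    annotate_novel(site, known0, tolerance = 0L))$is_novel)
})

test_that("the mis-priming filter is safe for true sites on synthetic data", {
  sim <- small_sim()
  ends <- extract_read_ends(sim$reads, sim$orientation)
  mis <- is_misprimed(ends$chrom, ends$pos, ends$strand, sim$genome)
  art <- sim$read_truth$origin[match(ends$read_id,
                                     sim$read_truth$read_id)] == "artifact"
  expect_gte(mean(mis[art]), 0.95)   # artifacts removed
  expect_lte(mean(mis[!art]), 0.01)  # true-site reads retained
})
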