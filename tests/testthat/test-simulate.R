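test_that("invalid configurations are rejected", {
  expect_error(simulation_config(fraction_null = 0.5),
               "fractions must sum to 1")
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(misprime_rate = 1), "misprime_rate")
  expect_error(simulation_config(reads_per_gene = 0), "reads_per_gene")
})

test_that("the simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_genes = 8, reads_per_gene = 100, seed = 3)
  s1 <- simulate_apa_experiment(cfg)
  s2 <- simulate_apa_experiment(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$read_truth, s2$read_truth)
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("reference construction plants the promised architecture", {
  cfg <- simulation_config(n_genes = 12, fraction_cryptic = 1,
                           fraction_lengthening = 0, fraction_shortening = 0,
                           fraction_null = 0, seed = 5)
  ref <- build_reference(cfg)
  ## every gene carries exactly one flagged cryptic site
  n_cry <- tapply(ref$sites$is_cryptic, ref$sites$gene_id, sum)
  expect_true(all(n_cry == 1))
  ## PAS hexamer planted upstream of every cleavage site, strand-aware
  seqs <- as.character(ref$genome)
  for (i in seq_len(nrow(ref$sites))) {
    s <- ref$sites[i, ]
    win <- if (s$strand == "+") {
      substr(seqs[[s$chrom]], s$pos - 30, s$pos - 10)
    } else {
      apa3seq::revcomp(substr(seqs[[s$chrom]], s$pos + 10, s$pos + 30))
    }
    expect_match(win, "AATAAA|ATTAAA")
  }
  ## one A-rich stretch (>= 6 consecutive sense-strand A) per gene body,
  ## >= 50 nt from any true site
  gm <- ref$gene_models
  for (g in seq_len(nrow(gm))) {
    cl <- gm$artifact_cleavage[g]
    win <- if (gm$strand[g] == "+") {
      substr(seqs[[gm$chrom[g]]], cl + 1, cl + 8)
    } else {
      apa3seq::revcomp(substr(seqs[[gm$chrom[g]]], cl - 8, cl - 1))
    }
    expect_identical(win, "AAAAAAAA")
    d <- abs(ref$sites$pos[ref$sites$gene_id == gm$gene_id[g]] - cl)
    expect_true(all(d >= 50))
  }
})

test_that("the emitted GTF has one gene record and two exons per gene", {
  cfg <- simulation_config(n_genes = 50, seed = 11)
  ref <- build_reference(cfg)
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(ref, gtf)
  lines <- readLines(gtf)
  type <- vapply(strsplit(lines, "\t"), `[[`, "", 3)
  expect_identical(sum(type == "gene"), 50L)
  expect_identical(sum(type == "exon"), 100L)
  ## round-trip through the module's own reader without loss
  gm <- read_gene_models(gtf)
  expect_identical(gm$gene_id, sort(ref$gene_models$gene_id))
  ord <- match(gm$gene_id, ref$gene_models$gene_id)
  expect_identical(gm$tes, ref$gene_models$tes[ord])
  expect_identical(gm$stop_pos, ref$gene_models$stop_pos[ord])
  expect_identical(gm$start, ref$gene_models$start[ord])
})

test_that("true usage fractions obey the planted class contracts", {
  cfg <- simulation_config(n_genes = 40, seed = 2)
  truth <- assign_usage(build_reference(cfg))
  st <- truth$sites
  sums <- tapply(st$usage_control, st$gene_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  sums <- tapply(st$usage_knockdown, st$gene_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  gm <- truth$gene_models
  for (g in seq_len(nrow(gm))) {
    s <- st[st$gene_id == gm$gene_id[g], ]
    s <- s[order(s$sense_pos), ]
    if (gm$class[g] == "null") {
      expect_identical(s$usage_control, s$usage_knockdown)
    } else if (gm$class[g] == "lengthening") {
      ## >= 0.15 usage mass moves proximal -> distal
      expect_lte(s$usage_knockdown[1], s$usage_control[1] - 0.15)
      k <- nrow(s)
      expect_gte(s$usage_knockdown[k], s$usage_control[k] + 0.15)
    } else if (gm$class[g] == "shortening") {
      expect_gte(s$usage_knockdown[1], s$usage_control[1] + 0.15)
    } else {
      cr <- s[s$is_cryptic, ]
      expect_lte(cr$usage_control, 0.05)
      expect_gte(cr$usage_knockdown, 0.10)
      expect_gte(cr$usage_knockdown - cr$usage_control, 0.10)
    }
  }
})

test_that("simulated read ends follow the planted sites and artifacts", {
  sim <- small_sim()
  rt <- sim$read_truth
  truth <- sim$sites
  art <- rt$origin == "artifact"
  ## artifact reads end exactly at the planted cleavage position
  gm <- sim$gene_models
  expect_identical(rt$cleavage_pos[art],
                   gm$artifact_cleavage[match(rt$gene_id[art], gm$gene_id)])
  ## non-artifact ends stay within +-6 nt of their true site (sd 2)
  d <- abs(rt$cleavage_pos[!art] -
             truth$pos[match(rt$origin[!art], truth$site_id)])
  expect_gte(mean(d <= 6), 0.99)
  ## conservation: per gene, reads split site/artifact as configured
  expect_equal(mean(art), sim$config$misprime_rate, tolerance = 0.02)
})

test_that("misprime_rate 0 yields no read ends at planted A-rich stretches", {
  cfg <- simulation_config(n_genes = 6, misprime_rate = 0,
                           reads_per_gene = 300, seed = 9)
  sim <- simulate_apa_experiment(cfg)
  expect_false(any(sim$read_truth$origin == "artifact"))
  gm <- sim$gene_models
  hit <- mapply(function(g, cl) {
    any(abs(sim$read_truth$cleavage_pos[sim$read_truth$gene_id == g] -
              cl) <= 1)
  }, gm$gene_id, gm$artifact_cleavage)
  expect_false(any(hit))
})

test_that("read records round-trip through the BED reader without loss", {
  sim <- small_sim()
  s <- sim$sample_sheet$sample[1]
  sel <- S4Vectors::mcols(sim$reads)$sample == s
  path <- tempfile(fileext = ".bed")
  write_reads_bed(sim$reads[sel], path)
  back <- read_reads_bed(path, sample = s)
  expect_identical(GenomicRanges::start(back),
                   GenomicRanges::start(sim$reads[sel]))
  expect_identical(GenomicRanges::end(back),
                   GenomicRanges::end(sim$reads[sel]))
  expect_identical(as.character(GenomicRanges::strand(back)),
                   as.character(GenomicRanges::strand(sim$reads[sel])))
  expect_identical(S4Vectors::mcols(back)$read_id,
                   S4Vectors::mcols(sim$reads[sel])$read_id)
})
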