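## independent oracle: two-sided Fisher p by explicit table enumeration
## with binomial coefficients (no dhyper)
enum_fisher_p <- function(a, b, c, d) {
  k <- a + b
  m <- a + c
  n <- b + d
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  probs <- exp(logp)
  obs <- probs[xs == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

test_that("the exact usage test matches enumeration and fisher.test", {
  tables <- rbind(
    c(10, 90, 40, 60),
    c(0, 10, 5, 5),
    c(3, 0, 0, 4),
    c(1, 1, 1, 1),
    c(12, 3, 2, 13),
    c(0, 0, 7, 3),     # degenerate margin -> p = 1
    c(25, 5, 5, 25))
  p <- fisher_exact_p(tables[, 1], tables[, 2], tables[, 3], tables[, 4])
  want <- apply(tables, 1, function(t) enum_fisher_p(t[1], t[2], t[3], t[4]))
  expect_equal(p, want, tolerance = 1e-12)
  nondeg <- rowSums(tables[, 1:2]) > 0 & rowSums(tables[, 3:4]) > 0 &
    (tables[, 1] + tables[, 3]) > 0 & (tables[, 2] + tables[, 4]) > 0
  for (i in which(nondeg)) {
    ft <- stats::fisher.test(matrix(tables[i, ], 2, byrow = TRUE))
    expect_equal(p[i], ft$p.value, tolerance = 1e-9)
  }
  ## identical proportions in both conditions -> p = 1
  expect_equal(fisher_exact_p(10L, 90L, 20L, 180L), 1)
})

test_that("sites are assigned to genes by strand, window and nearest TES", {
  gm <- rbind(one_gene_model("+", 1000L, 5000L, 3000L, "g1"),
              one_gene_model("+", 20000L, 24000L, 22000L, "g2"))
  counts <- matrix(10, 4, 1, dimnames = list(NULL, "s1"))
  sites <- make_sites("chr1", c(4500L, 5500L, 300L, 4500L),
                      c("+", "+", "+", "-"), counts)
  out <- assign_sites_to_genes(sites, gm, downstream_extension = 5000L)
  ## in-gene and 500-nt-downstream sites assigned; upstream-of-gene and
  ## opposite-strand sites not
  expect_identical(S4Vectors::mcols(out)$rep_pos, c(4500L, 5500L))
  expect_identical(S4Vectors::mcols(out)$gene_id, c("g1", "g1"))
  ## a site between two extended genes goes to the nearer TES
  gm2 <- rbind(one_gene_model("+", 1000L, 5000L, 3000L, "g1"),
               one_gene_model("+", 6000L, 9000L, 7000L, "g2"))
  site <- make_sites("chr1", 8500L, "+",
                     matrix(1, 1, 1, dimnames = list(NULL, "s1")))
  out <- assign_sites_to_genes(site, gm2, downstream_extension = 5000L)
  expect_identical(S4Vectors::mcols(out)$gene_id, "g2")
})

test_that("usage fractions and delta PUI follow the count arithmetic", {
  counts <- rbind(c(30, 30, 30, 20, 20, 20),   # proximal
                  c(10, 0, 0, 40, 0, 0))       # distal, ctrl 10/100 kd 40/100
  colnames(counts) <- sheet33$sample
  sites <- make_sites("chr1", c(100L, 200L), "+", counts)
  S4Vectors::mcols(sites)$gene_id <- "g1"
  u <- compute_usage(sites, sheet33)
  pc <- u$per_condition
  expect_equal(pc$usage_control, c(0.9, 0.1))
  expect_equal(pc$usage_knockdown, c(0.6, 0.4))
  expect_equal(pc$delta_usage, c(-0.3, 0.3))
  expect_identical(pc$site_rank, c(1L, 2L))
  ## per-sample normalisation
  ps <- u$per_sample
  expect_equal(ps$usage[ps$sample == "kd_1"], c(1 / 3, 2 / 3))
  expect_equal(ps$usage[ps$sample == "ctrl_2"], c(1, 0))
  ## an all-zero sample column yields undefined per-sample usage
  counts0 <- counts
  counts0[, "ctrl_2"] <- 0
  sites0 <- make_sites("chr1", c(100L, 200L), "+", counts0)
  S4Vectors::mcols(sites0)$gene_id <- "g1"
  ps0 <- compute_usage(sites0, sheet33)$per_sample
  expect_true(all(is.nan(ps0$usage[ps0$sample == "ctrl_2"])))
  ## minus strand: proximal = highest genomic coordinate
  sites_m <- make_sites("chr1", c(100L, 200L), "-", counts)
  S4Vectors::mcols(sites_m)$gene_id <- "g1"
  pcm <- compute_usage(sites_m, sheet33)$per_condition
  expect_identical(pcm$rep_pos[pcm$site_rank == 1L], 200L)
})

test_that("usage is compositional: per-gene delta PUI sums to zero", {
  sim <- small_sim()
  called <- call_polya_sites(sim$reads, sim$genome, sim$sample_sheet)
  assigned <- assign_sites_to_genes(called$sites, sim$gene_models)
  pc <- compute_usage(assigned, sim$sample_sheet)$per_condition
  sums <- tapply(pc$delta_usage, pc$gene_id, sum)
  expect_true(all(abs(sums) < 1e-9))
  expect_true(all(pc$delta_usage >= -1 & pc$delta_usage <= 1))
})

test_that("the reporting pair is the two largest usage changes", {
  gd <- data.table::data.table(
    gene_id = "g", site_id = c("a", "b", "c"), site_rank = 1:3,
    rep_pos = c(100L, 200L, 300L),
    count_control = c(50, 50, 50), count_knockdown = c(50, 50, 50),
    delta_usage = c(0.02, 0.2, -0.15))
  pair <- select_gene_pair(gd)
  expect_identical(pair$site_id, c("b", "c"))
  ## two sites -> identity
  expect_identical(select_gene_pair(gd[1:2])$site_id, c("a", "b"))
  ## ties: larger pooled count, then 5'-most; invariant to input order
  gd$delta_usage <- c(0.2, -0.2, 0.2)
  gd$count_knockdown <- c(50, 90, 50)
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    pair <- select_gene_pair(gd[perm])
    expect_identical(pair$site_id, c("a", "b"))
  }
  expect_error(select_gene_pair(gd[1]), "fewer than two")
})

test_that("direction calls honour strict thresholds", {
  expect_identical(call_direction(0.3, 0.001), "lengthening")
  expect_identical(call_direction(0.3, 0.2), "none")
  expect_identical(call_direction(-0.3, 0.001), "shortening")
  ## boundary: |delta PUI| must strictly exceed 0.10
  expect_identical(call_direction(-0.10, 0.001), "none")
  expect_identical(call_direction(0.10, 0.001), "none")
  ## boundary: adjusted p must be strictly below alpha
  expect_identical(call_direction(0.3, 0.05), "none")
  expect_identical(call_direction(c(0.2, NA), c(0.01, NA)),
                   c("lengthening", "none"))
})

test_that("expression association flags 1.5-fold changes with pseudocount", {
  out <- associate_expression(c(100, 100, 0), c(200, 120, 50))
  expect_equal(out$expression_log2fc[1], log2(201 / 101))
  expect_identical(out$expression_flag, c(TRUE, FALSE, TRUE))
  expect_true(all(is.finite(out$expression_log2fc)))
})

test_that("single-site genes are excluded from APA testing", {
  counts1 <- matrix(rep(c(30, 5), each = 6), 2, 6, byrow = TRUE)
  colnames(counts1) <- sheet33$sample
  sites <- make_sites("chr1", c(100L, 200L), "+", counts1)
  S4Vectors::mcols(sites)$gene_id <- c("g1", "g2")  # one site each
  u <- compute_usage(sites, sheet33)
  res <- apa_gene_results(u)
  expect_identical(nrow(res), 0L)
  pc <- test_site_usage(u)$per_condition
  expect_true(all(is.na(pc$p_value)))
})

test_that("gene-level results recover a planted strong shift", {
  counts <- rbind(c(90, 90, 90, 60, 60, 60),
                  c(10, 10, 10, 40, 40, 40))
  colnames(counts) <- sheet33$sample
  sites <- make_sites("chr1", c(100L, 500L), "+", counts)
  S4Vectors::mcols(sites)$gene_id <- "g1"
  res <- apa_gene_results(compute_usage(sites, sheet33))
  expect_equal(res$delta_pui, 0.3)
  expect_identical(res$direction, "lengthening")
  expect_lt(res$adj_p, 0.05)
  ## degenerate: a zero condition margin yields p = 1 and no call
  counts0 <- counts
  counts0[, 4:6] <- 0
  sites0 <- make_sites("chr1", c(100L, 500L), "+", counts0)
  S4Vectors::mcols(sites0)$gene_id <- "g1"
  res0 <- apa_gene_results(compute_usage(sites0, sheet33))
  expect_identical(nrow(res0), 0L)  # knockdown total is zero -> unusable
})
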