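test_that("overlap fraction follows the >=1 bp and flank definitions", {
  sizes <- c(chrI = 100000)
  annot <- granges_0based("chrI", 1000, 2000, sizes)
  expect_equal(overlap_fraction(annot, annot, 0), 1)
  # query ending exactly where the annotation starts (0-based adjacency)
  q <- granges_0based("chrI", 900, 1000, sizes)
  expect_equal(overlap_fraction(q, annot, 0), 0)
  expect_equal(overlap_fraction(q, annot, 500), 1)
  expect_error(overlap_fraction(GenomicRanges::GRanges(), annot, 0), "empty")
})

test_that("overlap fraction equals the quadratic all-pairs oracle", {
  set.seed(5)
  sizes <- c(chrA = 50000, chrB = 30000)
  for (rep in 1:100) {
    nq <- 20; na <- 5
    qc <- sample(names(sizes), nq, replace = TRUE)
    qs <- floor(runif(nq, 0, sizes[qc] - 500)); qe <- qs + sample(50:500, nq, TRUE)
    ac <- sample(names(sizes), na, replace = TRUE)
    as_ <- floor(runif(na, 0, sizes[ac] - 800)); ae <- as_ + sample(100:800, na, TRUE)
    fl <- sample(c(0, 100, 500), 1)
    f <- overlap_fraction(granges_0based(qc, qs, qe, sizes),
                          granges_0based(ac, as_, ae, sizes), fl)
    f_oracle <- overlap_fraction_oracle(qs, qe, qc, as_, ae, ac, fl, sizes)
    expect_equal(f, f_oracle)
  }
})

test_that("overlap fraction is monotone non-decreasing in the flank", {
  set.seed(6)
  sizes <- c(chrA = 50000)
  qs <- floor(runif(30, 0, 48000))
  q <- granges_0based("chrA", qs, qs + sample(100:1000, 30, TRUE), sizes)
  a <- granges_0based("chrA", c(5000, 20000), c(5400, 21000), sizes)
  fs <- vapply(c(0, 100, 500, 1000, 5000), function(fl)
    overlap_fraction(q, a, fl), 0)
  expect_true(all(diff(fs) >= 0))
})

test_that("the Monte Carlo overlap test handles degenerate annotations", {
  sizes <- c(chrI = 100000)
  # annotation covering the whole genome: every null F = 1, p = 1
  whole <- granges_0based("chrI", 0, 100000, sizes)
  q <- granges_0based("chrI", c(500, 3000), c(1500, 4000), sizes)
  r <- mc_overlap_test(q, whole, sizes, region_length_bp = 1000,
                       n_sims = 200, seed = 1)
  expect_true(all(r$null_f == 1))
  expect_equal(r$p_empirical, 1)
  # empty annotation: warning, p = 1
  expect_warning(
    r0 <- mc_overlap_test(q, GenomicRanges::GRanges(), sizes,
                          region_length_bp = 1000, n_sims = 100, seed = 1),
    "empty annotation")
  expect_equal(r0$p_empirical, 1)
  expect_equal(r0$f_observed, 0)
})

test_that("a saturated observed overlap on a sparse annotation is significant", {
  # toy genome: 1 Mb with a single 10 kb block; 10 query regions inside it.
  # Analytically, per-region null hit probability ~ (10000 + 1000)/1e6, so
  # P(all 10 hit) is far below 1e-3.
  sizes <- c(chrI = 1000000)
  block <- granges_0based("chrI", 500000, 510000, sizes)
  q <- granges_0based("chrI", seq(500500, 509000, length.out = 10),
                      seq(500500, 509000, length.out = 10) + 500, sizes)
  r <- mc_overlap_test(q, block, sizes, region_length_bp = 1000,
                       n_sims = 10000, seed = 2)
  expect_equal(r$f_observed, 1)
  expect_lte(r$p_empirical, 0.001)
  expect_match(r$p_text, "^<")
})

test_that("the null is invariant to annotation order and merging", {
  sizes <- c(chrI = 200000, chrII = 150000)
  a <- granges_0based(c("chrI", "chrI", "chrII", "chrI"),
                      c(1000, 1500, 7000, 50000),
                      c(2000, 2600, 9000, 51000), sizes)
  run <- function(annot) {
    mc_overlap_test(f_observed = 0.3, n_regions = 25, annot = annot,
                    chrom_sizes = sizes, region_length_bp = 800,
                    n_sims = 2000, seed = 31)
  }
  r1 <- run(a)
  r2 <- run(rev(a))
  r3 <- run(GenomicRanges::reduce(a))
  expect_identical(r1$null_f, r2$null_f)
  expect_identical(r1$null_f, r3$null_f)
  expect_identical(r1$p_empirical, r3$p_empirical)
})

test_that("the arm/center partition tiles chromosomes with half-open bounds", {
  sizes <- c(chrI = 1200, chrX = 1200)
  p <- chrom_partition(sizes, x_chrom = "chrX")
  for (cn in names(sizes)) {
    rows <- p[p$chrom == cn, ]
    expect_equal(min(rows$start), 0)
    expect_equal(max(rows$end), sizes[[cn]])
    expect_equal(sum(rows$end - rows$start), sizes[[cn]])
  }
  # a gene midpoint exactly at the 1/4 boundary goes to the center
  models <- data.frame(gene_id = "g", chrom = "chrI", start = 250L, end = 350L,
                       strand = "+", gene_length = 100L, exon_length = 80L)
  # midpoint 300 = 1200/4
  r <- arm_center_enrichment("g", rbind(models,
    data.frame(gene_id = c("a1", "a2", "c1"), chrom = "chrI",
               start = c(10L, 1000L, 500L), end = c(20L, 1010L, 510L),
               strand = "+", gene_length = 10L, exon_length = 5L)),
    sizes["chrI"], x_chrom = "chrX")
  obs <- r$table[r$table$region == "center", "observed"]
  expect_equal(obs, 1)
})

test_that("genes placed at chromosome midpoints land fully in the center", {
  sizes <- c(chrI = 100000)
  mk <- function(ids, pos) data.frame(
    gene_id = ids, chrom = "chrI", start = pos, end = pos + 100L,
    strand = "+", gene_length = 100L, exon_length = 80L)
  universe <- mk(paste0("g", 1:50), seq(1000L, 99000L, length.out = 50))
  mid <- mk(paste0("m", 1:5), rep(49950L, 5) + (0:4))
  all_genes <- rbind(universe, mid)
  r <- arm_center_enrichment(paste0("m", 1:5), all_genes, sizes, x_chrom = "none")
  tab <- r$table
  expect_equal(tab$observed[tab$region == "center"], 5)
  expect_equal(tab$observed[tab$region == "arms"], 0)
})

test_that("uniform gene sets are rarely called enriched", {
  set.seed(8)
  sizes <- c(chrI = 100000)
  universe <- data.frame(
    gene_id = paste0("g", 1:400), chrom = "chrI",
    start = floor(runif(400, 0, 99000)), strand = "+",
    gene_length = 200L, exon_length = 100L)
  universe$end <- universe$start + 200L
  n_sig <- 0
  for (i in 1:100) {
    pick <- sample(universe$gene_id, 60)
    r <- arm_center_enrichment(pick, universe, sizes, x_chrom = "none")
    if (!is.null(r$tests) && any(r$tests$p_value < 0.05)) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 10)  # no chromosome significant in >= 90% of draws
})

test_that("chromosome depletion test matches its hypergeometric oracle", {
  set.seed(9)
  universe <- data.frame(
    gene_id = paste0("g", 1:1000),
    chrom = rep(c("chrI", "chrX"), c(800, 200)),
    start = 0L, end = 100L, strand = "+",
    gene_length = 100L, exon_length = 80L)
  # identity set: fold 1, unremarkable p
  r_all <- chrom_depletion_test(universe$gene_id, universe, "chrX",
                                n_sims = 2000, seed = 1)
  expect_equal(r_all$fold_depletion, 1)
  expect_gte(r_all$p_value, 0.4)
  # autosome-only set of 100 when X holds 20%: strong depletion
  auto <- sample(universe$gene_id[universe$chrom == "chrI"], 100)
  r_dep <- chrom_depletion_test(auto, universe, "chrX",
                                n_sims = 10000, seed = 2)
  expect_gte(r_dep$fold_depletion, 5)
  expect_lt(r_dep$p_value, 0.01)
  expect_match(r_dep$fold_display, "^>")   # observed 0: lower bound notation
  expect_equal(r_dep$p_value, phyper(0, 200, 800, 100), tolerance = 3e-3)
  # MC p converges to the hypergeometric tail as n_sims grows
  some <- c(sample(universe$gene_id[universe$chrom == "chrI"], 90),
            sample(universe$gene_id[universe$chrom == "chrX"], 10))
  exact <- phyper(10, 200, 800, 100)
  errs <- vapply(c(500, 5000, 50000), function(ns) {
    abs(chrom_depletion_test(some, universe, "chrX", n_sims = ns,
                             seed = 3)$p_value - exact)
  }, 0)
  expect_lt(errs[3], 0.01)
  expect_lt(errs[3], errs[1] + 0.005)
  expect_error(chrom_depletion_test(character(0), universe, "chrX"), "empty")
  expect_error(chrom_depletion_test("g1", universe, "chrZ"), "absent")
})
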