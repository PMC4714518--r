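test_that("condition groups encode the design exclusions", {
  g <- condition_groups()
  expect_false("23C-G1" %in% g$G23)
  expect_equal(g$G23, paste0("23C-G", 2:6))
  expect_length(intersect(g$G15, g$Gp15), 0)
  expect_true(all(unlist(g) %in% generation_levels()))
})

# small deterministic-ish dataset used across the calling tests
make_small_run <- function(seed = 7, n_genes = 300,
                           props = c(wt_heat_induced = 0.05, heat_repressed = 0.03,
                                     nhg_plain = 0, high_stringent_nhg = 0.05,
                                     cumulative_nhg = 0, sirna_loss = 0,
                                     sirna_gain = 0), ...) {
  cfg <- sim_config(n_genes = n_genes, class_props = props, seed = seed, ...)
  truth <- simulate_genome(cfg)
  counts <- simulate_counts(cfg, truth)
  list(cfg = cfg, truth = truth, counts = counts,
       wt = merge_genotype(counts, "WT"),
       mut = merge_genotype(counts, "hrde1"))
}

test_that("flat genes are never called; sub-cutoff folds are excluded", {
  run <- make_small_run()
  wc <- call_temperature_sensitive(run$wt)
  ts <- truth_sets(run$truth)
  # planted nulls with identical expectation across generations: none called
  expect_length(intersect(wc$heat_induced, ts$null_genes), 0)
  # a 1.5-fold gene cannot pass fold_cutoff 2 regardless of q: force a strong
  # sub-cutoff shift by scaling expected counts
  m <- matrix(rep(c(400L, 600L), each = 8), 2, 8, byrow = TRUE,
              dimnames = list(c("flat", "shift"),
                              paste0("s", 1:8)))
  m["shift", ] <- c(rep(400L, 3), rep(600L, 5))  # exact 1.5-fold, no noise
  meta <- tiny_meta(8, generations = c(paste0("15C-G", 1:3), paste0("23C-G", 2:6)))
  cm <- count_matrix(m, meta)
  cc <- call_temperature_sensitive(cm, config = classify_config())
  expect_false("shift" %in% cc$heat_induced)
  expect_false("flat" %in% cc$heat_induced)
})

test_that("missing generations are reported by name", {
  run <- make_small_run()
  crop <- subset_samples(run$wt, run$wt$samples$generation != "23C-G4")
  expect_error(call_temperature_sensitive(crop), "23C-G4")
})

test_that("raising the fold cutoff only shrinks the called sets", {
  run <- make_small_run()
  c2 <- call_temperature_sensitive(run$mut, config = classify_config(fold_cutoff = 2))
  c4 <- call_temperature_sensitive(run$mut, config = classify_config(fold_cutoff = 4))
  expect_true(all(c4$heat_induced %in% c2$heat_induced))
  expect_true(all(c4$heat_repressed %in% c2$heat_repressed))
})

test_that("swapping group labels maps heat-induced to heat-repressed exactly", {
  run <- make_small_run()
  g <- condition_groups()
  swapped <- list(G15 = g$G23, G23 = g$G15, Gp15 = g$Gp15)
  fwd <- call_temperature_sensitive(run$mut, grouping = g)
  rev <- call_temperature_sensitive(run$mut, grouping = swapped)
  expect_setequal(fwd$heat_induced, rev$heat_repressed)
  expect_setequal(fwd$heat_repressed, rev$heat_induced)
})

test_that("the cascade identities hold on a synthetic run", {
  run <- make_small_run(props = c(wt_heat_induced = 0.04, heat_repressed = 0.02,
                                  nhg_plain = 0.06, high_stringent_nhg = 0.04,
                                  cumulative_nhg = 0.01, sirna_loss = 0,
                                  sirna_gain = 0))
  wc <- call_temperature_sensitive(run$wt)
  mc <- call_temperature_sensitive(run$mut)
  casc <- build_cascade(wc, mc, run$wt, run$mut)
  expect_setequal(casc$nhg, setdiff(casc$heat_induced_mut, casc$heat_induced_wt))
  expect_true(all(casc$high_stringent_nhg %in% casc$nhg))
  expect_setequal(casc$hrde1_repressed_23C_unique,
                  setdiff(casc$hrde1_repressed_23C,
                          union(casc$hrde1_repressed_15C,
                                casc$hrde1_repressed_p15C)))
  # recovery against the planted truth
  ts <- truth_sets(run$truth)
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  expect_gte(jacc(casc$nhg, ts$nhg), 0.85)
  expect_gte(jacc(casc$heat_induced_wt, ts$heat_induced_wt), 0.85)
  expect_gte(jacc(casc$high_stringent_nhg, ts$high_stringent_nhg), 0.85)
})

test_that("identical call sets collapse the NHG set to empty", {
  run <- make_small_run()
  wc <- call_temperature_sensitive(run$wt)
  casc <- build_cascade(wc, wc, run$wt, run$wt)
  expect_length(casc$nhg, 0)
})

test_that("differing gene universes between genotypes are an error", {
  run <- make_small_run()
  wc <- call_temperature_sensitive(run$wt)
  mc <- call_temperature_sensitive(run$mut)
  crop <- count_matrix(run$mut$counts[-1, ], run$mut$samples)
  expect_error(build_cascade(wc, mc, run$wt, crop), "universes differ")
  expect_error(call_hrde1_repressed(run$wt, crop, condition_groups()$G23),
               "universes differ")
})

test_that("HRDE-1-repressed calls: null case and planted 23 C derepression", {
  run <- make_small_run()
  # identical matrices in both genotypes: nothing called
  same <- call_hrde1_repressed(run$wt, run$wt, condition_groups()$G23)
  expect_length(same$repressed, 0)
  # planted 4-fold mutant-only derepression at 23 C (the high-stringency
  # trajectory with heat_fold = 4), seed 11
  run4 <- make_small_run(seed = 11, n_genes = 600, heat_fold = 4,
                         props = c(wt_heat_induced = 0, heat_repressed = 0,
                                   nhg_plain = 0, high_stringent_nhg = 0.05,
                                   cumulative_nhg = 0, sirna_loss = 0,
                                   sirna_gain = 0))
  planted <- truth_sets(run4$truth)$high_stringent_nhg
  at23 <- call_hrde1_repressed(run4$wt, run4$mut, condition_groups()$G23)
  at15 <- call_hrde1_repressed(run4$wt, run4$mut, condition_groups()$G15)
  sens <- length(intersect(at23$repressed, planted)) / length(planted)
  expect_gte(sens, 0.9)
  expect_length(intersect(at15$repressed, planted), 0)
})

test_that("the cascade arithmetic reproduces the published worked example", {
  v <- cascade_arithmetic(37, 314, 26, 208, 72)
  expect_equal(v$nhg_count, 288)
  expect_equal(v$mut_wt_ratio, 8.5)
  expect_equal(v$wt_overlap_percent, 70)
  expect_equal(v$unique_23C_count, 136)
})

test_that("the packaged high-stringency NHG table is intact", {
  tab <- load_table1_fixture()
  expect_equal(nrow(tab), 41)
  hit <- table1_lookup("F58H7.5")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$chromosome, "IV")
  expect_match(hit$transposon_note, "CER3")
  # absent gene: empty result, not an error
  none <- table1_lookup("no-such-gene")
  expect_equal(nrow(none), 0)
})
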