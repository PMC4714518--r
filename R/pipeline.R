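#' Load an experiment file tree
#'
#' Reads the directory layout written by [simulate_experiment()] (or an
#' equivalently organised real dataset): count TSVs with metadata
#' sidecars, `genes.tsv`, `ltr.bed`, `chrom_sizes.tsv` and, when present,
#' `truth.json`.
#'
#' @param dir experiment directory.
#' @return List: `counts` (named list of [count_matrix()]), `models`,
#'   `ltr`, `chrom_sizes`, `truth` (parsed JSON or `NULL`).
#' @export
load_experiment <- function(dir) {
  if (!dir.exists(dir)) stop("experiment directory not found: ", dir)
  cs <- read_chrom_sizes(file.path(dir, "chrom_sizes.tsv"))
  models <- read_gene_models(file.path(dir, "genes.tsv"), cs)
  ltr <- read_intervals(file.path(dir, "ltr.bed"), cs)
  count_files <- setdiff(
    list.files(dir, pattern = "\\.tsv$", full.names = TRUE),
    c(file.path(dir, "genes.tsv"), file.path(dir, "chrom_sizes.tsv")))
  count_files <- count_files[!grepl("\\.meta\\.tsv$", count_files)]
  counts <- lapply(count_files, read_counts)
  names(counts) <- tools::file_path_sans_ext(basename(count_files))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path) else NULL
  list(counts = counts, models = models, ltr = ltr, chrom_sizes = cs,
       truth = truth)
}

#' @keywords internal
#' Merge all mRNA count matrices of one genotype (across repeats).
.mrna_by_genotype <- function(exp, genotype) {
  mats <- Filter(function(cm) any(cm$samples$library == "mRNA" &
                                    cm$samples$genotype == genotype),
                 exp$counts)
  if (!length(mats)) stop("no mRNA samples for genotype ", genotype)
  pieces <- lapply(mats, function(cm) {
    subset_samples(cm, cm$samples$library == "mRNA" &
                     cm$samples$genotype == genotype)
  })
  k <- do.call(cbind, lapply(pieces, function(p) p$counts))
  meta <- do.call(rbind, lapply(pieces, function(p) p$samples))
  rownames(meta) <- NULL
  count_matrix(k, meta)
}

#' Run the classification stage on an experiment directory
#'
#' Temperature-sensitive calls per genotype, the HRDE-1-repressed calls
#' per temperature group, and the gene-set cascade. When `out_dir` is
#' given, writes one TSV per named gene set (gene id plus per-repeat fold
#' and q) and a JSON summary with the set sizes and the Venn arithmetic.
#'
#' @param dir experiment directory (see [load_experiment()]), or an
#'   already-loaded experiment list.
#' @param out_dir optional output directory for TSV/JSON results.
#' @param config a [classify_config()].
#' @return The `gene_set_cascade`, with attribute `calls` holding the
#'   per-genotype temperature-sensitive results.
#' @export
run_classification <- function(dir, out_dir = NULL,
                               config = classify_config()) {
  exp <- if (is.character(dir)) load_experiment(dir) else dir
  wt <- .mrna_by_genotype(exp, "WT")
  mut <- .mrna_by_genotype(exp, "hrde1")
  wt_calls <- call_temperature_sensitive(wt, config = config)
  mut_calls <- call_temperature_sensitive(mut, config = config)
  cascade <- build_cascade(wt_calls, mut_calls, wt, mut, config)
  attr(cascade, "calls") <- list(WT = wt_calls, hrde1 = mut_calls)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    set_names <- c("heat_induced_wt", "heat_repressed_wt",
                   "heat_induced_mut", "heat_repressed_mut", "nhg",
                   "high_stringent_nhg", "hrde1_repressed_15C",
                   "hrde1_repressed_23C", "hrde1_repressed_p15C",
                   "hrde1_repressed_23C_unique")
    for (s in set_names) {
      utils::write.table(
        data.frame(gene_id = cascade[[s]]),
        file.path(out_dir, paste0(s, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      c(lapply(stats::setNames(nm = set_names),
               function(s) length(cascade[[s]])),
        list(venn = cascade_arithmetic(
          length(cascade$heat_induced_wt),
          length(cascade$heat_induced_mut),
          length(intersect(cascade$heat_induced_wt,
                           cascade$heat_induced_mut)),
          length(cascade$hrde1_repressed_23C),
          length(cascade$hrde1_repressed_23C) -
            length(cascade$hrde1_repressed_23C_unique)))),
      file.path(out_dir, "cascade_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  cascade
}

#' Run the genomic-association stage
#'
#' Monte Carlo LTR association of a gene set (the gene extents are the
#' query regions) at the standard flanks, the arm/center enrichment, and
#' the X-chromosome depletion test.
#'
#' @param gene_set character vector of gene ids.
#' @param exp loaded experiment (or directory path).
#' @param flanks flank widths in bp (default `c(0, 500, 1000)`).
#' @param n_sims Monte Carlo simulations per flank (default 1e5).
#' @param seed RNG seed.
#' @param x_chrom X-chromosome name.
#' @param out_dir optional output directory for a JSON result.
#' @return List: `ltr` (per-flank `overlap_result`s), `arm_center`,
#'   `x_depletion`.
#' @export
run_association <- function(gene_set, exp, flanks = c(0, 500, 1000),
                            n_sims = 1e5, seed = 1, x_chrom = "chrX",
                            out_dir = NULL) {
  if (is.character(exp) && length(exp) == 1 && dir.exists(exp)) {
    exp <- load_experiment(exp)
  }
  models <- exp$models
  query <- genes_to_granges(models[models$gene_id %in% gene_set, ],
                            exp$chrom_sizes)
  if (!length(query)) stop("gene set shares no gene with the universe")
  ltr_res <- lapply(stats::setNames(nm = paste0("flank_", flanks)), function(f) NULL)
  for (i in seq_along(flanks)) {
    ltr_res[[i]] <- mc_overlap_test(
      query = query, annot = exp$ltr, chrom_sizes = exp$chrom_sizes,
      flank_bp = flanks[i], n_sims = n_sims,
      seed = .derive_seed(seed, paste0("assoc_flank_", flanks[i])))
  }
  ac <- arm_center_enrichment(gene_set, models, exp$chrom_sizes, x_chrom)
  xd <- chrom_depletion_test(intersect(gene_set, models$gene_id), models,
                             x_chrom, n_sims = min(n_sims, 10000),
                             seed = .derive_seed(seed, "assoc_xdep"))
  res <- list(ltr = ltr_res, arm_center = ac, x_depletion = xd)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(
      seed = seed, n_sims = n_sims,
      ltr = lapply(ltr_res, function(r) list(
        f_observed = r$f_observed, p_empirical = r$p_empirical,
        p_text = r$p_text, flank_bp = r$flank_bp)),
      x_depletion = res$x_depletion[c("observed", "expected",
                                      "fold_display", "p_value")]),
      file.path(out_dir, "association.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Run the ChIP trend stage
#'
#' Pol II generation deltas of the later generations against `15C-G3` per
#' genotype with gene-set shift tests, cumulative-trend calls on the
#' mutant mRNA series over the six 23 C generations, and post-stress
#' persistence calls.
#'
#' @param exp loaded experiment (or directory path).
#' @param gene_set gene ids tested for shifts (e.g. the NHG set).
#' @param out_dir optional output directory.
#' @return List: `pol2_shifts` (per generation pair and genotype),
#'   `cumulative` (trend-call table for `gene_set`), `persistent`.
#' @export
run_chip_trends <- function(exp, gene_set, out_dir = NULL) {
  if (is.character(exp) && length(exp) == 1 && dir.exists(exp)) {
    exp <- load_experiment(exp)
  }
  models <- exp$models
  glen <- stats::setNames(models$gene_length, models$gene_id)
  elen <- stats::setNames(models$exon_length, models$gene_id)
  pol2_cm <- Filter(function(cm) any(cm$samples$library == "chip_pol2"),
                    exp$counts)
  if (!length(pol2_cm)) stop("trend stage requires Pol II ChIP counts (chip_pol2)")
  pol2 <- rpkm(pol2_cm[[1]], glen, "gene")
  later <- c("23C-G2", "23C-G4", "23C-G6", "p15C-G1", "p15C-G2")
  shifts <- list()
  for (gt in c("WT", "hrde1")) {
    for (gen in later) {
      d <- generation_delta(pol2, gen, "15C-G3", genotype = gt)
      shifts[[paste(gt, gen, sep = "_")]] <-
        c(list(genotype = gt, generation = gen),
          set_shift_test(d, gene_set))
    }
  }
  # cumulative/persistent calls on the mutant mRNA series (repeat 1)
  mrna_mut <- subset_samples(.mrna_by_genotype(exp, "hrde1"),
                             .mrna_by_genotype(exp, "hrde1")$samples$repeat_id == 1)
  expr <- rpkm(mrna_mut, elen, "exon")
  gens23 <- paste0("23C-G", 1:6)
  series23 <- vapply(gens23, function(g)
    rowMeans(expr$values[, expr$samples$generation == g, drop = FALSE]),
    numeric(nrow(expr$values)))
  baseline <- rowMeans(
    expr$values[, expr$samples$generation %in% condition_groups()$G15,
                drop = FALSE])
  gensp <- paste0("p15C-G", 1:3)
  seriesp <- vapply(gensp, function(g)
    rowMeans(expr$values[, expr$samples$generation == g, drop = FALSE]),
    numeric(nrow(expr$values)))
  keep <- rownames(series23) %in% gene_set
  cum <- call_cumulative(series23[keep, , drop = FALSE])
  persist <- call_persistent(seriesp[keep, , drop = FALSE], baseline[keep])
  res <- list(pol2_shifts = shifts, cumulative = cum, persistent = persist)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(lapply(shifts, function(s)
      s[c("genotype", "generation", "median_set", "median_background",
          "p_value")]),
      file.path(out_dir, "pol2_shifts.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(cum, file.path(out_dir, "cumulative_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Run the siRNA phase stage
#'
#' Phase means per genotype, mutant-vs-WT siRNA calls per phase, the
#' down-call retention fractions, and (when a cascade is supplied) the
#' cross-tabulation of reduced-siRNA genes against HRDE-1-repressed genes.
#'
#' @param exp loaded experiment (or directory path).
#' @param cascade optional `gene_set_cascade` for the mRNA cross-tab.
#' @param config a [classify_config()].
#' @param out_dir optional output directory.
#' @return List: `means` (per genotype), `calls` (per phase),
#'   `retention`, `crosstab` (or `NULL`).
#' @export
run_sirna_phases <- function(exp, cascade = NULL,
                             config = classify_config(), out_dir = NULL) {
  if (is.character(exp) && length(exp) == 1 && dir.exists(exp)) {
    exp <- load_experiment(exp)
  }
  srna <- Filter(function(cm) any(cm$samples$library == "sRNA"), exp$counts)
  if (!length(srna)) stop("siRNA stage requires antisense sRNA counts")
  srna <- srna[[1]]
  wt <- subset_samples(srna, srna$samples$genotype == "WT")
  mut <- subset_samples(srna, srna$samples$genotype == "hrde1")
  means <- list(WT = phase_means(wt), hrde1 = phase_means(mut))
  calls <- call_sirna_changes(wt, mut, phase = NULL, config = config)
  ret <- sirna_retention(calls)
  ct <- NULL
  if (!is.null(cascade)) {
    universe <- rownames(srna$counts)
    ct <- list(
      at_15C = crosstab_sirna_mrna(calls$I$down_in_mutant,
                                   cascade$hrde1_repressed_15C, universe),
      at_23C = crosstab_sirna_mrna(calls$III$down_in_mutant,
                                   cascade$hrde1_repressed_23C, universe))
  }
  res <- list(means = means, calls = calls, retention = ret, crosstab = ct)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (ph in names(calls)) {
      utils::write.table(calls[[ph]]$table,
                         file.path(out_dir, paste0("sirna_phase_", ph, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(list(
      up_per_phase = lapply(calls, function(x) length(x$up_in_mutant)),
      down_per_phase = lapply(calls, function(x) length(x$down_in_mutant)),
      retention = ret),
      file.path(out_dir, "sirna_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Assemble the pipeline report
#'
#' Collects the headline quantities of the completed stages into one
#' summary: set sizes and Venn arithmetic of the cascade, LTR association
#' fractions and p-values, Pol II shift medians, cumulative/persistent
#' counts, and siRNA call counts per phase. Stages not supplied are
#' reported as `"missing"` rather than failing.
#'
#' @param classification a `gene_set_cascade`, or `NULL`.
#' @param association result of [run_association()], or `NULL`.
#' @param trends result of [run_chip_trends()], or `NULL`.
#' @param sirna result of [run_sirna_phases()], or `NULL`.
#' @param out_path optional JSON output path.
#' @return The report list.
#' @export
pipeline_report <- function(classification = NULL, association = NULL,
                            trends = NULL, sirna = NULL, out_path = NULL) {
  rep <- list()
  rep$classification <- if (is.null(classification)) "missing" else {
    ov <- length(intersect(classification$heat_induced_wt,
                           classification$heat_induced_mut))
    c(list(
      heat_induced_wt = length(classification$heat_induced_wt),
      heat_induced_mut = length(classification$heat_induced_mut),
      overlap = ov,
      nhg = length(classification$nhg),
      high_stringent_nhg = length(classification$high_stringent_nhg),
      hrde1_repressed_23C = length(classification$hrde1_repressed_23C),
      hrde1_repressed_23C_unique =
        length(classification$hrde1_repressed_23C_unique)),
      cascade_arithmetic(
        length(classification$heat_induced_wt),
        length(classification$heat_induced_mut), ov,
        length(classification$hrde1_repressed_23C),
        length(classification$hrde1_repressed_23C) -
          length(classification$hrde1_repressed_23C_unique)))
  }
  rep$association <- if (is.null(association)) "missing" else list(
    ltr = lapply(association$ltr, function(r)
      list(flank_bp = r$flank_bp, f_observed = r$f_observed,
           p = r$p_text)),
    x_depletion = association$x_depletion[c("observed", "expected",
                                            "fold_display", "p_value")])
  rep$trends <- if (is.null(trends)) "missing" else list(
    n_cumulative = sum(trends$cumulative$cumulative),
    n_persistent_g1 = if (ncol(trends$persistent)) sum(trends$persistent[, 1]) else 0,
    pol2_shifts = lapply(trends$pol2_shifts, function(s)
      s[c("genotype", "generation", "median_set", "median_background",
          "p_value")]))
  rep$sirna <- if (is.null(sirna)) "missing" else list(
    up_per_phase = lapply(sirna$calls, function(x) length(x$up_in_mutant)),
    down_per_phase = lapply(sirna$calls, function(x) length(x$down_in_mutant)))
  if (!is.null(out_path)) {
    jsonlite::write_json(rep, out_path, auto_unbox = TRUE, digits = NA)
  }
  rep
}
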