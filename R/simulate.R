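#' Configuration of the synthetic multigenerational experiment
#'
#' Defaults emulate the magnitudes of the real study design: 2000 genes on
#' six chromosomes (one X), an 8-fold heat induction for planted
#' heat-responsive classes (the observed median mutant induction of the
#' high-stringency class), a 1.5x per-generation cumulative factor, a 0.5x
#' per-generation post-stress decay, LTR annotation covering ~0.4% of the
#' genome with 35% of nuclear-RNAi-target genes placed in or near LTRs,
#' and negative-binomial counts (variance = mu + alpha mu^2, alpha = 0.1)
#' over log-normal baseline expression.
#'
#' The plain (non-high-stringency) NHG class is planted with a mutant
#' baseline of `1/hrde1_fold` and a small (1.4x) WT 23 C drift so that the
#' mutant is heat-induced while mutant/WT at 23 C stays below 2 — keeping
#' plain and high-stringency NHGs separable, as in the real cascade.
#'
#' @param n_genes number of genes.
#' @param chrom_sizes named chromosome lengths (one name containing "X").
#' @param class_props named class proportions (remainder is `null`).
#' @param heat_fold planted heat induction (default 8).
#' @param hrde1_fold planted HRDE-1 repression magnitude (default 4).
#' @param cumulative_factor per-23 C-generation growth of the cumulative
#'   class (default 1.5).
#' @param persistence_decay per-post-stress-generation decay (default 0.5).
#' @param sirna_fold planted siRNA loss/gain magnitude (default 5).
#' @param baseline_meanlog,baseline_sdlog log-normal mRNA baseline.
#' @param sirna_meanlog,sirna_sdlog log-normal antisense-siRNA baseline.
#' @param alpha NB dispersion (default 0.1).
#' @param depth_range uniform range of per-sample depth factors.
#' @param gene_length_range uniform range of gene lengths in bp (mean
#'   2920, the mean NHG size used as the Monte Carlo region length).
#' @param ltr_fraction target LTR fraction of the genome (default 0.004).
#' @param ltr_linkage fraction of NHG-family genes planted in/near an LTR.
#' @param seed master seed; each output stream derives its own sub-seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       chrom_sizes = c(chrI = 1700000, chrII = 1700000,
                                       chrIII = 1700000, chrIV = 1700000,
                                       chrV = 1700000, chrX = 1500000),
                       class_props = c(wt_heat_induced = 0.015,
                                       heat_repressed = 0.010,
                                       nhg_plain = 0.050,
                                       high_stringent_nhg = 0.020,
                                       cumulative_nhg = 0.003,
                                       sirna_loss = 0.025,
                                       sirna_gain = 0.025),
                       heat_fold = 8, hrde1_fold = 4,
                       cumulative_factor = 1.5, persistence_decay = 0.5,
                       sirna_fold = 5,
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       sirna_meanlog = log(60), sirna_sdlog = 1,
                       alpha = 0.1,
                       depth_range = c(0.8, 1.2),
                       gene_length_range = c(1000, 4840),
                       ltr_fraction = 0.004, ltr_linkage = 0.35,
                       seed = 7) {
  stopifnot(sum(class_props) <= 1, heat_fold > 0, hrde1_fold > 0,
            cumulative_factor > 0, persistence_decay > 0, alpha >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' @keywords internal
#' Derive a per-stream seed from the master seed and a role string, so that
#' adding an output stream never perturbs the others. Kept below 2^31.
.derive_seed <- function(seed, role) {
  h <- 0
  for (ch in utf8ToInt(role)) h <- (h * 131 + ch) %% 2147483629
  as.integer(((seed %% 2147483629) * 48271 + h) %% 2147483629) + 1L
}

#' Simulate the genome: genes, classes and LTR annotation
#'
#' Places genes sequentially per chromosome with random exponential gaps,
#' assigns each gene a planted class (siRNA-gain genes are restricted to
#' autosomes, mirroring the observed X depletion), draws per-gene baseline
#' expression, and lays down LTR intervals: a fraction `ltr_linkage` of
#' NHG-family genes receive an LTR inside the gene body, and the remaining
#' LTR budget (up to `ltr_fraction` of the genome) is placed uniformly.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_truth`: `chrom_sizes`, `models` (gene-model
#'   data.frame), `ltr` (`GRanges`), `classes` (named per-gene labels),
#'   `baseline`, `sirna_baseline`, `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, "genome"))
  cs <- config$chrom_sizes
  n <- config$n_genes
  n_per <- floor(n * cs / sum(cs))
  rem <- n - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1L

  models <- list()
  for (cn in names(cs)) {
    nc <- n_per[[cn]]
    if (nc == 0) next
    len <- round(stats::runif(nc, config$gene_length_range[1],
                              config$gene_length_range[2]))
    if (sum(len) > 0.95 * cs[[cn]]) {
      stop("overcrowded genome: genes do not fit on ", cn)
    }
    slack <- cs[[cn]] - sum(len)
    gaps <- stats::rexp(nc + 1)
    gaps <- floor(gaps / sum(gaps) * slack)
    starts <- cumsum(c(gaps[1], len[-nc] + gaps[2:nc]))
    models[[cn]] <- data.frame(
      gene_id = sprintf("%s_g%04d", sub("^chr", "", cn), seq_len(nc)),
      chrom = cn, start = starts, end = starts + len,
      strand = sample(c("+", "-"), nc, replace = TRUE),
      gene_length = len, exon_length = round(0.8 * len),
      stringsAsFactors = FALSE)
  }
  models <- do.call(rbind, models)
  rownames(models) <- NULL
  models <- validate_gene_models(models, cs)

  # planted classes; siRNA-gain genes kept off the X chromosome
  x_chrom <- grep("X", names(cs), value = TRUE)[1]
  classes <- rep("null", nrow(models))
  names(classes) <- models$gene_id
  counts_per_class <- round(config$class_props * nrow(models))
  pool <- models$gene_id
  for (cl in names(counts_per_class)) {
    eligible <- if (cl == "sirna_gain") {
      intersect(pool, models$gene_id[models$chrom != x_chrom])
    } else pool
    chosen <- sample(eligible, min(counts_per_class[[cl]], length(eligible)))
    classes[chosen] <- cl
    pool <- setdiff(pool, chosen)
  }

  baseline <- stats::setNames(
    stats::rlnorm(nrow(models), config$baseline_meanlog, config$baseline_sdlog),
    models$gene_id)
  sirna_baseline <- stats::setNames(
    stats::rlnorm(nrow(models), config$sirna_meanlog, config$sirna_sdlog),
    models$gene_id)

  # LTR annotation: linked intervals inside NHG-family genes, then a
  # uniform background up to the genome-fraction budget
  nhg_family <- names(classes)[classes %in%
    c("nhg_plain", "high_stringent_nhg", "cumulative_nhg")]
  n_linked <- round(config$ltr_linkage * length(nhg_family))
  linked <- if (n_linked > 0) sample(nhg_family, n_linked) else character(0)
  ltr_chrom <- character(0); ltr_start <- integer(0); ltr_end <- integer(0)
  for (g in linked) {
    row <- models[models$gene_id == g, ]
    ll <- round(stats::runif(1, 200, 600))
    off <- floor(stats::runif(1, 0, max(1, row$gene_length - ll)))
    ltr_chrom <- c(ltr_chrom, row$chrom)
    ltr_start <- c(ltr_start, row$start + off)
    ltr_end <- c(ltr_end, min(row$start + off + ll, row$end))
  }
  budget <- config$ltr_fraction * sum(cs) - sum(ltr_end - ltr_start)
  while (budget > 200) {
    ll <- round(stats::runif(1, 200, 600))
    cn <- sample(names(cs), 1, prob = cs / sum(cs))
    s <- floor(stats::runif(1, 0, cs[[cn]] - ll))
    ltr_chrom <- c(ltr_chrom, cn)
    ltr_start <- c(ltr_start, s)
    ltr_end <- c(ltr_end, s + ll)
    budget <- budget - ll
  }
  ltr <- GenomicRanges::GRanges(
    seqnames = ltr_chrom,
    ranges = IRanges::IRanges(start = ltr_start + 1L, end = ltr_end),
    name = sprintf("LTR_%03d", seq_along(ltr_chrom)))
  GenomeInfoDb::seqlevels(ltr) <- names(cs)
  GenomeInfoDb::seqlengths(ltr) <- unname(cs)

  structure(list(chrom_sizes = cs, models = models, ltr = ltr,
                 classes = classes, baseline = baseline,
                 sirna_baseline = sirna_baseline,
                 linked_ltr_genes = linked, config = config),
            class = "sim_truth")
}

#' @keywords internal
#' Per-class expected expression multiplier over the 12 generations.
#' Returns a genotypes x generations x ... numeric matrix (2 x 12) for one
#' class and one library type.
.class_multipliers <- function(class, config, library) {
  gens <- generation_levels()
  at23 <- grepl("^23C", gens)
  atp15 <- grepl("^p15C", gens)
  wt <- rep(1, 12); mut <- rep(1, 12)
  hf <- config$heat_fold
  if (library %in% c("mRNA", "chip_pol2")) {
    if (class == "wt_heat_induced") {
      wt[at23] <- hf; mut[at23] <- hf
    } else if (class == "heat_repressed") {
      wt[at23] <- 1 / hf; mut[at23] <- 1 / hf
    } else if (class == "nhg_plain") {
      wt[at23] <- 1.4
      mut <- mut / config$hrde1_fold
      mut[at23] <- mut[at23] * hf
    } else if (class == "high_stringent_nhg") {
      mut[at23] <- hf
    } else if (class == "cumulative_nhg") {
      k <- seq_len(6)
      mut[at23] <- 2 * config$cumulative_factor^(k - 1)
      g6 <- mut[which(at23)[6]]
      mut[atp15] <- g6 * config$persistence_decay^seq_len(3)
    }
  } else if (library == "sRNA") {
    sif <- config$sirna_fold
    phase234 <- at23 | atp15   # phases II-IV
    if (class == "sirna_loss") {
      mut[phase234] <- 1 / sif
    } else if (class == "sirna_gain") {
      mut[phase234] <- sif
    } else if (class %in% c("nhg_plain", "high_stringent_nhg", "cumulative_nhg")) {
      wt[at23] <- 1.5
      mut[phase234] <- 0.5
    }
  } else if (library == "chip_h3k9me3") {
    if (class %in% c("nhg_plain", "high_stringent_nhg", "cumulative_nhg")) {
      wt <- wt * 4; mut <- mut * 4
      wt[at23] <- wt[at23] * 0.7
      mut[at23] <- mut[at23] * 0.7 * 0.7
      mut[atp15] <- mut[atp15] * 0.7
    }
  }
  rbind(WT = wt, hrde1 = mut)
}

#' Expected mean matrix for one library/repeat
#'
#' The per-gene per-sample expected counts (before depth factors) implied
#' by the planted classes — every generated count's expectation is
#' reconstructible from the truth via this function.
#'
#' @param truth a `sim_truth` (see [simulate_genome()]).
#' @param library library type (`mRNA`, `sRNA`, `chip_pol2`,
#'   `chip_h3k9me3`).
#' @return Numeric matrix genes x (2 genotypes * 12 generations); columns
#'   named `<genotype>_<generation>`.
#' @export
expected_means <- function(truth, library) {
  base <- if (library == "sRNA") truth$sirna_baseline else truth$baseline
  gens <- generation_levels()
  cols <- as.vector(outer(c("WT", "hrde1"), gens, paste, sep = "_"))
  mu <- matrix(0, length(base), length(cols),
               dimnames = list(names(base), cols))
  for (cl in unique(truth$classes)) {
    m <- .class_multipliers(cl, truth$config, library)
    sel <- truth$classes == cl
    for (gt in c("WT", "hrde1")) {
      mu[sel, paste(gt, gens, sep = "_")] <-
        outer(base[sel], m[gt, ], "*")
    }
  }
  mu
}

#' Simulate counts for every library of the design
#'
#' Draws NB counts (variance = mu + alpha mu^2) around the expected means
#' of [expected_means()], scaled by per-sample depth factors: two mRNA
#' repeats, one antisense-siRNA repeat, one Pol II and one H3K9me3 ChIP
#' repeat, each covering 12 generations x 2 genotypes. Each output stream
#' uses its own derived RNG seed, so outputs are individually reproducible.
#'
#' @param config a [sim_config()].
#' @param truth the matching `sim_truth`; simulated if omitted.
#' @return Named list of [count_matrix()] objects: `mRNA_rep1`,
#'   `mRNA_rep2`, `sRNA_rep1`, `chip_pol2_rep1`, `chip_h3k9me3_rep1`.
#' @export
simulate_counts <- function(config = sim_config(), truth = NULL) {
  if (is.null(truth)) truth <- simulate_genome(config)
  if (!identical(truth$config$seed, config$seed) ||
      !identical(truth$config$n_genes, config$n_genes)) {
    stop("config does not match the one inside truth")
  }
  gens <- generation_levels()
  specs <- list(
    mRNA_rep1 = list(library = "mRNA", repeat_id = 1L),
    mRNA_rep2 = list(library = "mRNA", repeat_id = 2L),
    sRNA_rep1 = list(library = "sRNA", repeat_id = 1L),
    chip_pol2_rep1 = list(library = "chip_pol2", repeat_id = 1L),
    chip_h3k9me3_rep1 = list(library = "chip_h3k9me3", repeat_id = 1L))
  out <- list()
  for (role in names(specs)) {
    sp <- specs[[role]]
    set.seed(.derive_seed(config$seed, role))
    mu <- expected_means(truth, sp$library)
    n_samp <- ncol(mu)
    depth <- stats::runif(n_samp, config$depth_range[1], config$depth_range[2])
    mu_d <- sweep(mu, 2, depth, "*")
    k <- matrix(
      stats::rnbinom(length(mu_d), mu = mu_d,
                     size = 1 / max(config$alpha, 1e-12)),
      nrow = nrow(mu_d), dimnames = dimnames(mu_d))
    meta <- data.frame(
      sample_id = paste0(colnames(mu), "_", sp$library, "_r", sp$repeat_id),
      genotype = rep(c("WT", "hrde1"), times = length(gens)),
      generation = rep(gens, each = 2),
      repeat_id = sp$repeat_id, library = sp$library,
      stringsAsFactors = FALSE)
    colnames(k) <- meta$sample_id
    out[[role]] <- count_matrix(k, meta)
  }
  out
}

#' Ground-truth gene sets implied by the planted classes
#'
#' @param truth a `sim_truth`.
#' @return List of character vectors: `heat_induced_wt`,
#'   `heat_induced_mut`, `heat_repressed`, `nhg`, `high_stringent_nhg`,
#'   `cumulative_nhg`, `sirna_loss`, `sirna_gain`, `null_genes`.
#' @export
truth_sets <- function(truth) {
  cl <- truth$classes
  nm <- names(cl)
  list(
    heat_induced_wt = nm[cl == "wt_heat_induced"],
    heat_induced_mut = nm[cl %in% c("wt_heat_induced", "nhg_plain",
                                    "high_stringent_nhg", "cumulative_nhg")],
    heat_repressed = nm[cl == "heat_repressed"],
    nhg = nm[cl %in% c("nhg_plain", "high_stringent_nhg", "cumulative_nhg")],
    high_stringent_nhg = nm[cl %in% c("high_stringent_nhg", "cumulative_nhg")],
    cumulative_nhg = nm[cl == "cumulative_nhg"],
    sirna_loss = nm[cl == "sirna_loss"],
    sirna_gain = nm[cl == "sirna_gain"],
    null_genes = nm[cl == "null"])
}

#' Write a complete synthetic experiment to disk
#'
#' Emits exactly the formats the readers consume: five count TSVs with
#' metadata sidecars, the gene-model TSV, the LTR BED, the
#' chromosome-sizes TSV, and a ground-truth JSON (classes, planted
#' parameters, linked LTR genes).
#'
#' @param dir output directory.
#' @param config a [sim_config()].
#' @param force overwrite a non-empty directory.
#' @return Invisibly, a list with `truth`, `counts` and the file `paths`.
#' @export
simulate_experiment <- function(dir, config = sim_config(), force = FALSE) {
  if (!dir.exists(dirname(dir))) stop("parent directory missing: ", dirname(dir))
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    stop("output directory not empty (use force = TRUE): ", dir)
  }
  dir.create(dir, showWarnings = FALSE, recursive = FALSE)
  truth <- simulate_genome(config)
  counts <- simulate_counts(config, truth)
  paths <- character(0)
  for (role in names(counts)) {
    p <- file.path(dir, paste0(role, ".tsv"))
    write_counts(counts[[role]], p)
    paths <- c(paths, p)
  }
  gp <- file.path(dir, "genes.tsv")
  utils::write.table(truth$models, gp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bp <- file.path(dir, "ltr.bed")
  write_intervals(truth$ltr, bp)
  cp <- file.path(dir, "chrom_sizes.tsv")
  utils::write.table(
    data.frame(names(truth$chrom_sizes), unname(truth$chrom_sizes)),
    cp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  tp <- file.path(dir, "truth.json")
  cfg <- truth$config
  jsonlite::write_json(list(
    seed = cfg$seed,
    classes = as.list(truth$classes),
    linked_ltr_genes = truth$linked_ltr_genes,
    params = list(heat_fold = cfg$heat_fold, hrde1_fold = cfg$hrde1_fold,
                  cumulative_factor = cfg$cumulative_factor,
                  persistence_decay = cfg$persistence_decay,
                  sirna_fold = cfg$sirna_fold, alpha = cfg$alpha,
                  ltr_fraction = cfg$ltr_fraction,
                  ltr_linkage = cfg$ltr_linkage)
  ), tp, auto_unbox = TRUE, digits = NA)
  invisible(list(truth = truth, counts = counts,
                 paths = c(paths, gp, bp, cp, tp)))
}
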