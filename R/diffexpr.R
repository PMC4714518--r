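#' Differential-calling configuration
#'
#' Thresholds for all fold/FDR-based calls: a minimal fold change of 2 and
#' FDR <= 0.1, required in both biological repeats. "Both repeats" is
#' implemented as independent per-repeat differential runs whose
#' significant sets are intersected; a pooled mode treating all repeats as
#' replicates of one run is available but not the default.
#'
#' @param fold_cutoff minimal fold change (> 1), default 2.
#' @param fdr_cutoff FDR threshold in (0, 1), default 0.1.
#' @param require_both_repeats intersect per-repeat calls (default `TRUE`).
#' @param mode `"intersect"` (per-repeat runs intersected) or `"pooled"`.
#' @param pseudocount added to both normalized means when either is zero,
#'   so fold changes stay finite; raw means are reported alongside.
#' @return List of class `classify_config`.
#' @export
classify_config <- function(fold_cutoff = 2, fdr_cutoff = 0.1,
                            require_both_repeats = TRUE,
                            mode = c("intersect", "pooled"),
                            pseudocount = 0.5) {
  stopifnot(fold_cutoff > 1, fdr_cutoff > 0, fdr_cutoff < 1)
  structure(list(fold_cutoff = fold_cutoff, fdr_cutoff = fdr_cutoff,
                 require_both_repeats = isTRUE(require_both_repeats),
                 mode = match.arg(mode), pseudocount = pseudocount),
            class = "classify_config")
}

#' Two-group negative-binomial differential comparison
#'
#' The work-horse underlying every fold/FDR call: median-of-ratios size
#' factors over the pooled samples, method-of-moments dispersion with the
#' two groups as conditions, per-gene conditional NB exact test on group
#' count sums, and BH-FDR correction. Fold change is `mean_B / mean_A` of
#' size-factor-normalized means, with `pseudocount` added to both means
#' only when either is zero.
#'
#' @param counts a [count_matrix()] (or plain matrix) holding both groups.
#' @param group_a,group_b sample ids (or column indices) of the two groups;
#'   each needs >= 2 samples.
#' @param config a [classify_config()].
#' @return data.frame: `gene_id`, `mean_a`, `mean_b` (normalized means),
#'   `fold_change` (B over A), `p_value`, `q_value`.
#' @export
de_compare <- function(counts, group_a, group_b, config = classify_config()) {
  k <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  ia <- if (is.character(group_a)) match(group_a, colnames(k)) else group_a
  ib <- if (is.character(group_b)) match(group_b, colnames(k)) else group_b
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample id in group")
  if (length(ia) < 2 || length(ib) < 2) stop("each group needs >= 2 samples")
  sub <- k[, c(ia, ib), drop = FALSE]
  sf <- size_factors(sub)
  na <- length(ia)
  groups <- list(a = seq_len(na), b = na + seq_along(ib))
  disp <- estimate_dispersion(sub, sf, groups)
  norm <- sweep(sub, 2, sf, "/")
  mean_a <- rowMeans(norm[, groups$a, drop = FALSE])
  mean_b <- rowMeans(norm[, groups$b, drop = FALSE])
  ka <- rowSums(sub[, groups$a, drop = FALSE])
  kb <- rowSums(sub[, groups$b, drop = FALSE])
  sfa <- sf[groups$a]; sfb <- sf[groups$b]
  alpha <- disp$alpha
  p <- vapply(seq_len(nrow(sub)), function(i) {
    nb_exact_test(ka[i], kb[i], sfa, sfb, alpha[i])
  }, 0)
  pc <- ifelse(mean_a == 0 | mean_b == 0, config$pseudocount, 0)
  fold <- (mean_b + pc) / (mean_a + pc)
  data.frame(gene_id = rownames(sub), mean_a = mean_a, mean_b = mean_b,
             fold_change = fold, p_value = p, q_value = bh_fdr(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @keywords internal
#' Join two sample subsets (possibly from the same matrix) into one
#' count_matrix with guaranteed-unique sample ids; returns the joint matrix
#' and the renamed group ids.
.join_counts <- function(counts_a, ids_a, counts_b, ids_b) {
  ka <- counts_a$counts[, ids_a, drop = FALSE]
  kb <- counts_b$counts[, ids_b, drop = FALSE]
  ma <- counts_a$samples[match(ids_a, counts_a$samples$sample_id), , drop = FALSE]
  mb <- counts_b$samples[match(ids_b, counts_b$samples$sample_id), , drop = FALSE]
  new_a <- paste0("A.", ids_a); new_b <- paste0("B.", ids_b)
  colnames(ka) <- new_a; colnames(kb) <- new_b
  ma$sample_id <- new_a; mb$sample_id <- new_b
  list(joint = count_matrix(cbind(ka, kb), rbind(ma, mb)),
       a = new_a, b = new_b)
}

#' @keywords internal
.select_samples <- function(counts, genotype = NULL, repeat_id = NULL,
                            generations = NULL, library = NULL) {
  m <- counts$samples
  keep <- rep(TRUE, nrow(m))
  if (!is.null(genotype)) keep <- keep & m$genotype %in% genotype
  if (!is.null(repeat_id)) keep <- keep & m$repeat_id %in% repeat_id
  if (!is.null(generations)) keep <- keep & m$generation %in% generations
  if (!is.null(library)) keep <- keep & m$library %in% library
  m$sample_id[keep]
}

#' Call temperature-sensitive genes for one genotype
#'
#' Per biological repeat, compares mean mRNA expression between the 15 C
#' group and the 23 C group (see [condition_groups()]; `23C-G1` and the
#' post-stress generations are excluded). Heat-induced genes show a fold
#' increase >= `fold_cutoff` at FDR <= `fdr_cutoff`; heat-repressed genes a
#' fold decrease <= 1/`fold_cutoff`. With `require_both_repeats` the
#' per-repeat significant sets are intersected.
#'
#' @param counts [count_matrix()] of mRNA samples for one genotype
#'   (one or two repeats).
#' @param grouping generation groups, default [condition_groups()].
#' @param config a [classify_config()].
#' @return List: `per_repeat` (named list of per-repeat `de_compare`
#'   tables, 15 C as group A), `heat_induced`, `heat_repressed`
#'   (character vectors of gene ids).
#' @export
call_temperature_sensitive <- function(counts, grouping = condition_groups(),
                                       config = classify_config()) {
  stopifnot(inherits(counts, "count_matrix"))
  reps <- sort(unique(counts$samples$repeat_id))
  missing_gen <- setdiff(c(grouping$G15, grouping$G23),
                         unique(counts$samples$generation))
  if (length(missing_gen)) {
    stop("missing generation sample(s): ", paste(missing_gen, collapse = ", "))
  }
  if (config$mode == "pooled") reps <- list(reps)
  per_repeat <- lapply(reps, function(r) {
    a <- .select_samples(counts, repeat_id = r, generations = grouping$G15)
    b <- .select_samples(counts, repeat_id = r, generations = grouping$G23)
    de_compare(counts, a, b, config)
  })
  names(per_repeat) <- vapply(reps, function(r)
    paste0("repeat", paste(r, collapse = "+")), "")
  induced <- lapply(per_repeat, function(d)
    d$gene_id[d$fold_change >= config$fold_cutoff & d$q_value <= config$fdr_cutoff])
  repressed <- lapply(per_repeat, function(d)
    d$gene_id[d$fold_change <= 1 / config$fold_cutoff & d$q_value <= config$fdr_cutoff])
  combine <- function(sets) {
    if (config$require_both_repeats && length(sets) > 1) {
      Reduce(intersect, sets)
    } else {
      Reduce(union, sets)
    }
  }
  list(per_repeat = per_repeat,
       heat_induced = combine(induced),
       heat_repressed = combine(repressed))
}

#' Call HRDE-1-repressed genes within a temperature group
#'
#' Genes with mutant/WT fold >= `fold_cutoff` at FDR <= `fdr_cutoff` within
#' the given generation group, i.e. genes the nuclear RNAi pathway
#' represses at that temperature. Per-repeat runs are intersected under
#' `require_both_repeats` when both repeats are present in both genotypes.
#'
#' @param counts_wt,counts_mut mRNA [count_matrix()] objects for WT and
#'   mutant; identical gene universes.
#' @param group character vector of generation labels (one entry of
#'   [condition_groups()]).
#' @param config a [classify_config()].
#' @return List: `per_repeat` tables (WT as group A) and `repressed`
#'   (gene ids).
#' @export
call_hrde1_repressed <- function(counts_wt, counts_mut, group,
                                 config = classify_config()) {
  if (!identical(rownames(counts_wt$counts), rownames(counts_mut$counts))) {
    stop("gene universes differ between genotypes")
  }
  reps <- intersect(unique(counts_wt$samples$repeat_id),
                    unique(counts_mut$samples$repeat_id))
  if (!length(reps)) stop("no shared biological repeat between genotypes")
  per_repeat <- lapply(reps, function(r) {
    a <- .select_samples(counts_wt, repeat_id = r, generations = group)
    b <- .select_samples(counts_mut, repeat_id = r, generations = group)
    if (length(a) < 2 || length(b) < 2) {
      stop("group needs >= 2 samples per genotype (repeat ", r, ")")
    }
    j <- .join_counts(counts_wt, a, counts_mut, b)
    de_compare(j$joint, j$a, j$b, config)
  })
  names(per_repeat) <- paste0("repeat", reps)
  sets <- lapply(per_repeat, function(d)
    d$gene_id[d$fold_change >= config$fold_cutoff & d$q_value <= config$fdr_cutoff])
  repressed <- if (config$require_both_repeats && length(sets) > 1) {
    Reduce(intersect, sets)
  } else {
    Reduce(union, sets)
  }
  list(per_repeat = per_repeat, repressed = repressed)
}

#' Build the gene-set cascade
#'
#' Derives the named gene sets from the temperature-sensitive and
#' genotype-comparison calls:
#' * `nhg` — nuclear RNAi-repressed heat-inducible genes: heat-induced in
#'   the mutant but not in WT;
#' * `high_stringent_nhg` — NHGs with at least `fold_cutoff`-fold
#'   HRDE-1-dependent repression (mutant/WT at 23 C) in both repeats
#'   (FDR additionally required unless `require_fdr = FALSE`);
#' * `hrde1_repressed_15C` / `_23C` / `_p15C` — per-temperature
#'   mutant-over-WT calls, and `hrde1_repressed_23C_unique`, the 23 C calls
#'   not repressed at either 15 C condition.
#'
#' @param wt_calls,mut_calls results of [call_temperature_sensitive()] for
#'   WT and mutant.
#' @param counts_wt,counts_mut the mRNA [count_matrix()] objects.
#' @param config a [classify_config()].
#' @param grouping generation groups, default [condition_groups()].
#' @param require_fdr also require FDR <= `fdr_cutoff` in the
#'   high-stringency filter (default `TRUE`).
#' @return List of class `gene_set_cascade` with the named sets and
#'   `hrde1_per_group` detail tables.
#' @export
build_cascade <- function(wt_calls, mut_calls, counts_wt, counts_mut,
                          config = classify_config(),
                          grouping = condition_groups(),
                          require_fdr = TRUE) {
  if (!identical(rownames(counts_wt$counts), rownames(counts_mut$counts))) {
    stop("gene universes differ between genotypes")
  }
  nhg <- setdiff(mut_calls$heat_induced, wt_calls$heat_induced)

  hrde1 <- lapply(stats::setNames(nm = names(grouping)), function(gname) {
    call_hrde1_repressed(counts_wt, counts_mut, grouping[[gname]], config)
  })

  # high-stringency filter: mutant/WT repression at 23 C in every repeat
  hs <- nhg
  for (tab in hrde1$G23$per_repeat) {
    ok <- tab$fold_change >= config$fold_cutoff
    if (require_fdr) ok <- ok & tab$q_value <= config$fdr_cutoff
    hs <- intersect(hs, tab$gene_id[ok])
  }

  r23 <- hrde1$G23$repressed
  r15 <- hrde1$G15$repressed
  rp15 <- hrde1$Gp15$repressed
  structure(list(
    heat_induced_wt = wt_calls$heat_induced,
    heat_repressed_wt = wt_calls$heat_repressed,
    heat_induced_mut = mut_calls$heat_induced,
    heat_repressed_mut = mut_calls$heat_repressed,
    nhg = nhg,
    high_stringent_nhg = hs,
    hrde1_repressed_15C = r15,
    hrde1_repressed_23C = r23,
    hrde1_repressed_p15C = rp15,
    hrde1_repressed_23C_unique = setdiff(r23, union(r15, rp15)),
    hrde1_per_group = hrde1
  ), class = "gene_set_cascade")
}

#' @export
print.gene_set_cascade <- function(x, ...) {
  sets <- c("heat_induced_wt", "heat_repressed_wt", "heat_induced_mut",
            "heat_repressed_mut", "nhg", "high_stringent_nhg",
            "hrde1_repressed_15C", "hrde1_repressed_23C",
            "hrde1_repressed_p15C", "hrde1_repressed_23C_unique")
  cat("gene_set_cascade:\n")
  for (s in sets) cat(sprintf("  %-28s %d genes\n", s, length(x[[s]])))
  invisible(x)
}

#' Venn arithmetic on heat-induced and HRDE-1-repressed set sizes
#'
#' The headline arithmetic of the cascade, computed from set sizes: the NHG
#' count (mutant heat-induced minus the WT overlap), the mutant/WT
#' heat-induced ratio, the percentage of WT heat-induced genes recovered in
#' the mutant, and the count of 23 C HRDE-1-repressed genes unique to 23 C.
#'
#' @param n_heat_induced_wt,n_heat_induced_mut heat-induced set sizes.
#' @param n_overlap size of their intersection.
#' @param n_hrde1_23C size of the 23 C HRDE-1-repressed set.
#' @param n_hrde1_23C_shared how many of those are also repressed at 15 C
#'   or post-stress 15 C.
#' @return List: `nhg_count`, `mut_wt_ratio` (1 d.p.),
#'   `wt_overlap_percent`, `unique_23C_count`.
#' @examples
#' cascade_arithmetic(37, 314, 26, 208, 72)
#' @export
cascade_arithmetic <- function(n_heat_induced_wt, n_heat_induced_mut,
                               n_overlap,
                               n_hrde1_23C = NA, n_hrde1_23C_shared = NA) {
  stopifnot(n_overlap <= n_heat_induced_wt, n_overlap <= n_heat_induced_mut)
  list(
    nhg_count = n_heat_induced_mut - n_overlap,
    mut_wt_ratio = round(n_heat_induced_mut / n_heat_induced_wt, 1),
    wt_overlap_percent = round(100 * n_overlap / n_heat_induced_wt),
    unique_23C_count = if (is.na(n_hrde1_23C)) NA_integer_ else
      n_hrde1_23C - n_hrde1_23C_shared
  )
}

#' The packaged high-stringency NHG table
#'
#' A transcription of the published table of 41 high-stringency nuclear
#' RNAi-repressed heat-inducible genes, with chromosome and
#' transposon-context annotations (many lie in or near CER-family LTR
#' retrotransposons).
#'
#' @return data.frame with columns `gene_name`, `chromosome`,
#'   `transposon_note` (41 rows).
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "high_stringent_nhgs.tsv",
                      package = "nhgpipe", mustWork = TRUE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!identical(names(tab), c("gene_name", "chromosome", "transposon_note"))) {
    stop("high-stringency NHG fixture corrupted: unexpected columns")
  }
  tab
}

#' @rdname load_table1_fixture
#' @param gene_name gene name to look up.
#' @return `table1_lookup()` returns the matching row(s), or a zero-row
#'   data.frame when the gene is absent (not an error).
#' @export
table1_lookup <- function(gene_name) {
  tab <- load_table1_fixture()
  tab[tab$gene_name == gene_name, , drop = FALSE]
}
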