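#' Per-phase normalized siRNA means
#'
#' Size-factor-normalized mean antisense small RNA count per gene over the
#' three generations of each chronological phase (see [phase_groups()]).
#' Size factors are estimated once across all samples of the genotype.
#'
#' @param counts antisense-siRNA [count_matrix()] for one genotype covering
#'   all 12 generations.
#' @param grouping phase definition, default [phase_groups()].
#' @param sf optional precomputed size factors.
#' @return Numeric matrix genes x phases (columns `I`, `II`, `III`, `IV`).
#' @export
phase_means <- function(counts, grouping = phase_groups(), sf = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  gens <- counts$samples$generation
  for (ph in names(grouping)) {
    miss <- setdiff(grouping[[ph]], gens)
    if (length(miss)) {
      stop("phase ", ph, " incomplete; missing generation(s): ",
           paste(miss, collapse = ", "))
    }
  }
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts$counts, 2, sf, "/")
  out <- vapply(grouping, function(g) {
    rowMeans(norm[, gens %in% g, drop = FALSE])
  }, numeric(nrow(norm)))
  if (nrow(norm) == 1) out <- matrix(out, nrow = 1,
                                     dimnames = list(rownames(norm), names(grouping)))
  out
}

#' Call siRNA expression changes between mutant and WT per phase
#'
#' Per phase, the three generations are treated as replicates and the
#' negative-binomial machinery of [de_compare()] is applied to mutant vs.
#' WT antisense siRNA counts. Genes with fold >= `fold_cutoff` at FDR <=
#' `fdr_cutoff` are called `up_in_mutant`; genes with fold <=
#' 1/`fold_cutoff` are `down_in_mutant`. The two directions are disjoint by
#' construction.
#'
#' @param counts_wt,counts_mut antisense [count_matrix()] objects for WT
#'   and mutant (identical gene universes).
#' @param phase phase label (`"I"`..`"IV"`), or `NULL` for all four.
#' @param config a [classify_config()].
#' @param grouping phase definition, default [phase_groups()].
#' @return For one phase, a list `up_in_mutant`, `down_in_mutant`
#'   (gene ids) plus the `table`; for `phase = NULL`, a named list of such
#'   results.
#' @export
call_sirna_changes <- function(counts_wt, counts_mut, phase = NULL,
                               config = classify_config(),
                               grouping = phase_groups()) {
  if (!identical(rownames(counts_wt$counts), rownames(counts_mut$counts))) {
    stop("gene universes differ between genotypes")
  }
  if (is.null(phase)) {
    return(lapply(stats::setNames(nm = names(grouping)), function(ph)
      call_sirna_changes(counts_wt, counts_mut, ph, config, grouping)))
  }
  gens <- grouping[[phase]]
  if (is.null(gens)) stop("unknown phase: ", phase)
  a <- .select_samples(counts_wt, generations = gens)
  b <- .select_samples(counts_mut, generations = gens)
  if (length(a) < length(gens) || length(b) < length(gens)) {
    stop("phase ", phase, " absent or incomplete in a genotype")
  }
  j <- .join_counts(counts_wt, a, counts_mut, b)
  tab <- de_compare(j$joint, j$a, j$b, config)
  sig <- tab$q_value <= config$fdr_cutoff
  list(phase = phase,
       up_in_mutant = tab$gene_id[sig & tab$fold_change >= config$fold_cutoff],
       down_in_mutant = tab$gene_id[sig & tab$fold_change <= 1 / config$fold_cutoff],
       table = tab)
}

#' Cross-tabulate siRNA calls against mRNA calls
#'
#' 2x2 contingency of siRNA-changed vs. mRNA-changed genes over a common
#' universe, with overlap fractions in both directions and a
#' hypergeometric enrichment p-value for the intersection.
#'
#' @param sirna_genes,mrna_genes character vectors of called gene ids.
#' @param universe character vector of all testable gene ids (non-empty).
#' @return List: `table` (2x2 matrix), `overlap`,
#'   `fraction_of_mrna` (share of mRNA calls that also changed in siRNA),
#'   `fraction_of_sirna`, `p_hyper`.
#' @export
crosstab_sirna_mrna <- function(sirna_genes, mrna_genes, universe) {
  if (!length(universe)) stop("empty gene universe")
  sirna_genes <- intersect(sirna_genes, universe)
  mrna_genes <- intersect(mrna_genes, universe)
  ov <- length(intersect(sirna_genes, mrna_genes))
  ns <- length(sirna_genes); nm <- length(mrna_genes); N <- length(universe)
  tab <- matrix(c(ov, nm - ov, ns - ov, N - ns - nm + ov), 2, 2,
                dimnames = list(sirna = c("changed", "unchanged"),
                                mrna = c("changed", "unchanged")))
  p_hyper <- stats::phyper(ov - 1, ns, N - ns, nm, lower.tail = FALSE)
  list(table = tab, overlap = ov,
       fraction_of_mrna = if (nm > 0) ov / nm else NA_real_,
       fraction_of_sirna = if (ns > 0) ov / ns else NA_real_,
       p_hyper = p_hyper)
}

#' Box statistics of siRNA phase means for user-supplied gene lists
#'
#' Deterministic five-number summaries (min, lower quartile, median, upper
#' quartile, max; quartiles by the linear-interpolation rule of
#' `quantile(type = 7)`) of per-phase siRNA means for each supplied gene
#' list — used to compare e.g. published co-IP target lists or
#' germline-specific gene sets across phases and genotypes.
#'
#' @param means genes x phases matrix (see [phase_means()]).
#' @param gene_lists named list of character vectors; ids outside the
#'   universe are dropped with a warning, an empty list after filtering is
#'   an error.
#' @return data.frame: `list_name`, `phase`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max`.
#' @export
target_set_summary <- function(means, gene_lists) {
  stopifnot(is.list(gene_lists), !is.null(names(gene_lists)))
  out <- list()
  for (nm in names(gene_lists)) {
    ids <- gene_lists[[nm]]
    keep <- intersect(ids, rownames(means))
    if (length(keep) < length(ids)) {
      warning(sprintf("list '%s': %d id(s) outside the universe dropped",
                      nm, length(ids) - length(keep)))
    }
    if (!length(keep)) stop("list '", nm, "' empty after filtering")
    for (ph in colnames(means)) {
      v <- means[keep, ph]
      q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        list_name = nm, phase = ph, n = length(v),
        min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Retention of down-called genes across consecutive phases
#'
#' For each phase transition, the fraction of genes called
#' `down_in_mutant` in the earlier phase that remain in that category in
#' the later phase — a descriptive statistic of the cumulative loss of
#' siRNA expression, not a test.
#'
#' @param calls result of `call_sirna_changes(..., phase = NULL)`.
#' @return data.frame: `from`, `to`, `n_from`, `n_retained`, `fraction`.
#' @export
sirna_retention <- function(calls) {
  phs <- names(calls)
  out <- list()
  for (i in seq_len(length(phs) - 1)) {
    a <- calls[[phs[i]]]$down_in_mutant
    b <- calls[[phs[i + 1]]]$down_in_mutant
    out[[i]] <- data.frame(
      from = phs[i], to = phs[i + 1],
      n_from = length(a), n_retained = length(intersect(a, b)),
      fraction = if (length(a)) length(intersect(a, b)) / length(a) else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
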