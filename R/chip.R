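#' Per-gene signal ratio between two generations
#'
#' The generation delta: the ratio of per-gene signal (RPKM) between a
#' numerator and a denominator generation for one genotype, e.g. Pol II at
#' a 23 C generation over the last pre-stress 15 C generation. A
#' pseudocount keeps ratios finite at silent genes. When several samples
#' match a generation (e.g. two repeats), their values are averaged first.
#'
#' @param signal an `expression_matrix` (see [rpkm()]).
#' @param gen_num,gen_den generation labels for numerator and denominator.
#' @param genotype restrict to one genotype (`"WT"`/`"hrde1"`); `NULL`
#'   uses all matching samples.
#' @param pseudocount added to both values (default 0.1 RPKM).
#' @return Named numeric vector of per-gene ratios.
#' @export
generation_delta <- function(signal, gen_num, gen_den, genotype = NULL,
                             pseudocount = 0.1) {
  stopifnot(inherits(signal, "expression_matrix"))
  pick <- function(gen) {
    sel <- signal$samples$generation == gen
    if (!is.null(genotype)) sel <- sel & signal$samples$genotype == genotype
    if (!any(sel)) stop("generation absent from signal matrix: ", gen)
    rowMeans(signal$values[, sel, drop = FALSE])
  }
  num <- pick(gen_num)
  den <- pick(gen_den)
  (num + pseudocount) / (den + pseudocount)
}

#' Shift test of a gene set's deltas against the background
#'
#' One-sided Wilcoxon rank-sum test (set greater than background) of a gene
#' set's generation deltas against all background genes, with the two
#' medians reported — the standard way to ask whether, say, NHG Pol II
#' levels rose at a 23 C generation relative to the genome at large.
#'
#' @param deltas named per-gene ratio vector (see [generation_delta()]).
#' @param gene_set character vector of gene ids (>= 2 present in `deltas`).
#' @param background gene ids forming the comparison set; defaults to all
#'   genes in `deltas` (the set is not removed from the background).
#' @return List: `median_set`, `median_background`, `p_value`, `n_set`.
#' @export
set_shift_test <- function(deltas, gene_set, background = names(deltas)) {
  set_vals <- deltas[intersect(gene_set, names(deltas))]
  if (length(set_vals) < 2) stop("gene set shares < 2 genes with the delta universe")
  bg_vals <- deltas[intersect(background, names(deltas))]
  p <- wilcoxon_one_sided(unname(set_vals), unname(bg_vals), "greater")
  list(median_set = stats::median(set_vals),
       median_background = stats::median(bg_vals),
       p_value = p, n_set = length(set_vals))
}

#' Call cumulative (progressively increasing) expression trends
#'
#' A gene is called cumulative over the six consecutive 23 C generations
#' when its expression trend is progressively increasing: positive Spearman
#' rank correlation with the generation index at one-sided p <
#' `trend_p_cutoff`, and a final-over-first fold span of at least
#' `span_fold` (an effect-size guard so that a weak monotone drift is not
#' called).
#'
#' @param series numeric matrix, genes x 6 (columns in chronological
#'   generation order `23C-G1..23C-G6`), of normalized expression.
#' @param trend_p_cutoff one-sided Spearman p threshold (default 0.05).
#' @param span_fold minimal last/first fold (default 2).
#' @param pseudocount added to first/last values for the span ratio.
#' @return data.frame: `gene_id`, `rho`, `trend_p`, `span`, `cumulative`.
#' @export
call_cumulative <- function(series, trend_p_cutoff = 0.05, span_fold = 2,
                            pseudocount = 0.1) {
  series <- as.matrix(series)
  if (ncol(series) != 6) stop("series must have all six 23 C generations")
  gen_idx <- seq_len(6)
  res <- t(apply(series, 1, function(v) {
    if (all(!is.finite(v))) return(c(NA, 1))
    ct <- suppressWarnings(
      stats::cor.test(v, gen_idx, method = "spearman",
                      alternative = "greater"))
    c(unname(ct$estimate), ct$p.value)
  }))
  span <- (series[, 6] + pseudocount) / (series[, 1] + pseudocount)
  cumulative <- !is.na(res[, 1]) & res[, 1] > 0 &
    res[, 2] < trend_p_cutoff & span >= span_fold
  data.frame(gene_id = rownames(series), rho = res[, 1], trend_p = res[, 2],
             span = span, cumulative = cumulative,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call post-stress persistence of activation
#'
#' After the shift back to 15 C, a gene's activation is called persistent
#' at a post-stress generation when its expression still exceeds
#' `fold` times its pre-stress 15 C baseline mean.
#'
#' @param series numeric matrix, genes x post-stress generations
#'   (`p15C-G1..G3`), of normalized expression.
#' @param baseline named per-gene pre-stress 15 C baseline means.
#' @param fold persistence threshold (default 2).
#' @param pseudocount added to baseline and values.
#' @return Logical matrix, genes x generations: persistent or not.
#' @export
call_persistent <- function(series, baseline, fold = 2, pseudocount = 0.1) {
  series <- as.matrix(series)
  if (is.null(names(baseline))) {
    if (length(baseline) != nrow(series)) stop("baseline must be named or match series")
    names(baseline) <- rownames(series)
  }
  miss <- setdiff(rownames(series), names(baseline))
  if (length(miss)) stop("missing baseline for gene(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  b <- baseline[rownames(series)] + pseudocount
  if (any(b <= 0)) stop("baseline must be positive after pseudocount")
  out <- sweep(series + pseudocount, 1, b, "/") >= fold
  dimnames(out) <- dimnames(series)
  out
}
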