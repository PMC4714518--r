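#' Fraction of query regions overlapping an annotation
#'
#' A query region counts as overlapping iff it shares at least 1 bp with
#' any annotation interval extended by `flank_bp` on both sides (clipped at
#' chromosome ends). Strand is ignored.
#'
#' @param query non-empty `GRanges` of query regions.
#' @param annot `GRanges` annotation (e.g. LTR retrotransposons).
#' @param flank_bp flank added to each annotation interval (bp).
#' @return The overlap fraction F in `[0, 1]`.
#' @export
overlap_fraction <- function(query, annot, flank_bp = 0) {
  if (length(query) == 0) stop("query interval set is empty")
  if (length(annot) == 0) return(0)
  ext <- GenomicRanges::trim(suppressWarnings(annot + flank_bp))
  mean(GenomicRanges::countOverlaps(query, ext, ignore.strand = TRUE) > 0)
}

#' @keywords internal
#' Per-chromosome start windows whose regions hit the annotation.
#' A region [s, s+len-1] (1-based) overlaps annotation [a, b] iff
#' a - len + 1 <= s <= b; windows are merged and clipped to the valid
#' start range [1, L - len + 1].
.hit_windows <- function(annot, chrom_sizes, region_length, flank_bp) {
  ext <- if (length(annot)) GenomicRanges::trim(suppressWarnings(annot + flank_bp)) else annot
  ext <- GenomicRanges::reduce(ext, ignore.strand = TRUE)
  lapply(stats::setNames(nm = names(chrom_sizes)), function(cn) {
    L <- chrom_sizes[[cn]]
    smax <- L - region_length + 1
    if (smax < 1) return(numeric(0))
    a <- ext[as.character(GenomicRanges::seqnames(ext)) == cn]
    if (!length(a)) return(numeric(0))
    ws <- pmax(1, GenomicRanges::start(a) - region_length + 1)
    we <- pmin(GenomicRanges::end(a), smax)
    keep <- ws <= we
    if (!any(keep)) return(numeric(0))
    ir <- IRanges::reduce(IRanges::IRanges(ws[keep], we[keep]))
    # interleaved breaks; findInterval(s, breaks) odd <=> s inside a window
    as.numeric(rbind(IRanges::start(ir) - 0.5, IRanges::end(ir) + 0.5))
  })
}

#' Monte Carlo test of genomic association with an annotation
#'
#' Tests whether a set of query regions overlaps an annotation more often
#' than expected for random placement. Each simulation places `n_regions`
#' regions of fixed length on the genome — chromosome sampled with
#' probability proportional to its length, start uniform so the region
#' never crosses a chromosome end — and records the overlap fraction F.
#' The empirical p-value is the fraction of simulations with
#' `F >= F_observed`; a zero count is reported as `< 1/n_sims` in the text
#' field (no pseudocount is added).
#'
#' @param query `GRanges` of observed query regions, or `NULL` when
#'   `f_observed` is supplied directly.
#' @param annot `GRanges` annotation.
#' @param chrom_sizes named chromosome lengths.
#' @param n_regions regions per simulation; defaults to `length(query)`.
#' @param region_length_bp fixed region length (default 2920 bp, the mean
#'   size of the NHG gene class that motivates the default).
#' @param flank_bp annotation flank in bp (0, 500 or 1000 in the standard
#'   analysis).
#' @param n_sims number of simulations (default 1e5).
#' @param seed optional RNG seed for reproducibility.
#' @param f_observed observed overlap fraction, if precomputed.
#' @return List of class `overlap_result`: `f_observed`, `null_f`
#'   (length `n_sims`), `p_empirical`, `p_text`, and the configuration.
#' @export
mc_overlap_test <- function(query = NULL, annot, chrom_sizes,
                            n_regions = NULL, region_length_bp = 2920,
                            flank_bp = 0, n_sims = 1e5, seed = NULL,
                            f_observed = NULL) {
  stopifnot(n_sims >= 1, region_length_bp > 0)
  if (is.null(f_observed)) {
    if (is.null(query)) stop("supply query regions or f_observed")
    f_observed <- overlap_fraction(query, annot, flank_bp)
    if (is.null(n_regions)) n_regions <- length(query)
  }
  if (is.null(n_regions)) stop("n_regions required when f_observed is given")
  ok_chroms <- chrom_sizes[chrom_sizes >= region_length_bp]
  if (!length(ok_chroms)) stop("region_length_bp exceeds every chromosome length")
  if (!is.null(seed)) set.seed(seed)
  empty_annot <- length(annot) == 0
  if (empty_annot) warning("empty annotation: every null F is 0 and p = 1")
  windows <- .hit_windows(annot, ok_chroms, region_length_bp, flank_bp)
  probs <- ok_chroms / sum(ok_chroms)
  smax <- ok_chroms - region_length_bp + 1

  null_f <- numeric(n_sims)
  chunk <- max(1L, floor(2e6 / n_regions))
  done <- 0L
  while (done < n_sims) {
    b <- min(chunk, n_sims - done)
    total <- b * n_regions
    ci <- sample.int(length(ok_chroms), total, replace = TRUE, prob = probs)
    s <- floor(stats::runif(total) * smax[ci]) + 1
    hit <- logical(total)
    for (j in seq_along(ok_chroms)) {
      w <- windows[[j]]
      if (!length(w)) next
      sel <- ci == j
      if (!any(sel)) next
      hit[sel] <- findInterval(s[sel], w) %% 2L == 1L
    }
    sim_id <- rep(seq_len(b), each = n_regions)
    null_f[done + seq_len(b)] <-
      as.numeric(rowsum(as.numeric(hit), sim_id)) / n_regions
    done <- done + b
  }
  n_ge <- sum(null_f >= f_observed - 1e-12)
  p <- n_ge / n_sims
  structure(list(
    f_observed = f_observed, null_f = null_f, p_empirical = p,
    p_text = if (n_ge == 0) sprintf("< %g", 1 / n_sims) else sprintf("%g", p),
    n_regions = n_regions, region_length_bp = region_length_bp,
    flank_bp = flank_bp, n_sims = n_sims, seed = seed
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: F = %.4f over %d regions (%d bp, flank %d)\n",
              x$f_observed, x$n_regions, x$region_length_bp, x$flank_bp))
  cat(sprintf("  null: %d sims, mean F = %.4f; p %s\n",
              x$n_sims, mean(x$null_f),
              if (startsWith(x$p_text, "<")) x$p_text else paste("=", x$p_text)))
  invisible(x)
}

#' Chromosome arm/center partition
#'
#' Autosomes are split into arms (the outer quarter of the chromosome at
#' each end) and a central region (the middle half) — arms carry most of
#' the heterochromatin domains in *C. elegans*. The X chromosome is split
#' into two parts at 1/6 of its length. Regions are half-open toward the
#' chromosome start and tile each chromosome exactly.
#'
#' @param chrom_sizes named chromosome lengths.
#' @param x_chrom name of the X chromosome in `chrom_sizes`.
#' @return data.frame: `chrom`, `region`, `start`, `end`
#'   (0-based half-open).
#' @export
chrom_partition <- function(chrom_sizes, x_chrom = "chrX") {
  out <- lapply(names(chrom_sizes), function(cn) {
    L <- chrom_sizes[[cn]]
    if (cn == x_chrom) {
      b <- round(L / 6)
      data.frame(chrom = cn, region = c("part1", "part2"),
                 start = c(0, b), end = c(b, L))
    } else {
      b1 <- round(L / 4); b2 <- L - round(L / 4)
      data.frame(chrom = cn,
                 region = c("left_arm", "center", "right_arm"),
                 start = c(0, b1, b2), end = c(b1, b2, L))
    }
  })
  do.call(rbind, out)
}

#' @keywords internal
#' Assign genes to partition regions by midpoint (half-open boundaries).
.assign_region <- function(models, partition) {
  mp <- floor((models$start + models$end) / 2)
  region <- rep(NA_character_, nrow(models))
  for (i in seq_len(nrow(partition))) {
    sel <- models$chrom == partition$chrom[i] &
      mp >= partition$start[i] & mp < partition$end[i]
    region[sel] <- partition$region[i]
  }
  region
}

#' Arm/center enrichment of a gene set
#'
#' Per chromosome, compares the observed distribution of a gene set over
#' the partition regions (arms pooled vs. center for autosomes; the two
#' 1/6-split parts for X) against the expectation proportional to all-gene
#' counts, with a chi-square goodness-of-fit p-value.
#'
#' @param gene_set character vector of gene ids.
#' @param all_genes gene-model data.frame (the gene universe).
#' @param chrom_sizes named chromosome lengths.
#' @param x_chrom name of the X chromosome.
#' @return List: `table` (chrom, region, observed, expected),
#'   `tests` (chrom, statistic, p_value, direction). Chromosomes with a
#'   region empty of universe genes are skipped with a warning.
#' @export
arm_center_enrichment <- function(gene_set, all_genes, chrom_sizes,
                                  x_chrom = "chrX") {
  part <- chrom_partition(chrom_sizes, x_chrom)
  all_genes$.region <- .assign_region(all_genes, part)
  set_models <- all_genes[all_genes$gene_id %in% gene_set, , drop = FALSE]
  # pool the two autosome arms
  pool <- function(r) ifelse(r %in% c("left_arm", "right_arm"), "arms", r)
  tabs <- list(); tests <- list()
  for (cn in names(chrom_sizes)) {
    uni <- pool(all_genes$.region[all_genes$chrom == cn])
    obs <- pool(set_models$.region[set_models$chrom == cn])
    cats <- if (cn == x_chrom) c("part1", "part2") else c("arms", "center")
    n_uni <- vapply(cats, function(ct) sum(uni == ct), 0)
    n_obs <- vapply(cats, function(ct) sum(obs == ct), 0)
    if (any(n_uni == 0)) {
      warning("chromosome ", cn, " skipped: a region holds no universe genes")
      next
    }
    expected <- n_uni / sum(n_uni) * sum(n_obs)
    tabs[[cn]] <- data.frame(chrom = cn, region = cats,
                             observed = n_obs, expected = expected,
                             row.names = NULL)
    if (sum(n_obs) > 0) {
      gof <- chi_square_gof(n_obs, n_uni)
      dirn <- cats[which.max(n_obs - expected)]
      tests[[cn]] <- data.frame(chrom = cn, statistic = gof$statistic,
                                p_value = gof$p_value,
                                enriched_region = dirn, row.names = NULL)
    }
  }
  list(table = do.call(rbind, tabs), tests = do.call(rbind, tests))
}

#' Monte Carlo chromosome-depletion test
#'
#' Tests whether a gene set is depleted on one chromosome relative to the
#' gene universe. Each simulation draws a uniform same-size subset of the
#' universe (without replacement) and counts members on the chromosome; the
#' p-value is the fraction of simulations with a count less than or equal
#' to the observed one. The fold depletion is the expected over the
#' observed chromosome fraction; an observed count of zero is reported as a
#' lower bound (`fold_display`).
#'
#' @param gene_set character vector of gene ids (non-empty).
#' @param all_genes gene-model data.frame (universe, with `chrom`).
#' @param chrom chromosome to test.
#' @param n_sims number of Monte Carlo draws.
#' @param seed optional RNG seed.
#' @return List: `observed`, `expected`, `fold_depletion`, `fold_display`,
#'   `p_value`, `n_sims`.
#' @export
chrom_depletion_test <- function(gene_set, all_genes, chrom,
                                 n_sims = 10000, seed = NULL) {
  if (!length(gene_set)) stop("gene_set is empty")
  if (!chrom %in% all_genes$chrom) stop("chromosome absent from universe: ", chrom)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(all_genes)
  on_chrom <- all_genes$chrom == chrom
  nX <- sum(on_chrom)
  set_idx <- match(gene_set, all_genes$gene_id)
  if (anyNA(set_idx)) stop("gene_set contains ids outside the universe")
  n <- length(set_idx)
  obs <- sum(on_chrom[set_idx])
  expected <- n * nX / N
  sims <- vapply(seq_len(n_sims), function(i) {
    sum(on_chrom[sample.int(N, n)])
  }, 0L)
  p <- mean(sims <= obs)
  fold <- if (obs > 0) expected / obs else Inf
  list(observed = obs, expected = expected,
       fold_depletion = fold,
       fold_display = if (obs > 0) sprintf("%.1f", fold)
                      else sprintf("> %.1f", expected),
       p_value = p, n_sims = n_sims)
}
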