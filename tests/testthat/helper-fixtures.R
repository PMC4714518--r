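# Shared in-code fixtures for the suite. Everything is generated; nothing
# binary is stored.

# minimal valid metadata for n mRNA samples of one genotype/repeat
tiny_meta <- function(n = 2, genotype = "WT", repeat_id = 1,
                      generations = generation_levels()[seq_len(n)],
                      library = "mRNA") {
  data.frame(
    sample_id = paste0("s", seq_len(n)),
    genotype = genotype, generation = generations,
    repeat_id = repeat_id, library = library,
    stringsAsFactors = FALSE)
}

tiny_counts <- function(mat, ...) {
  count_matrix(mat, tiny_meta(ncol(mat), ...))
}

# merge the two mRNA repeats of one genotype from a simulate_counts() list
merge_genotype <- function(counts_list, genotype) {
  ms <- lapply(counts_list[c("mRNA_rep1", "mRNA_rep2")], function(cm)
    subset_samples(cm, cm$samples$genotype == genotype &
                     cm$samples$library == "mRNA"))
  count_matrix(do.call(cbind, lapply(ms, function(p) p$counts)),
               do.call(rbind, lapply(ms, function(p) p$samples)))
}

# a small all-null simulation config (no planted classes)
null_props <- c(wt_heat_induced = 0, heat_repressed = 0, nhg_plain = 0,
                high_stringent_nhg = 0, cumulative_nhg = 0,
                sirna_loss = 0, sirna_gain = 0)

# independent quadratic all-pairs overlap oracle on plain coordinates
overlap_fraction_oracle <- function(q_start, q_end, q_chrom,
                                    a_start, a_end, a_chrom, flank,
                                    chrom_sizes) {
  hit <- vapply(seq_along(q_start), function(i) {
    any(vapply(seq_along(a_start), function(j) {
      if (a_chrom[j] != q_chrom[i]) return(FALSE)
      s <- max(0, a_start[j] - flank)
      e <- min(chrom_sizes[[a_chrom[j]]], a_end[j] + flank)
      q_start[i] < e && q_end[i] > s   # 0-based half-open overlap
    }, TRUE))
  }, TRUE)
  mean(hit)
}

granges_0based <- function(chrom, start, end, chrom_sizes, strand = "*") {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, end),
                               strand = strand)
  GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
  GenomeInfoDb::seqlengths(gr) <- unname(chrom_sizes)
  gr
}
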