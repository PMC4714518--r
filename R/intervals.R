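#' Read a chromosome-sizes table
#'
#' Two-column TSV (chromosome name, length in bp), no header.
#'
#' @param path path to the TSV.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
  if (any(tab$size <= 0) || any(tab$size != round(tab$size))) {
    stop("chromosome sizes must be positive integers")
  }
  if (anyDuplicated(tab$chrom)) stop("duplicate chromosome in sizes file")
  stats::setNames(as.integer(tab$size), tab$chrom)
}

#' Read a BED interval file against known chromosome sizes
#'
#' BED coordinates are 0-based half-open on disk and are converted to the
#' 1-based closed `GRanges` convention in memory. Intervals on unknown
#' chromosomes or exceeding the chromosome length are hard errors. A strand
#' column (BED6) is honoured when present; otherwise strand is unset (`*`).
#'
#' @param path path to a BED3/BED6 file.
#' @param chrom_sizes named vector of chromosome lengths
#'   (see [read_chrom_sizes()]).
#' @return A `GRanges` with `seqlengths` set from `chrom_sizes`.
#' @export
read_intervals <- function(path, chrom_sizes) {
  gr <- rtracklayer::import(path, format = "BED")
  unknown <- setdiff(as.character(GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(gr))),
                     names(chrom_sizes))
  if (length(unknown)) {
    stop("interval(s) on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  if (length(gr)) {
    lim <- chrom_sizes[as.character(GenomicRanges::seqnames(gr))]
    over <- GenomicRanges::end(gr) > lim | GenomicRanges::start(gr) < 1
    if (any(over)) {
      i <- which(over)[1]
      stop(sprintf("interval %s:%d-%d exceeds chromosome length %d",
                   as.character(GenomicRanges::seqnames(gr))[i],
                   GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i],
                   lim[i]))
    }
  }
  GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
  GenomeInfoDb::seqlengths(gr) <- unname(chrom_sizes)
  gr
}

#' Write intervals to BED
#'
#' Inverse of [read_intervals()]; coordinates convert back to 0-based
#' half-open on disk.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_intervals <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene models
#'
#' Two on-disk forms are accepted: a 7-column TSV
#' (`gene_id`, `chrom`, `start`, `end`, `strand`, `gene_length`,
#' `exon_length`; start/end 0-based half-open) or GFF3 (detected from the
#' file extension), from which exon lengths are computed as the per-gene sum
#' of reduced exon widths.
#'
#' @param path path to the gene-model file.
#' @param chrom_sizes optional named chromosome lengths for validation.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `gene_length`, `exon_length`.
#' @export
read_gene_models <- function(path, chrom_sizes = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "GFF3")
    genes <- gr[gr$type == "gene"]
    if (!length(genes)) stop("no 'gene' features in GFF: ", path)
    ids <- genes$ID
    if (is.null(ids) || anyNA(ids)) stop("GFF gene features must carry ID")
    exons <- gr[gr$type == "exon"]
    exon_len <- stats::setNames(
      GenomicRanges::width(genes), ids)  # fallback: full gene length
    if (length(exons)) {
      parent <- vapply(exons$Parent, function(p) as.character(p)[1], "")
      # exons usually name transcripts; map to genes when they name genes
      keep <- parent %in% ids
      if (any(keep)) {
        by_gene <- split(exons[keep], parent[keep])
        red <- vapply(by_gene, function(e)
          sum(GenomicRanges::width(GenomicRanges::reduce(e))), 0)
        exon_len[names(red)] <- red
      }
    }
    out <- data.frame(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(genes)),
      start = GenomicRanges::start(genes) - 1L,
      end = GenomicRanges::end(genes),
      strand = as.character(GenomicRanges::strand(genes)),
      gene_length = GenomicRanges::width(genes),
      exon_length = as.integer(exon_len[ids]),
      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    req <- c("gene_id", "chrom", "start", "end", "strand",
             "gene_length", "exon_length")
    miss <- setdiff(req, names(out))
    if (length(miss)) stop("gene-model TSV lacks column(s): ",
                           paste(miss, collapse = ", "))
    out <- out[, req]
  }
  validate_gene_models(out, chrom_sizes)
}

#' @keywords internal
validate_gene_models <- function(models, chrom_sizes = NULL) {
  if (anyDuplicated(models$gene_id)) {
    stop("duplicate gene_id in gene models: ",
         paste(unique(models$gene_id[duplicated(models$gene_id)]), collapse = ", "))
  }
  if (any(models$start < 0) || any(models$start >= models$end)) {
    stop("gene models require 0 <= start < end")
  }
  if (!all(models$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  if (any(models$gene_length != models$end - models$start)) {
    stop("gene_length must equal end - start")
  }
  if (any(models$exon_length > models$gene_length) || any(models$exon_length <= 0)) {
    stop("exon_length must be in (0, gene_length]")
  }
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(models$chrom), names(chrom_sizes))
    if (length(unknown)) stop("gene(s) on unknown chromosome(s): ",
                              paste(unknown, collapse = ", "))
    if (any(models$end > chrom_sizes[models$chrom])) {
      stop("gene model exceeds chromosome length")
    }
  }
  models
}

#' Convert gene models to GRanges
#'
#' @param models gene-model data.frame (see [read_gene_models()]).
#' @param chrom_sizes optional named chromosome lengths to set as
#'   `seqlengths`.
#' @return A named `GRanges` (1-based closed).
#' @export
genes_to_granges <- function(models, chrom_sizes = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(start = models$start + 1L, end = models$end),
    strand = models$strand)
  names(gr) <- models$gene_id
  if (!is.null(chrom_sizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- unname(chrom_sizes)
  }
  gr
}

#' Strand-aware per-gene tag counting
#'
#' Counts aligned tags per gene. A tag is counted for a gene iff it overlaps
#' the gene by at least 1 bp and its strand matches the gene's strand
#' (`sense`) or is opposite (`antisense`). A tag overlapping k genes
#' increments all k (no fractional assignment). mRNA libraries are counted
#' sense; antisense counting is the convention for endogenous siRNAs, which
#' are antisense to their target mRNA.
#'
#' @param alignments `GRanges` of aligned tags; strand must be `+`/`-`.
#' @param genes gene-model data.frame or a stranded `GRanges` with names.
#' @param orientation `"sense"` or `"antisense"`.
#' @return Named integer vector of per-gene counts.
#' @export
count_tags <- function(alignments, genes, orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  if (is.data.frame(genes)) genes <- genes_to_granges(genes)
  std <- as.character(GenomicRanges::strand(alignments))
  if (any(std == "*")) {
    stop("strandless alignment(s) present; strand-aware counting requires +/-")
  }
  if (orientation == "antisense") {
    alignments <- GenomicRanges::invertStrand(alignments)
  }
  n <- GenomicRanges::countOverlaps(genes, alignments, ignore.strand = FALSE)
  stats::setNames(as.integer(n), names(genes))
}

#' RPKM quantification
#'
#' Reads per kilobase of feature per million mapped reads:
#' `count / (library_total / 1e6) / (length / 1e3)`. RNA libraries
#' (mRNA, sRNA) are normalized by exon length; ChIP libraries by full gene
#' length. A basis/library mismatch is refused unless `force = TRUE`.
#'
#' @param counts a [count_matrix()].
#' @param lengths named per-gene lengths in bp (exon or gene lengths,
#'   matching `length_basis`).
#' @param length_basis `"exon"` (mRNA/sRNA) or `"gene"` (ChIP).
#' @param force bypass the basis/library consistency check.
#' @return An `expression_matrix`: list with `values` (genes x samples RPKM
#'   matrix) and `samples` (the metadata).
#' @export
rpkm <- function(counts, lengths, length_basis = c("exon", "gene"),
                 force = FALSE) {
  stopifnot(inherits(counts, "count_matrix"))
  length_basis <- match.arg(length_basis)
  libs <- unique(counts$samples$library)
  chip <- grepl("^chip", libs)
  if (!force) {
    if (length_basis == "exon" && any(chip)) {
      stop("ChIP libraries use length_basis = 'gene' (use force = TRUE to override)")
    }
    if (length_basis == "gene" && any(!chip)) {
      stop("mRNA/sRNA libraries use length_basis = 'exon' (use force = TRUE to override)")
    }
  }
  if (any(counts$total_per_sample == 0)) {
    stop("zero library total for sample(s): ",
         paste(names(counts$total_per_sample)[counts$total_per_sample == 0],
               collapse = ", "))
  }
  ids <- rownames(counts$counts)
  if (is.null(names(lengths))) {
    if (length(lengths) != length(ids)) stop("lengths must be named or match gene count")
    names(lengths) <- ids
  }
  miss <- setdiff(ids, names(lengths))
  if (length(miss)) stop("missing length for gene(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  len <- lengths[ids]
  if (any(len <= 0)) stop("feature lengths must be positive")
  vals <- sweep(counts$counts, 2, counts$total_per_sample / 1e6, "/")
  vals <- sweep(vals, 1, len / 1e3, "/")
  structure(list(values = vals, samples = counts$samples,
                 length_basis = length_basis),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (RPKM, %s length): %d genes x %d samples\n",
              x$length_basis, nrow(x$values), ncol(x$values)))
  invisible(x)
}
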