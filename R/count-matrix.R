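#' Construct a validated count matrix
#'
#' A `count_matrix` bundles a genes x samples matrix of non-negative
#' integer read counts with the per-sample metadata of the
#' multigenerational design. Column order of `counts` must match the row
#' order of `samples$sample_id`.
#'
#' @param counts integer matrix (genes x samples) with rownames = gene ids.
#' @param samples sample metadata data.frame (see [validate_sample_meta()]).
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `samples` and `total_per_sample` (column sums).
#' @examples
#' m <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), genotype = "WT",
#'                    generation = c("15C-G1", "15C-G2"),
#'                    repeat_id = 1, library = "mRNA")
#' cm <- count_matrix(m, meta)
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0) {
    stop("counts must have gene ids as rownames")
  }
  samples <- validate_sample_meta(samples)
  if (ncol(counts) != nrow(samples)) {
    stop("counts has ", ncol(counts), " columns but metadata has ",
         nrow(samples), " samples")
  }
  if (!is.null(colnames(counts)) && !identical(colnames(counts), samples$sample_id)) {
    if (!setequal(colnames(counts), samples$sample_id)) {
      stop("sample(s) in counts without metadata: ",
           paste(setdiff(colnames(counts), samples$sample_id), collapse = ", "))
    }
    counts <- counts[, samples$sample_id, drop = FALSE]
  }
  colnames(counts) <- samples$sample_id
  if (nrow(counts) > 0) {
    dup <- rownames(counts)[duplicated(rownames(counts))]
    if (length(dup)) stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
    bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("invalid count at gene '%s', sample '%s': %s",
                   rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                   counts[bad[1, 1], bad[1, 2]]))
    }
    storage.mode(counts) <- "integer"
  }
  structure(list(counts = counts, samples = samples,
                 total_per_sample = colSums(counts)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("libraries:", paste(unique(x$samples$library), collapse = ", "), "\n")
  cat("genotypes:", paste(unique(x$samples$genotype), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a count matrix by sample predicate
#'
#' @param x a `count_matrix`.
#' @param keep logical vector over samples (or an expression of metadata
#'   columns evaluated in the metadata).
#' @return A `count_matrix` restricted to the selected samples.
#' @export
subset_samples <- function(x, keep) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- which(keep)
  count_matrix(x$counts[, keep, drop = FALSE], x$samples[keep, , drop = FALSE])
}

#' Read a count matrix and its metadata sidecar
#'
#' Counts are a TSV with the gene id in the first column and one column per
#' sample; metadata is a sidecar TSV with one row per sample
#' (`sample_id`, `genotype`, `generation`, `repeat_id`, `library`). Input
#' gene order is preserved. Every sample in the header must have a metadata
#' row; negative, non-integral or duplicated entries are hard errors naming
#' the offending cell.
#'
#' @param path path to the counts TSV.
#' @param meta_path path to the metadata TSV; defaults to
#'   `<path minus extension>.meta.tsv`.
#' @return A [count_matrix()].
#' @seealso [write_counts()] for the inverse.
#' @export
read_counts <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) {
    meta_path <- paste0(tools::file_path_sans_ext(path), ".meta.tsv")
  }
  if (!file.exists(path)) stop("counts file not found: ", path)
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  sample_ids <- colnames(tab)[-1]
  missing_meta <- setdiff(sample_ids, meta$sample_id)
  if (length(missing_meta)) {
    stop("sample(s) in counts header without metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  if (nrow(tab) == 0) {
    m <- matrix(integer(0), nrow = 0, ncol = length(sample_ids),
                dimnames = list(NULL, sample_ids))
    return(count_matrix(m, meta))
  }
  gene_ids <- tab[[1]]
  num <- suppressWarnings(
    vapply(tab[-1], as.numeric, numeric(nrow(tab)))
  )
  num <- matrix(num, nrow = nrow(tab),
                dimnames = list(gene_ids, sample_ids))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid count at gene '%s', sample '%s': %s",
                 gene_ids[bad[1, 1]], sample_ids[bad[1, 2]],
                 tab[bad[1, 1], bad[1, 2] + 1L]))
  }
  count_matrix(num, meta)
}

#' Write a count matrix and its metadata sidecar
#'
#' @param x a [count_matrix()].
#' @param path output TSV path; the metadata sidecar is written to
#'   `meta_path`.
#' @param meta_path sidecar path, default `<path minus extension>.meta.tsv`.
#' @return Invisibly, `c(path, meta_path)`.
#' @export
write_counts <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(meta_path)) {
    meta_path <- paste0(tools::file_path_sans_ext(path), ".meta.tsv")
  }
  out <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(x$counts) == 0) {
    out <- stats::setNames(
      as.data.frame(matrix(integer(0), 0, 1 + ncol(x$counts))),
      c("gene_id", colnames(x$counts)))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_cols <- c("sample_id", "genotype", "generation", "temperature",
                 "repeat_id", "library")
  utils::write.table(x$samples[, meta_cols], meta_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(path, meta_path))
}
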