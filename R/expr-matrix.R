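#' Multi-tissue expression matrix
#'
#' Container for a gene x sample experiment with a raw count layer, an RPKM
#' layer and per-sample metadata (tissue, replicate, dataset). Both layers
#' share the same dimnames; every sample carries a tissue label.
#'
#' @param counts integer-like gene x sample matrix of read counts.
#' @param rpkm numeric gene x sample matrix of RPKM values, same shape.
#' @param samples data.frame with columns `sample_id`, `tissue`, `replicate`
#'   and optionally `dataset`; `sample_id` must match the matrix column names.
#' @param gene_lengths optional named numeric vector of transcript lengths (bp).
#' @return object of class `tissue_expr`.
#' @export
tissue_expr <- function(counts, rpkm, samples, gene_lengths = NULL) {
  counts <- as.matrix(counts)
  rpkm <- as.matrix(rpkm)
  if (!identical(dim(counts), dim(rpkm)) ||
      !identical(dimnames(counts), dimnames(rpkm))) {
    stop_input("count and rpkm layers must share identical gene x sample shape")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_input("expression layers need gene rownames and sample colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_input("counts must be nonnegative integers")
  }
  if (any(rpkm < 0)) stop_input("rpkm values must be nonnegative")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "replicate")
  if (!all(need %in% names(samples))) {
    stop_input("sample metadata needs columns: ", paste(need, collapse = ", "))
  }
  if (!identical(as.character(samples$sample_id), colnames(counts))) {
    stop_input("samples$sample_id must match matrix column names in order")
  }
  if (anyNA(samples$tissue)) stop_input("every sample needs a tissue label")
  if (is.null(samples$dataset)) samples$dataset <- "dataset1"
  if (!is.null(gene_lengths)) {
    gene_lengths <- gene_lengths[rownames(counts)]
    if (anyNA(gene_lengths)) stop_input("gene_lengths must cover every gene")
  }
  structure(
    list(counts = counts, rpkm = rpkm, samples = samples,
         gene_lengths = gene_lengths),
    class = "tissue_expr"
  )
}

#' @export
print.tissue_expr <- function(x, ...) {
  tt <- table(x$samples$tissue)
  cat("Multi-tissue expression matrix\n")
  cat("  genes:  ", nrow(x$counts), "\n", sep = "")
  cat("  samples:", ncol(x$counts), "across", length(tt), "tissues\n")
  cat("  replicates per tissue: ",
      paste(sprintf("%s=%d", names(tt), as.integer(tt)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.tissue_expr <- function(x) dim(x$counts)

#' Genes of an expression matrix
#' @param x a `tissue_expr` object.
#' @return character vector of gene identifiers.
#' @export
genes <- function(x) UseMethod("genes")

#' @export
genes.tissue_expr <- function(x) rownames(x$counts)

#' Tissue labels present in an expression matrix
#' @param x a `tissue_expr` object.
#' @export
tissues <- function(x) UseMethod("tissues")

#' @export
tissues.tissue_expr <- function(x) unique(as.character(x$samples$tissue))

# columns belonging to one tissue (errors on unknown/empty tissue)
tissue_columns <- function(x, tissue) {
  idx <- which(x$samples$tissue == tissue)
  if (length(idx) == 0L) stop_input("tissue has no samples: ", tissue)
  idx
}

#' Counts per million
#'
#' CPM = count * 1e6 / library size, with library size the per-sample total
#' count. Errors if any sample has zero total, naming the sample.
#'
#' @param x a `tissue_expr` object.
#' @return numeric matrix of CPM values.
#' @export
cpm <- function(x) {
  lib <- colSums(x$counts)
  if (any(lib == 0)) {
    stop_input("zero library size for sample(s): ",
               paste(colnames(x$counts)[lib == 0], collapse = ", "))
  }
  sweep(x$counts, 2, lib / 1e6, "/")
}

#' Detection filter on counts per million
#'
#' A gene is retained iff its CPM is at least `min_cpm` in at least
#' `min_samples` samples (defaults: 1 CPM in 5 samples).
#'
#' @param x a `tissue_expr` object.
#' @param min_cpm CPM detection threshold.
#' @param min_samples minimum number of samples meeting the threshold.
#' @return character vector of retained gene ids.
#' @export
cpm_filter <- function(x, min_cpm = 1, min_samples = 5) {
  stopifnot(min_cpm >= 0, is_count(min_samples))
  keep <- rowSums(cpm(x) >= min_cpm) >= min_samples
  rownames(x$counts)[keep]
}

#' Log-transformed RPKM layer
#'
#' All log-RPKM thresholds in the calling rules use `log2(rpkm + 1)` by
#' default; base and pseudocount are configurable.
#'
#' @param x a `tissue_expr` object.
#' @param base logarithm base.
#' @param pseudocount added before taking logs.
#' @return numeric gene x sample matrix.
#' @export
log_rpkm <- function(x, base = 2, pseudocount = 1) {
  log(x$rpkm + pseudocount, base = base)
}

#' Write / read an expression matrix as TSV
#'
#' The expression TSV has genes as rows and a header row of sample ids; the
#' metadata TSV has columns sample_id, tissue, replicate, dataset. Count and
#' RPKM layers are written side by side as `<stem>_counts.tsv`,
#' `<stem>_rpkm.tsv` and `<stem>_samples.tsv`.
#'
#' @param x a `tissue_expr` object.
#' @param stem path stem for the three files.
#' @return invisibly, the vector of files written.
#' @export
write_tissue_expr <- function(x, stem) {
  files <- paste0(stem, c("_counts.tsv", "_rpkm.tsv", "_samples.tsv"))
  write_matrix_tsv(x$counts, files[1])
  write_matrix_tsv(x$rpkm, files[2])
  write.table(x$samples, files[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(files)
}

#' @rdname write_tissue_expr
#' @export
read_tissue_expr <- function(stem) {
  counts <- read_matrix_tsv(paste0(stem, "_counts.tsv"))
  rpkm <- read_matrix_tsv(paste0(stem, "_rpkm.tsv"))
  samples <- read.delim(paste0(stem, "_samples.tsv"), stringsAsFactors = FALSE)
  tissue_expr(counts, rpkm, samples)
}

write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
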