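#' Single-dataset expression matrix
#'
#' @param id dataset identifier.
#' @param mat gene x sample numeric matrix; may contain missing values.
#' @param platform free-form platform tag.
#' @return object of class `expr_dataset`.
#' @export
expr_dataset <- function(id, mat, platform = "unknown") {
  mat <- as.matrix(mat)
  if (ncol(mat) < 1) stop_input("dataset needs at least one sample")
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    stop_input("dataset needs unique gene rownames")
  }
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("s%03d", seq_len(ncol(mat)))
  }
  structure(list(id = id, mat = mat, platform = platform),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("Expression dataset", x$id, ":", nrow(x$mat), "genes x", ncol(x$mat),
      "samples (", x$platform, ")\n")
  invisible(x)
}

#' Collapse duplicate samples by group mean
#'
#' Samples sharing a key are replaced by their per-gene mean; missing values
#' are ignored in the mean (a group that is missing everywhere stays missing).
#'
#' @param dataset an [expr_dataset()].
#' @param key character/factor of length `ncol`, the sample grouping; must
#'   cover every sample.
#' @return an [expr_dataset()] with one column per group, in first-appearance
#'   order.
#' @export
collapse_duplicates <- function(dataset, key) {
  mat <- dataset$mat
  if (length(key) != ncol(mat)) {
    stop_input("grouping must cover all ", ncol(mat), " samples")
  }
  if (anyNA(key)) stop_input("grouping contains missing keys")
  key <- as.character(key)
  groups <- unique(key)
  out <- vapply(groups, function(g) {
    rowMeans(mat[, key == g, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(mat)))
  out[is.nan(out)] <- NA_real_
  expr_dataset(dataset$id, out, dataset$platform)
}

# rank-based inverse normal transform of one vector (ties -> average rank);
# NA preserved (imputed later), constant vectors handled by the caller
rank_inverse_normal <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  r <- rank(x[ok], ties.method = "average")
  x[ok] <- qnorm((r - 0.5) / n)
  x
}

#' Normalize a dataset to the standard normal distribution
#'
#' Per gene within the dataset: `rank_inverse_normal` maps the rank r of n
#' values to `qnorm((r - 0.5)/n)` (ties get average ranks); `zscore` maps to
#' `(x - mean)/sd`. Constant genes are set to 0 with a note (their sd is
#' undefined). Missing values are imputed AFTER normalization as 0, the
#' cross-dataset neutral value.
#'
#' @param dataset an [expr_dataset()].
#' @param method `"rank_inverse_normal"` (default) or `"zscore"`.
#' @return a normalized [expr_dataset()] without missing values.
#' @export
normalize_dataset <- function(dataset,
                              method = c("rank_inverse_normal", "zscore")) {
  method <- match.arg(method)
  mat <- dataset$mat
  n_const <- 0L
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, ]
    ok <- !is.na(x)
    distinct <- length(unique(x[ok]))
    if (distinct <= 1L) {
      mat[i, ok] <- 0
      if (sum(ok) > 0L) n_const <- n_const + 1L
      next
    }
    mat[i, ] <- if (method == "rank_inverse_normal") {
      rank_inverse_normal(x)
    } else {
      (x - mean(x[ok])) / sd(x[ok])
    }
  }
  if (n_const > 0L) {
    message("normalize_dataset(", dataset$id, "): ", n_const,
            " constant gene(s) set to 0")
  }
  mat[is.na(mat)] <- 0
  expr_dataset(dataset$id, mat, dataset$platform)
}

#' Assemble normalized datasets into one compendium
#'
#' Column-wise concatenation over a shared gene universe. Genes absent from a
#' dataset get the value 0 in that dataset's columns and are flagged
#' `zero-filled`; measured cells keep their source values. The sample ->
#' dataset index is preserved.
#'
#' @param datasets list of normalized [expr_dataset()] objects.
#' @param universe gene id vector; must contain every measured gene. Defaults
#'   to the union of measured genes.
#' @return object of class `expr_compendium`: `mat` (dense, no missing
#'   values), `measured` (logical flag matrix), `samples` (data.frame with
#'   dataset, sample, column id).
#' @export
assemble_compendium <- function(datasets, universe = NULL) {
  stopifnot(length(datasets) >= 1)
  ids <- vapply(datasets, function(d) d$id, "")
  all_genes <- unique(unlist(lapply(datasets, function(d) rownames(d$mat))))
  if (is.null(universe)) universe <- sort(all_genes)
  if (!all(all_genes %in% universe)) {
    stop_input("universe must contain every measured gene")
  }
  cols <- unlist(lapply(datasets, function(d) {
    paste(d$id, colnames(d$mat), sep = ".")
  }))
  if (anyDuplicated(cols)) {
    stop_input("duplicate (dataset, sample) ids: ",
               paste(unique(cols[duplicated(cols)]), collapse = ", "))
  }
  mat <- matrix(0, length(universe), length(cols),
                dimnames = list(universe, cols))
  measured <- matrix(FALSE, length(universe), length(cols),
                     dimnames = list(universe, cols))
  at <- 0L
  for (d in datasets) {
    if (anyNA(d$mat)) {
      stop_input("dataset ", d$id, " contains missing values; normalize first")
    }
    j <- at + seq_len(ncol(d$mat))
    mat[rownames(d$mat), j] <- d$mat
    measured[rownames(d$mat), j] <- TRUE
    at <- at + ncol(d$mat)
  }
  stopifnot(all(is.finite(mat)))
  samples <- data.frame(
    dataset = rep(ids, vapply(datasets, function(d) ncol(d$mat), 1L)),
    sample = unlist(lapply(datasets, function(d) colnames(d$mat))),
    column = cols, stringsAsFactors = FALSE
  )
  structure(list(mat = mat, measured = measured, samples = samples),
            class = "expr_compendium")
}

#' @export
print.expr_compendium <- function(x, ...) {
  cat("Expression compendium:", nrow(x$mat), "genes x", ncol(x$mat),
      "samples across", length(unique(x$samples$dataset)), "datasets\n")
  cat(sprintf("  zero-filled cells: %.1f%%\n", 100 * mean(!x$measured)))
  invisible(x)
}

#' Write / read a compendium as TSV (matrix plus a flags companion file)
#'
#' @param compendium an [assemble_compendium()] object.
#' @param stem path stem; writes `<stem>.tsv`, `<stem>_measured.tsv` and
#'   `<stem>_samples.tsv`.
#' @export
write_compendium <- function(compendium, stem) {
  write_matrix_tsv(compendium$mat, paste0(stem, ".tsv"))
  write_matrix_tsv(compendium$measured * 1L, paste0(stem, "_measured.tsv"))
  write.table(compendium$samples, paste0(stem, "_samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' @rdname write_compendium
#' @export
read_compendium <- function(stem) {
  mat <- read_matrix_tsv(paste0(stem, ".tsv"))
  measured <- read_matrix_tsv(paste0(stem, "_measured.tsv")) == 1
  samples <- read.delim(paste0(stem, "_samples.tsv"), stringsAsFactors = FALSE)
  structure(list(mat = mat, measured = measured, samples = samples),
            class = "expr_compendium")
}
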