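#' Call expressed genes per tissue
#'
#' A gene is expressed in a tissue iff the mean of `log2(rpkm + 1)` over that
#' tissue's replicates is strictly greater than `mean_cut` AND every replicate
#' is strictly greater than `rep_cut`.
#'
#' @param x a [tissue_expr()] object with an RPKM layer.
#' @param mean_cut threshold on the replicate mean (default 2).
#' @param rep_cut threshold every replicate must exceed (default 1).
#' @param base,pseudocount log convention, see [log_rpkm()].
#' @return named list: per tissue, a character vector of expressed gene ids.
#' @export
call_expressed <- function(x, mean_cut = 2, rep_cut = 1, base = 2, pseudocount = 1) {
  lr <- log_rpkm(x, base, pseudocount)
  out <- lapply(tissues(x), function(t) {
    cols <- tissue_columns(x, t)
    sub <- lr[, cols, drop = FALSE]
    keep <- rowMeans(sub) > mean_cut & apply(sub, 1, min) > rep_cut
    rownames(sub)[keep]
  })
  names(out) <- tissues(x)
  out
}

#' Expressed-by-mean gene sets (single-clause rule)
#'
#' Simpler membership rule used for pathway-target Venn partitioning: a gene
#' counts as expressed in a tissue iff its mean `log2(rpkm + 1)` over the
#' tissue's replicates is strictly greater than `cut`.
#'
#' @inheritParams call_expressed
#' @param cut threshold on the replicate mean (default 2).
#' @return named list of per-tissue gene id vectors.
#' @export
expressed_by_mean <- function(x, cut = 2, base = 2, pseudocount = 1) {
  lr <- log_rpkm(x, base, pseudocount)
  out <- lapply(tissues(x), function(t) {
    sub <- lr[, tissue_columns(x, t), drop = FALSE]
    rownames(sub)[rowMeans(sub) > cut]
  })
  names(out) <- tissues(x)
  out
}

# row-wise Welch two-sample t on log-expression matrices (genes x replicates).
# Zero-variance convention: if both groups are constant, p = 1 when the means
# are equal and p = 0 otherwise.
welch_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2 || n2 < 2) stop_input("Welch test needs >= 2 replicates per group")
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  list(estimate = m1 - m2, p = p)
}

#' Differential statistic for one tissue
#'
#' Computes, per gene, a log2 fold-change and a Welch two-sample t p-value on
#' `log2(rpkm + 1)`. Two contrasts are supported:
#' \describe{
#'   \item{`rest_average`}{the tissue against the average of the other
#'     tissues. The fold-change is the tissue mean minus the mean of the other
#'     tissues' per-tissue means (so unbalanced replicate counts do not bias
#'     the contrast); the p-value tests the tissue's replicates against the
#'     pooled replicates of the other tissues.}
#'   \item{`each_other`}{one comparison per other tissue (three comparisons
#'     for four tissues), each a tissue-vs-tissue fold-change and Welch test.}
#' }
#'
#' @param x a [tissue_expr()] object.
#' @param tissue target tissue label.
#' @param contrast `"rest_average"` or `"each_other"`.
#' @param base,pseudocount log convention.
#' @return for `rest_average`, a data.frame (gene, logFC, p); for
#'   `each_other`, a named list of such data.frames, one per other tissue.
#' @export
differential_stat <- function(x, tissue,
                              contrast = c("rest_average", "each_other"),
                              base = 2, pseudocount = 1) {
  contrast <- match.arg(contrast)
  if (!tissue %in% tissues(x)) stop_input("unknown tissue: ", tissue)
  lr <- log_rpkm(x, base, pseudocount)
  others <- setdiff(tissues(x), tissue)
  a <- lr[, tissue_columns(x, tissue), drop = FALSE]
  if (contrast == "rest_average") {
    other_means <- vapply(
      others,
      function(o) rowMeans(lr[, tissue_columns(x, o), drop = FALSE]),
      numeric(nrow(lr))
    )
    if (is.null(dim(other_means))) { # single-gene input: keep matrix shape
      other_means <- matrix(other_means, nrow = nrow(lr),
                            dimnames = list(rownames(lr), others))
    }
    b <- lr[, x$samples$tissue %in% others, drop = FALSE]
    w <- welch_rows(a, b)
    data.frame(gene = rownames(lr),
               logFC = rowMeans(a) - rowMeans(other_means),
               p = w$p, row.names = NULL, stringsAsFactors = FALSE)
  } else {
    out <- lapply(others, function(o) {
      b <- lr[, tissue_columns(x, o), drop = FALSE]
      w <- welch_rows(a, b)
      data.frame(gene = rownames(lr), logFC = w$estimate, p = w$p,
                 row.names = NULL, stringsAsFactors = FALSE)
    })
    names(out) <- others
    out
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted q-values, monotone in p-rank and capped at 1. Input must
#' lie in `[0, 1]`.
#'
#' @param pvalues numeric vector of raw p-values.
#' @return numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop_input("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(pvalues, method = "BH")
}

#' Full gene-call table for a multi-tissue experiment
#'
#' Runs the complete calling chain: expressed sets, the rest-average and
#' each-other-tissue differential statistics with per-contrast BH adjustment,
#' and the enriched / unique rules. The thresholds interpret all `log(rpkm)`
#' cuts as `log2(rpkm + 1)`.
#'
#' Rules (strict `>` on expression and fold-change, non-strict on FDR):
#' * expressed: mean log-RPKM > `mean_cut` and every replicate > `rep_cut`;
#' * enriched: mean log-RPKM > `rpkm_cut`, q <= `fdr_cut` and logFC >
#'   `lfc_cut` against the average of the other tissues;
#' * unique: as enriched, but against each other tissue separately.
#'
#' @inheritParams call_expressed
#' @param rpkm_cut high-expression threshold on the tissue mean (default 5).
#' @param fdr_cut FDR threshold (default 0.05, non-strict).
#' @param lfc_cut log2 fold-change threshold (default 2, strict).
#' @return object of class `gene_calls` with elements `table` (per gene x
#'   tissue: mean and min replicate log-RPKM, logFC, p, q, flags), `pairwise`
#'   (per gene x tissue x other tissue), and the `expressed`, `enriched`,
#'   `unique` per-tissue gene sets.
#' @export
gene_calls <- function(x, mean_cut = 2, rep_cut = 1, rpkm_cut = 5,
                       fdr_cut = 0.05, lfc_cut = 2,
                       base = 2, pseudocount = 1) {
  lr <- log_rpkm(x, base, pseudocount)
  tls <- tissues(x)
  expressed <- call_expressed(x, mean_cut, rep_cut, base, pseudocount)

  tabs <- lapply(tls, function(t) {
    sub <- lr[, tissue_columns(x, t), drop = FALSE]
    de <- differential_stat(x, t, "rest_average", base, pseudocount)
    data.frame(gene = rownames(lr), tissue = t,
               mean_log_rpkm = rowMeans(sub),
               min_rep_log_rpkm = apply(sub, 1, min),
               logFC = de$logFC, p = de$p, q = bh_adjust(de$p),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, tabs)

  pw <- lapply(tls, function(t) {
    de <- differential_stat(x, t, "each_other", base, pseudocount)
    do.call(rbind, lapply(names(de), function(o) {
      data.frame(gene = de[[o]]$gene, tissue = t, other = o,
                 logFC = de[[o]]$logFC, p = de[[o]]$p,
                 q = bh_adjust(de[[o]]$p),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  })
  pairwise <- do.call(rbind, pw)

  calls <- structure(
    list(table = table, pairwise = pairwise, expressed = expressed,
         thresholds = list(mean_cut = mean_cut, rep_cut = rep_cut,
                           rpkm_cut = rpkm_cut, fdr_cut = fdr_cut,
                           lfc_cut = lfc_cut)),
    class = "gene_calls"
  )
  calls$enriched <- call_enriched(calls, rpkm_cut, fdr_cut, lfc_cut)
  calls$unique <- call_unique(calls, rpkm_cut, fdr_cut, lfc_cut)
  # flags on the long table; the chain unique => enriched => expressed holds
  # because the unique rule includes the enriched thresholds and expressed is
  # implied by mean_log_rpkm > rpkm_cut >= mean_cut with min rep handled below
  table$expressed <- mapply(function(g, t) g %in% expressed[[t]],
                            table$gene, table$tissue)
  table$enriched <- mapply(function(g, t) g %in% calls$enriched[[t]],
                           table$gene, table$tissue)
  table$unique <- mapply(function(g, t) g %in% calls$unique[[t]],
                         table$gene, table$tissue)
  calls$table <- table
  calls
}

#' @export
print.gene_calls <- function(x, ...) {
  cat("Gene calls across", length(x$expressed), "tissues\n")
  df <- data.frame(
    tissue = names(x$expressed),
    expressed = lengths(x$expressed),
    enriched = lengths(x$enriched[names(x$expressed)]),
    unique = lengths(x$unique[names(x$expressed)]),
    row.names = NULL
  )
  print(df)
  invisible(x)
}

#' Tissue-enriched gene sets
#'
#' A gene is enriched in a tissue iff its mean log-RPKM in that tissue exceeds
#' `rpkm_cut`, the rest-average contrast q-value is at most `fdr_cut`, the
#' rest-average logFC exceeds `lfc_cut`, and the gene passes the expressed
#' rule in that tissue.
#'
#' @param calls a [gene_calls()] object (must carry rest-average results).
#' @inheritParams gene_calls
#' @return named list of per-tissue enriched gene id vectors.
#' @export
call_enriched <- function(calls, rpkm_cut = 5, fdr_cut = 0.05, lfc_cut = 2) {
  if (!inherits(calls, "gene_calls") || is.null(calls$table)) {
    stop("rest-average differential results missing: run gene_calls() first")
  }
  tab <- calls$table
  out <- lapply(names(calls$expressed), function(t) {
    sub <- tab[tab$tissue == t, ]
    hit <- sub$mean_log_rpkm > rpkm_cut & sub$q <= fdr_cut & sub$logFC > lfc_cut
    intersect(sub$gene[hit], calls$expressed[[t]])
  })
  names(out) <- names(calls$expressed)
  out
}

#' Tissue-unique gene sets
#'
#' A gene is unique to a tissue iff it is highly expressed there (mean
#' log-RPKM > `rpkm_cut`) and, against *each* other tissue separately,
#' q <= `fdr_cut` and logFC > `lfc_cut`; unique genes are additionally
#' required to satisfy the enriched rule, making the subset relation
#' unique within enriched structural.
#'
#' @inheritParams call_enriched
#' @return named list of per-tissue unique gene id vectors.
#' @export
call_unique <- function(calls, rpkm_cut = 5, fdr_cut = 0.05, lfc_cut = 2) {
  if (!inherits(calls, "gene_calls") || is.null(calls$pairwise)) {
    stop("each-other-tissue differential results missing: run gene_calls() first")
  }
  enriched <- calls$enriched %||% call_enriched(calls, rpkm_cut, fdr_cut, lfc_cut)
  pw <- calls$pairwise
  tab <- calls$table
  out <- lapply(names(calls$expressed), function(t) {
    sub <- pw[pw$tissue == t, ]
    pass <- sub$q <= fdr_cut & sub$logFC > lfc_cut
    n_other <- length(unique(sub$other))
    all_pass <- tapply(pass, sub$gene, sum) == n_other
    cand <- names(all_pass)[all_pass]
    high <- tab$gene[tab$tissue == t & tab$mean_log_rpkm > rpkm_cut]
    intersect(intersect(cand, high), enriched[[t]])
  })
  names(out) <- names(calls$expressed)
  out
}

#' Venn partition of a gene set over tissue expression
#'
#' Partitions `gene_set` (restricted to genes expressed somewhere) into
#' disjoint blocks keyed by the exact combination of tissues in which each
#' gene is expressed; genes expressed nowhere are reported separately as the
#' `not_detected` remainder.
#'
#' @param gene_set character vector of gene ids (nonempty).
#' @param expressed_sets named list of per-tissue expressed gene id vectors,
#'   e.g. from [call_expressed()] or [expressed_by_mean()].
#' @return object of class `venn_partition`: `blocks` (named list keyed by
#'   `tissue1+tissue2+...`), `fractions` (share of `gene_set` per block) and
#'   `not_detected`.
#' @export
venn_partition <- function(gene_set, expressed_sets) {
  if (length(gene_set) == 0) stop_input("gene_set must be nonempty")
  gene_set <- unique(gene_set)
  tls <- names(expressed_sets)
  member <- vapply(expressed_sets, function(s) gene_set %in% s,
                   logical(length(gene_set)))
  if (length(gene_set) == 1L) member <- matrix(member, nrow = 1)
  key <- apply(member, 1, function(m) paste(tls[m], collapse = "+"))
  detected <- key != ""
  blocks <- split(gene_set[detected], key[detected])
  structure(
    list(blocks = blocks,
         fractions = vapply(blocks, length, 1L) / length(gene_set),
         not_detected = gene_set[!detected],
         tissues = tls),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition over tissues:", paste(x$tissues, collapse = ", "), "\n")
  for (k in names(x$blocks)) {
    cat(sprintf("  %-40s %4d (%.1f%%)\n", k, length(x$blocks[[k]]),
                100 * x$fractions[[k]]))
  }
  if (length(x$not_detected)) {
    cat("  not detected in any tissue:", length(x$not_detected), "\n")
  }
  invisible(x)
}

#' Spearman correlation of samples over tissue-enriched genes
#'
#' Sample-by-sample Spearman rank correlation of `log2(rpkm + 1)` restricted
#' to the union of the per-tissue enriched gene sets.
#'
#' @param x a [tissue_expr()] object.
#' @param enriched_sets named list of per-tissue enriched gene id vectors.
#' @return symmetric sample x sample correlation matrix with unit diagonal.
#' @export
enriched_correlation <- function(x, enriched_sets) {
  u <- unique(unlist(enriched_sets, use.names = FALSE))
  if (length(u) < 3) stop_input("need at least 3 enriched genes for correlation")
  cor(log_rpkm(x)[u, , drop = FALSE], method = "spearman")
}
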