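#' Precision-recall curve
#'
#' Items are sorted by score descending; tied scores enter together as a
#' single threshold step (no interpolation). At each step, precision =
#' TP/(TP+FP) and recall = TP/P.
#'
#' @param scores numeric prediction scores.
#' @param labels labels in {0,1} or {-1,+1} (anything positive counts as a
#'   positive); at least one positive and one negative required.
#' @return object of class `pr_curve`: data.frame `curve` with columns
#'   threshold, tp, fp, precision, recall, plus totals `n_pos`, `n_neg`.
#' @export
pr_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_input("scores/labels length mismatch")
  pos <- labels > 0
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("precision-recall undefined: need both classes", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # last index of each tied block
  step <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(p)[step]
  n_at <- step
  fp <- n_at - tp
  curve <- data.frame(
    threshold = s[step], tp = tp, fp = fp,
    precision = tp / n_at, recall = tp / n_pos
  )
  structure(list(curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat("Precision-recall curve:", x$n_pos, "positives,", x$n_neg,
      "negatives,", nrow(x$curve), "threshold steps\n")
  invisible(x)
}

#' @export
plot.pr_curve <- function(x, ...) {
  plot(x$curve$recall, x$curve$precision, type = "s", xlim = c(0, 1),
       ylim = c(0, 1), xlab = "recall", ylab = "precision", ...)
  invisible(x)
}

#' Precision at a recall target
#'
#' Precision at the first threshold step whose recall reaches the target
#' (no interpolation).
#'
#' @param curve a [pr_curve()] object.
#' @param recall_target recall in (0, 1] (default 0.10).
#' @return precision (scalar in \[0, 1\]).
#' @export
precision_at_recall <- function(curve, recall_target = 0.10) {
  if (!is.numeric(recall_target) || recall_target <= 0 || recall_target > 1) {
    stop_input("recall_target must lie in (0, 1]")
  }
  idx <- which(curve$curve$recall >= recall_target)[1]
  curve$curve$precision[idx]
}

#' Median of per-tissue precisions
#'
#' Standard median (mean of the middle two for even length).
#'
#' @param precisions numeric vector, nonempty.
#' @return scalar median.
#' @export
median_precision <- function(precisions) {
  if (length(precisions) == 0) stop_input("no precision values given")
  median(precisions)
}

#' Average normalized prediction score of gene sets per tissue
#'
#' For every gene set and tissue, the arithmetic mean of the normalized
#' prediction scores of the set's genes present in the prediction matrix;
#' genes absent from the matrix are counted and reported, and a fully absent
#' set is an error.
#'
#' @param predictions gene x tissue matrix of normalized scores, or a
#'   [tissue_svm()] fit (its `$predictions` are used).
#' @param gene_sets named list of gene id vectors.
#' @return object of class `tissue_score_summary`: `scores` (set x tissue
#'   matrix) and `missing` (genes per set absent from the predictions).
#' @export
gene_set_profile <- function(predictions, gene_sets) {
  if (inherits(predictions, "tissue_svm")) predictions <- predictions$predictions
  scores <- matrix(NA_real_, length(gene_sets), ncol(predictions),
                   dimnames = list(names(gene_sets), colnames(predictions)))
  missing <- setNames(integer(length(gene_sets)), names(gene_sets))
  for (i in seq_along(gene_sets)) {
    present <- intersect(gene_sets[[i]], rownames(predictions))
    missing[i] <- length(gene_sets[[i]]) - length(present)
    if (length(present) == 0) {
      stop_input("gene set entirely absent from predictions: ",
                 names(gene_sets)[i])
    }
    scores[i, ] <- colMeans(predictions[present, , drop = FALSE])
  }
  structure(list(scores = scores, missing = missing),
            class = "tissue_score_summary")
}

#' @export
print.tissue_score_summary <- function(x, ...) {
  cat("Gene-set x tissue average normalized scores\n")
  print(round(x$scores, 3))
  if (any(x$missing > 0)) {
    cat("genes missing from predictions:",
        paste(sprintf("%s=%d", names(x$missing)[x$missing > 0],
                      x$missing[x$missing > 0]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hypergeometric overlap of two gene sets
#'
#' Upper-tail test: p = P(X >= k), inclusive, for X hypergeometric with
#' universe size N, |A| successes and |B| draws, where k is the observed
#' overlap.
#'
#' @param setA,setB character vectors, both subsets of `universe`.
#' @param universe background gene universe.
#' @return list of class `overlap_result`: `n_A`, `n_B`, `n_universe`,
#'   `overlap`, `p`.
#' @export
hypergeom_overlap <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe)) {
    stop_input("both sets must lie within the universe")
  }
  k <- length(intersect(setA, setB))
  p <- phyper(k - 1, length(setA), length(universe) - length(setA),
              length(setB), lower.tail = FALSE)
  structure(list(n_A = length(setA), n_B = length(setB),
                 n_universe = length(universe), overlap = k, p = min(p, 1)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %d of |A|=%d, |B|=%d in N=%d: p = %.4g\n",
              x$overlap, x$n_A, x$n_B, x$n_universe, x$p))
  invisible(x)
}

#' Cross-species tissue overlap matrix
#'
#' Maps each worm tissue gene set through an ortholog table (many-to-many:
#' union of human partners, deduplicated, restricted to the universe), tests
#' it against every human tissue set with [hypergeom_overlap()], adjusts all
#' p-values jointly with Benjamini-Hochberg, and reports `-log10(q)` with
#' non-significant cells (q >= 0.05) masked as NA.
#'
#' @param worm_sets named list of worm tissue gene sets.
#' @param ortholog_map data.frame with columns `worm`, `human`.
#' @param human_sets named list of human tissue gene sets (subsets of
#'   `universe`).
#' @param universe human background gene universe.
#' @param q_cut significance mask threshold (default 0.05).
#' @return list of class `tissue_overlap`: matrices `overlap`, `p`, `q`,
#'   `neglog10_q` (masked), all worm x human.
#' @export
tissue_overlap_matrix <- function(worm_sets, ortholog_map, human_sets,
                                  universe, q_cut = 0.05) {
  if (!all(c("worm", "human") %in% names(ortholog_map))) {
    stop_input("ortholog_map needs columns worm, human")
  }
  universe <- unique(universe)
  nw <- length(worm_sets); nh <- length(human_sets)
  p <- k <- matrix(NA_real_, nw, nh,
                   dimnames = list(names(worm_sets), names(human_sets)))
  for (i in seq_len(nw)) {
    mapped <- unique(ortholog_map$human[ortholog_map$worm %in% worm_sets[[i]]])
    mapped <- intersect(mapped, universe)
    for (j in seq_len(nh)) {
      if (length(mapped) == 0) { # empty mapped set: k = 0, p = 1, not an error
        k[i, j] <- 0; p[i, j] <- 1
      } else {
        res <- hypergeom_overlap(mapped, intersect(human_sets[[j]], universe),
                                 universe)
        k[i, j] <- res$overlap; p[i, j] <- res$p
      }
    }
  }
  q <- matrix(bh_adjust(as.vector(p)), nw, nh, dimnames = dimnames(p))
  nlq <- -log10(q)
  nlq[q >= q_cut] <- NA_real_
  structure(list(overlap = k, p = p, q = q, neglog10_q = nlq, q_cut = q_cut),
            class = "tissue_overlap")
}

#' Gene-set enrichment over a flat annotation table
#'
#' One upper-tail hypergeometric test per term against `gene_set`, BH across
#' terms; terms with q < 0.05 are flagged significant.
#'
#' @param gene_set character vector, subset of `universe`.
#' @param term_sets named list: term -> gene set (subsets of `universe`).
#' @param universe background gene universe.
#' @param q_cut strict significance threshold (default 0.05).
#' @return data.frame (term, n_term, overlap, p, q, significant) sorted by p.
#' @export
set_enrichment <- function(gene_set, term_sets, universe, q_cut = 0.05) {
  if (length(term_sets) == 0) stop_input("empty annotation table")
  res <- lapply(term_sets, function(ts) {
    hypergeom_overlap(unique(ts), gene_set, universe)
  })
  out <- data.frame(
    term = names(term_sets),
    n_term = vapply(res, function(r) r$n_A, 1L),
    overlap = vapply(res, function(r) r$overlap, 1L),
    p = vapply(res, function(r) r$p, 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < q_cut
  out[order(out$p, out$term), ]
}
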