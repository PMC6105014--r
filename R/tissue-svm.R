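#' Fit per-tissue linear SVM tissue-expression models
#'
#' The package's central fitting function. For every tissue in the gold
#' standard it builds a training problem on the compendium (rows = labeled
#' genes, features = compendium samples), selects the regularization constant
#' by stratified `folds`-fold cross-validation maximizing precision at
#' `recall_target`, refits on all labeled genes at the best cost, scores
#' every gene in the compendium (`w . x_g - b`), and normalizes each tissue's
#' genome-wide score vector to the standard normal scale (z-transform) so
#' scores are comparable across tissues.
#'
#' @param compendium an [assemble_compendium()] object.
#' @param gold_standard a [build_gold_standard()] object.
#' @param c_grid regularization constants to search.
#' @param folds cross-validation folds (default 5).
#' @param recall_target recall at which precision is read (default 0.10).
#' @param seed global seed; each tissue's fold assignment uses a seed derived
#'   from it, so runs are reproducible tissue by tissue.
#' @param tissues optional subset of gold-standard tissues to model.
#' @return object of class `tissue_svm` with elements `models` (per-tissue
#'   [linear_svm()] fits), `cv` (per-tissue cross-validation summaries),
#'   `predictions` (gene x tissue normalized scores), `raw` (raw scores),
#'   `flags` (gene x tissue gold-standard status), `performance` (per-tissue
#'   held-out precision at the recall target, best cost, prior), and
#'   `norm` (per-tissue score mean/sd used for the z-transform).
#' @seealso [summary.tissue_svm()], [predict.tissue_svm()],
#'   [sample_contributions()]
#' @export
tissue_svm <- function(compendium, gold_standard,
                       c_grid = c(0.01, 0.1, 1, 10), folds = 5,
                       recall_target = 0.10, seed = 1L, tissues = NULL) {
  stopifnot(inherits(compendium, "expr_compendium"),
            inherits(gold_standard, "gold_standard"))
  tissues <- tissues %||% names(gold_standard$tissues)
  genes_all <- rownames(compendium$mat)
  models <- list(); cv <- list(); perf <- list(); heldout <- list()
  raw <- matrix(NA_real_, length(genes_all), length(tissues),
                dimnames = list(genes_all, tissues))
  flags <- matrix("unlabeled", length(genes_all), length(tissues),
                  dimnames = list(genes_all, tissues))
  for (t in tissues) {
    gs <- gold_standard$tissues[[t]]
    if (is.null(gs)) stop_input("tissue absent from gold standard: ", t)
    pos <- intersect(gs$positives, genes_all)
    neg <- intersect(gs$negatives, genes_all)
    dropped <- length(gs$positives) + length(gs$negatives) -
      length(pos) - length(neg)
    if (dropped > 0) {
      warning(dropped, " labeled gene(s) absent from the compendium for ", t,
              call. = FALSE)
    }
    labeled <- c(pos, neg)
    y <- rep(c(1, -1), c(length(pos), length(neg)))
    x <- compendium$mat[labeled, , drop = FALSE]
    res <- tryCatch(
      svm_cross_validate(x, y, folds = folds, c_grid = c_grid,
                         recall_target = recall_target,
                         seed = derive_seed(seed, t)),
      error = function(e) stop("cross-validation failed for tissue ", t, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    fit <- linear_svm(x, y, cost = res$best_c)
    names(fit$w) <- colnames(compendium$mat)
    models[[t]] <- fit
    cv[[t]] <- res
    heldout[[t]] <- list(scores = setNames(res$heldout, labeled), labels = y)
    raw[, t] <- drop(compendium$mat %*% fit$w) - fit$b
    flags[pos, t] <- "positive"
    flags[neg, t] <- "negative"
    perf[[t]] <- data.frame(
      tissue = t, n_pos = length(pos), n_neg = length(neg),
      prior = gs$prior, best_c = res$best_c,
      precision_at_target = res$precision_at_target,
      stringsAsFactors = FALSE
    )
  }
  mu <- colMeans(raw); sdv <- apply(raw, 2, sd)
  if (any(sdv == 0)) {
    stop("degenerate model: constant genome-wide scores for tissue(s) ",
         paste(tissues[sdv == 0], collapse = ", "), call. = FALSE)
  }
  predictions <- sweep(sweep(raw, 2, mu, "-"), 2, sdv, "/")
  structure(
    list(models = models, cv = cv, predictions = predictions, raw = raw,
         flags = flags, performance = do.call(rbind, perf),
         heldout = heldout, norm = list(mean = mu, sd = sdv),
         recall_target = recall_target,
         samples = compendium$samples),
    class = "tissue_svm"
  )
}

#' @export
print.tissue_svm <- function(x, ...) {
  cat("Per-tissue linear SVM tissue-expression models\n")
  cat("  tissues:", length(x$models), " features (samples):",
      length(x$models[[1]]$w), "\n")
  cat(sprintf("  median held-out precision at %d%% recall: %.3f\n",
              round(100 * x$recall_target),
              median_precision(x$performance$precision_at_target)))
  invisible(x)
}

#' Summarize a tissue SVM fit
#'
#' @param object a [tissue_svm()] fit.
#' @param ... unused.
#' @return data.frame: tissue, class sizes, prior, selected cost, held-out
#'   precision at the recall target.
#' @export
summary.tissue_svm <- function(object, ...) {
  df <- object$performance
  rownames(df) <- NULL
  df
}

#' @export
coef.tissue_svm <- function(object, ...) {
  vapply(object$models, function(m) m$w, numeric(length(object$models[[1]]$w)))
}

#' Predict normalized tissue-expression scores for new genes
#'
#' Applies each tissue model to new feature rows (same compendium sample
#' axis) and normalizes with the training-time per-tissue mean and sd.
#'
#' @param object a [tissue_svm()] fit.
#' @param newdata gene x sample matrix over the same samples, or an
#'   `expr_compendium`; defaults to the fit's own (normalized) predictions.
#' @param type `"normalized"` (default) or `"raw"`.
#' @param ... unused.
#' @return gene x tissue score matrix.
#' @export
predict.tissue_svm <- function(object, newdata = NULL,
                               type = c("normalized", "raw"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(if (type == "normalized") object$predictions else object$raw)
  }
  if (inherits(newdata, "expr_compendium")) newdata <- newdata$mat
  raw <- vapply(names(object$models), function(t) {
    predict(object$models[[t]], newdata)
  }, numeric(nrow(newdata)))
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1,
                                       dimnames = list(rownames(newdata),
                                                       names(object$models)))
  if (type == "raw") return(raw)
  sweep(sweep(raw, 2, object$norm$mean[colnames(raw)], "-"), 2,
        object$norm$sd[colnames(raw)], "/")
}

#' Z-normalize raw prediction scores
#'
#' Standard-normal transform of a genome-wide raw score vector:
#' `(s - mean(s)) / sd(s)`. Affine transforms of the input give identical
#' output; constant scores are an error (degenerate model).
#'
#' @param raw_scores numeric vector with at least two distinct values.
#' @return numeric vector with mean 0 and sd 1.
#' @export
normalize_scores <- function(raw_scores) {
  s <- sd(raw_scores)
  if (!is.finite(s) || s == 0) {
    stop("degenerate model: scores have no spread", call. = FALSE)
  }
  (raw_scores - mean(raw_scores)) / s
}

#' Rank compendium samples by their contribution to each tissue model
#'
#' For a linear SVM, larger (signed) feature weights indicate higher
#' relevance; samples are ranked by weight descending (rank 1 = largest),
#' with ties broken lexicographically by sample id for determinism.
#'
#' @param fit a [tissue_svm()] fit (all models share one sample axis).
#' @return object of class `sample_weight_report`: `ranks` (sample x tissue
#'   integer matrix, each column a permutation of 1..n samples) and
#'   `weights`.
#' @export
sample_contributions <- function(fit) {
  stopifnot(inherits(fit, "tissue_svm"))
  w <- coef(fit)
  ranks <- apply(w, 2, function(col) {
    ord <- order(-col, rownames(w))
    r <- integer(length(col)); r[ord] <- seq_along(col); r
  })
  rownames(ranks) <- rownames(w)
  structure(list(ranks = ranks, weights = w), class = "sample_weight_report")
}

#' Genes with similar tissue-expression profiles
#'
#' Cosine similarity between one gene's row of normalized prediction scores
#' and every other gene's row; the basis of "similar profile" lookups.
#'
#' @param predictions gene x tissue normalized score matrix or a
#'   [tissue_svm()] fit.
#' @param gene query gene id.
#' @param n number of neighbours to return.
#' @return data.frame (gene, cosine) of the `n` most similar genes,
#'   excluding the query itself.
#' @export
profile_similarity <- function(predictions, gene, n = 10) {
  if (inherits(predictions, "tissue_svm")) predictions <- predictions$predictions
  if (!gene %in% rownames(predictions)) stop_input("unknown gene: ", gene)
  q <- predictions[gene, ]
  qn <- sqrt(sum(q^2))
  norms <- sqrt(rowSums(predictions^2))
  ok <- norms > 0 & qn > 0
  cosine <- drop(predictions %*% q) / (norms * qn)
  cosine[!ok] <- NA_real_
  cosine <- cosine[setdiff(names(cosine), gene)]
  top <- head(order(-cosine), n)
  data.frame(gene = names(cosine)[top], cosine = unname(cosine[top]),
             stringsAsFactors = FALSE)
}

#' @export
print.sample_weight_report <- function(x, ...) {
  cat("Sample contribution ranks (rank 1 = largest weight)\n")
  for (t in colnames(x$ranks)) {
    top <- rownames(x$ranks)[order(x$ranks[, t])][1:min(3, nrow(x$ranks))]
    cat("  ", t, ": top samples ", paste(top, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
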