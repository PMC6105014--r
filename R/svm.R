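#' Linear soft-margin support vector machine
#'
#' Fits the primal problem
#' \deqn{\min_{w, b, \xi} \tfrac12 w^T w + c \sum_i \xi_i
#'   \quad \text{s.t.} \quad y_i (w \cdot x_i - b) \ge 1 - \xi_i,\ \xi_i \ge 0}
#' by solving its dual with a maximal-violating-pair SMO scheme (analytic
#' two-variable updates, LIBSVM-style working-set selection). Note the sign
#' convention: the decision value of a point x is `w . x - b`.
#'
#' The dual is solved to a KKT-violation tolerance `tol`; at the solution the
#' primal and dual objectives agree to within the duality gap, and reported
#' slacks satisfy `xi_i = max(0, 1 - y_i (w . x_i - b))`.
#'
#' @param x numeric feature matrix, one row per training example.
#' @param y labels in {-1, +1} (or a two-level factor mapped to them).
#' @param cost positive regularization constant c of the primal.
#' @param tol stopping tolerance on the maximal KKT violation.
#' @param max_iter iteration cap (a warning is raised if reached).
#' @return object of class `linear_svm` with elements `w` (named by feature),
#'   `b`, `cost`, `alpha`, `xi`, `support` (indices with alpha > 0),
#'   `objective` (primal value), `dual_objective`, `iterations`, `converged`.
#' @export
linear_svm <- function(x, y, cost = 1, tol = 1e-8, max_iter = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop_input("non-finite feature values")
  if (is.factor(y)) y <- ifelse(y == levels(y)[1], 1, -1)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop_input("labels must be -1/+1")
  if (length(unique(y)) < 2) stop("training requires both classes", call. = FALSE)
  if (length(y) != nrow(x)) stop_input("length(y) must equal nrow(x)")
  stopifnot(cost > 0)
  n <- nrow(x)
  if (is.null(max_iter)) max_iter <- max(20000L, 500L * n)

  K <- tcrossprod(x)
  Q <- (y %o% y) * K
  alpha <- numeric(n)
  G <- rep(-1, n) # gradient of the dual objective 1/2 a'Qa - e'a
  tau <- 1e-12
  it <- 0L
  repeat {
    # maximal violating pair over -y_i G_i
    yg <- -y * G
    up <- (y > 0 & alpha < cost) | (y < 0 & alpha > 0)
    low <- (y < 0 & alpha < cost) | (y > 0 & alpha > 0)
    m_val <- max(yg[up]); M_val <- min(yg[low])
    if (m_val - M_val < tol || it >= max_iter) break
    i <- which(up)[which.max(yg[up])]
    j <- which(low)[which.min(yg[low])]
    it <- it + 1L

    ai_old <- alpha[i]; aj_old <- alpha[j]
    if (y[i] != y[j]) {
      quad <- Q[i, i] + Q[j, j] + 2 * Q[i, j]
      if (quad <= 0) quad <- tau
      delta <- (-G[i] - G[j]) / quad
      diff <- alpha[i] - alpha[j]
      alpha[i] <- alpha[i] + delta
      alpha[j] <- alpha[j] + delta
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] <- 0; alpha[i] <- diff }
      } else {
        if (alpha[i] < 0) { alpha[i] <- 0; alpha[j] <- -diff }
      }
      if (diff > 0) {
        if (alpha[i] > cost) { alpha[i] <- cost; alpha[j] <- cost - diff }
      } else {
        if (alpha[j] > cost) { alpha[j] <- cost; alpha[i] <- cost + diff }
      }
    } else {
      quad <- Q[i, i] + Q[j, j] - 2 * Q[i, j]
      if (quad <= 0) quad <- tau
      delta <- (G[i] - G[j]) / quad
      s <- alpha[i] + alpha[j]
      alpha[i] <- alpha[i] - delta
      alpha[j] <- alpha[j] + delta
      if (s > cost) {
        if (alpha[i] > cost) { alpha[i] <- cost; alpha[j] <- s - cost }
      } else {
        if (alpha[j] < 0) { alpha[j] <- 0; alpha[i] <- s }
      }
      if (s > cost) {
        if (alpha[j] > cost) { alpha[j] <- cost; alpha[i] <- s - cost }
      } else {
        if (alpha[i] < 0) { alpha[i] <- 0; alpha[j] <- s }
      }
    }
    G <- G + Q[, i] * (alpha[i] - ai_old) + Q[, j] * (alpha[j] - aj_old)
  }
  converged <- it < max_iter
  if (!converged) {
    warning("linear_svm: iteration cap reached before tolerance", call. = FALSE)
  }

  w <- drop(crossprod(x, alpha * y))
  names(w) <- colnames(x)
  # offset from free support vectors (fall back to the violation interval)
  yg <- -y * G
  free <- alpha > tau & alpha < cost - tau
  b_std <- if (any(free)) mean(-y[free] * G[free]) else {
    up <- (y > 0 & alpha < cost) | (y < 0 & alpha > 0)
    low <- (y < 0 & alpha < cost) | (y > 0 & alpha > 0)
    (max(yg[up]) + min(yg[low])) / 2
  }
  b <- -b_std # printed-primal convention: decision = w.x - b
  f <- drop(x %*% w) - b
  xi <- pmax(0, 1 - y * f)
  model <- structure(
    list(w = w, b = b, cost = cost, alpha = alpha, xi = xi,
         support = which(alpha > tau),
         objective = 0.5 * sum(w^2) + cost * sum(xi),
         dual_objective = sum(alpha) - 0.5 * sum(alpha * (Q %*% alpha)),
         iterations = it, converged = converged),
    class = "linear_svm"
  )
  model
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("Linear soft-margin SVM (decision = w.x - b)\n")
  cat(sprintf("  features: %d, cost c = %g\n", length(x$w), x$cost))
  cat(sprintf("  support vectors: %d, primal objective: %.6g\n",
              length(x$support), x$objective))
  invisible(x)
}

#' @export
coef.linear_svm <- function(object, ...) object$w

#' Decision values for new points
#'
#' @param object a [linear_svm()] model.
#' @param newdata matrix with the model's features as columns.
#' @param ... unused.
#' @return numeric vector `newdata %*% w - b`.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$w)) {
    stop_input("newdata has ", ncol(newdata), " features; model expects ",
               length(object$w))
  }
  if (!is.null(colnames(newdata)) && !is.null(names(object$w))) {
    missing <- setdiff(names(object$w), colnames(newdata))
    if (length(missing)) {
      stop_input("newdata lacks model feature(s): ",
                 paste(head(missing, 5), collapse = ", "))
    }
    newdata <- newdata[, names(object$w), drop = FALSE]
  }
  drop(newdata %*% object$w) - object$b
}

#' Stratified cross-validation with selection by precision at recall
#'
#' Splits labeled examples into `folds` stratified random partitions; for
#' each cost in `c_grid` and each fold, trains on the remaining folds and
#' scores the held-out fold. The best cost maximizes the mean per-fold
#' precision at `recall_target`; every labeled example receives exactly one
#' held-out score (from the fold that excluded it) at the best cost.
#'
#' @inheritParams linear_svm
#' @param folds number of folds (default 5).
#' @param c_grid costs to evaluate.
#' @param recall_target recall at which precision is read off (default 0.10).
#' @param seed integer seed for the fold assignment.
#' @return list: `best_c`, `cv_precision` (cost x fold matrix), `heldout`
#'   (score per example at the best cost), `fold` (fold of each example),
#'   `precision_at_target` (from the pooled held-out scores at the best cost).
#' @export
svm_cross_validate <- function(x, y, folds = 5, c_grid = c(0.01, 0.1, 1, 10),
                               recall_target = 0.10, seed = 1L) {
  x <- as.matrix(x); y <- as.numeric(y)
  n_pos <- sum(y == 1); n_neg <- sum(y == -1)
  if (n_pos < folds || n_neg < folds) {
    stop("cross-validation requires at least `folds` examples per class",
         call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(1, -1)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  prec <- matrix(NA_real_, length(c_grid), folds,
                 dimnames = list(paste0("c=", c_grid), NULL))
  scores <- array(NA_real_, c(length(c_grid), length(y)))
  for (ci in seq_along(c_grid)) {
    for (f in seq_len(folds)) {
      test <- fold == f
      fit <- linear_svm(x[!test, , drop = FALSE], y[!test], cost = c_grid[ci])
      s <- predict(fit, x[test, , drop = FALSE])
      scores[ci, test] <- s
      prec[ci, f] <- precision_at_recall(pr_curve(s, y[test]), recall_target)
    }
  }
  mean_prec <- rowMeans(prec)
  best <- which(mean_prec == max(mean_prec))[1] # ties -> smallest cost
  heldout <- scores[best, ]
  stopifnot(!anyNA(heldout)) # every example scored exactly once, out of fold
  list(best_c = c_grid[best], cv_precision = prec, mean_precision = mean_prec,
       heldout = heldout, fold = fold,
       precision_at_target = precision_at_recall(pr_curve(heldout, y),
                                                 recall_target))
}
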