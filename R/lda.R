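#' Exhaustive linear-discriminant subset ranking
#'
#' Fits multi-class LDA by the between/within scatter generalized
#' eigenproblem, evaluates every protein subset of the requested sizes by
#' resubstitution confusion-matrix accuracy, finds the minimal subset size
#' achieving perfect accuracy, and ranks proteins by how often they occur
#' in the perfect minimal subsets.
#'
#' @name subset_lda
NULL

# Within- and between-class scatter matrices and class summaries.
scatter_matrices <- function(x, g) {
  classes <- levels(g)
  n <- nrow(x); k <- ncol(x)
  grand <- colMeans(x)
  W <- matrix(0, k, k)
  B <- matrix(0, k, k)
  means <- matrix(0, length(classes), k,
                  dimnames = list(classes, colnames(x)))
  for (cl in classes) {
    xc <- x[g == cl, , drop = FALSE]
    m <- colMeans(xc)
    means[cl, ] <- m
    xc <- sweep(xc, 2, m)
    W <- W + crossprod(xc)
    d <- m - grand
    B <- B + nrow(xc) * tcrossprod(d)
  }
  list(W = W, B = B, means = means, grand = grand, n = n,
       n_class = table(g))
}

# Cholesky of W with ridge fallback (epsilon * trace added to the diagonal
# when W is singular, e.g. collinear proteins with n = 26 samples).
chol_with_ridge <- function(W, ridge = 1e-8) {
  R <- tryCatch(chol(W), error = function(e) NULL)
  used_ridge <- FALSE
  if (is.null(R)) {
    eps <- ridge * max(sum(diag(W)), 1)
    R <- chol(W + diag(eps, nrow(W)))
    used_ridge <- TRUE
  }
  list(R = R, used_ridge = used_ridge)
}

#' Fit a linear discriminant model
#'
#' Solves the generalized eigenproblem of the between-class scatter against
#' the within-class scatter (via Cholesky reduction to a symmetric
#' eigenproblem). Discriminant directions are scaled so that the pooled
#' within-class covariance of the scores is the identity (the convention of
#' standard LDA implementations, so scores agree up to sign). A singular
#' within-class scatter is ridge-regularized (`ridge * trace` on the
#' diagonal) and flagged, so exhaustive subset enumeration never aborts.
#'
#' Classification of the training samples uses the pooled-covariance
#' Gaussian discriminant rule with class-proportion priors; the
#' resubstitution confusion matrix and its accuracy
#' (`trace(confusion)/n`) are part of the fit.
#'
#' @param x Numeric matrix, samples in rows, features (proteins) in
#'   columns.
#' @param labels Factor (or coercible) of class labels, at least 2 classes
#'   with at least 2 samples each.
#' @param ridge Ridge epsilon relative to `trace(W)` used only when the
#'   within-class scatter is singular (default `1e-8`).
#' @return An object of class `lda_fit`: class `means`, `scaling`
#'   (directions), `eigenvalues`, `ld_proportions` (eigenvalue / trace
#'   fractions, non-increasing, summing to 1), per-sample `scores`,
#'   `confusion`, `accuracy`, and `used_ridge`.
#' @export
fit_lda <- function(x, labels, ridge = 1e-8) {
  x <- as.matrix(x)
  g <- droplevels(as.factor(labels))
  if (nlevels(g) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(table(g) < 2)) stop("every class needs at least 2 samples",
                              call. = FALSE)
  if (nrow(x) != length(g)) stop("labels do not match rows", call. = FALSE)
  sc <- scatter_matrices(x, g)
  ch <- chol_with_ridge(sc$W, ridge)
  Rinv <- backsolve(ch$R, diag(ncol(x)))
  S <- crossprod(Rinv, sc$B) %*% Rinv
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  r <- min(ncol(x), nlevels(g) - 1L)
  lambda <- pmax(e$values[seq_len(r)], 0)
  V <- Rinv %*% e$vectors[, seq_len(r), drop = FALSE]
  # scale directions: unit pooled within-class variance of scores
  pooled <- sc$W / (sc$n - nlevels(g))
  for (j in seq_len(r)) {
    s2 <- drop(crossprod(V[, j], pooled %*% V[, j]))
    if (s2 > 0) V[, j] <- V[, j] / sqrt(s2)
  }
  colnames(V) <- paste0("LD", seq_len(r))
  scores <- sweep(x, 2, sc$grand) %*% V
  pred <- classify_pooled(x, sc, ch$R)
  confusion <- table(truth = g, predicted = factor(pred, levels = levels(g)))
  structure(
    list(means = sc$means, scaling = V, eigenvalues = lambda,
         ld_proportions = if (sum(lambda) > 0) lambda / sum(lambda)
                          else rep(1 / r, r),
         scores = scores, labels = g,
         confusion = confusion,
         accuracy = sum(diag(confusion)) / sc$n,
         used_ridge = ch$used_ridge),
    class = "lda_fit"
  )
}

# Gaussian discriminant classification with pooled covariance and
# class-proportion priors, reusing the Cholesky factor of W.
classify_pooled <- function(x, sc, R) {
  n <- sc$n
  classes <- rownames(sc$means)
  dfw <- n - length(classes)
  # pooled covariance = W / dfw; R is chol(W) so chol(pooled) = R / sqrt(dfw)
  Rp <- R / sqrt(dfw)
  z <- t(backsolve(Rp, t(x), transpose = TRUE))      # whitened samples
  mu <- t(backsolve(Rp, t(sc$means), transpose = TRUE))
  priors <- as.numeric(sc$n_class[classes]) / n
  delta <- z %*% t(mu) -
    matrix(0.5 * rowSums(mu^2), nrow(x), length(classes), byrow = TRUE) +
    matrix(log(priors), nrow(x), length(classes), byrow = TRUE)
  classes[max.col(delta, ties.method = "first")]
}

#' @export
print.lda_fit <- function(x, ...) {
  cat(sprintf("lda_fit: %d discriminants, resubstitution accuracy %.4f\n",
              ncol(x$scaling), x$accuracy))
  cat("  proportion of trace:",
      paste(sprintf("%s %.4f", colnames(x$scaling), x$ld_proportions),
            collapse = ", "), "\n")
  invisible(x)
}

# Lean resubstitution accuracy used inside the exhaustive search: the
# classifier of fit_lda without eigen decomposition or score export.
lda_resub_accuracy <- function(x, g, ridge = 1e-8) {
  sc <- scatter_matrices(x, g)
  ch <- chol_with_ridge(sc$W, ridge)
  pred <- classify_pooled(x, sc, ch$R)
  mean(pred == as.character(g))
}

#' Exact binomial coefficient
#'
#' @param n,k Non-negative integers with `k <= n`.
#' @return `choose(n, k)` as an exact integer-valued number.
#' @export
comb_count <- function(n, k) {
  if (!is_count(n, min = 0) || !is_count(k, min = 0)) {
    stop("`n` and `k` must be non-negative integers", call. = FALSE)
  }
  if (k > n) stopf("k (%d) exceeds n (%d)", k, n)
  out <- choose(n, k)
  if (out > 2^53) stop("binomial coefficient exceeds exact integer range",
                       call. = FALSE)
  round(out)
}

#' Exhaustive LDA subset search
#'
#' Evaluates every subset of the candidate proteins at each requested size
#' by LDA resubstitution accuracy, in lexicographic order over the stable
#' candidate order. The minimal size at which at least one subset reaches
#' accuracy 1 defines the perfect minimal combinations; the search still
#' covers the full requested size range for reporting.
#'
#' @param pm A complete log2-scale [protein_matrix()], or a plain numeric
#'   matrix (proteins in rows, samples in columns) with row names.
#' @param candidates Character vector of candidate protein ids (rows of the
#'   matrix); defaults to all rows.
#' @param sizes Integer vector of subset sizes to enumerate (default
#'   `2:5`).
#' @param labels Optional class labels; defaults to the design groups of
#'   `pm`.
#' @param ridge Ridge epsilon passed to the LDA fit.
#' @return An object of class `subset_ranking`: `evaluated` (data frame
#'   with `subset`, `size`, `accuracy` for every enumerated subset),
#'   `minimal_size` (`NA` if no perfect subset in range), `perfect_subsets`
#'   (list of id vectors at the minimal size), `perfect_by_size`, and
#'   `n_candidates`.
#' @export
subset_search <- function(pm, candidates = NULL, sizes = 2:5,
                          labels = NULL, ridge = 1e-8) {
  if (inherits(pm, "protein_matrix")) {
    if (anyNA(pm$assay)) stop("subset_search needs a complete matrix",
                              call. = FALSE)
    mat <- pm$assay
    labels <- labels %||% pm$design$group
  } else {
    mat <- as.matrix(pm)
    if (is.null(labels)) stop("`labels` required for a plain matrix",
                              call. = FALSE)
  }
  candidates <- candidates %||% rownames(mat)
  absent <- setdiff(candidates, rownames(mat))
  if (length(absent)) stopf("candidate(s) absent from matrix: %s",
                            paste(absent, collapse = ", "))
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1) || any(sizes > length(candidates))) {
    stop("subset sizes must be between 1 and the number of candidates",
         call. = FALSE)
  }
  g <- droplevels(as.factor(labels))
  X <- t(mat[candidates, , drop = FALSE])  # samples x candidates

  evaluated <- vector("list", length(sizes))
  perfect_by_size <- stats::setNames(vector("list", length(sizes)),
                                     as.character(sizes))
  for (si in seq_along(sizes)) {
    k <- sizes[si]
    combs <- utils::combn(length(candidates), k)
    acc <- numeric(ncol(combs))
    for (ci in seq_len(ncol(combs))) {
      acc[ci] <- lda_resub_accuracy(X[, combs[, ci], drop = FALSE], g, ridge)
    }
    keys <- apply(combs, 2, function(ix) paste(candidates[ix],
                                               collapse = "+"))
    evaluated[[si]] <- data.frame(subset = keys, size = k, accuracy = acc,
                                  stringsAsFactors = FALSE)
    perfect_by_size[[si]] <- lapply(which(acc == 1),
                                    function(ci) candidates[combs[, ci]])
  }
  evaluated <- do.call(rbind, evaluated)
  n_perfect <- vapply(perfect_by_size, length, 0L)
  minimal_size <- if (any(n_perfect > 0)) sizes[which(n_perfect > 0)[1L]]
                  else NA_integer_
  if (is.na(minimal_size)) {
    warnf("no perfect subset found in sizes %s",
          paste(range(sizes), collapse = ".."))
  }
  structure(
    list(evaluated = evaluated,
         minimal_size = minimal_size,
         perfect_subsets = if (is.na(minimal_size)) list()
                           else perfect_by_size[[as.character(minimal_size)]],
         perfect_by_size = perfect_by_size,
         n_candidates = length(candidates),
         sizes = sizes),
    class = "subset_ranking"
  )
}

#' @export
print.subset_ranking <- function(x, ...) {
  cat(sprintf("subset_ranking: %d candidates, sizes %s, %d subsets evaluated\n",
              x$n_candidates, paste(x$sizes, collapse = ","),
              nrow(x$evaluated)))
  if (is.na(x$minimal_size)) {
    cat("  no perfect subset in range\n")
  } else {
    cat(sprintf("  minimal perfect size: %d (%d perfect subset(s))\n",
                x$minimal_size, length(x$perfect_subsets)))
  }
  invisible(x)
}

#' Rank proteins by occurrence frequency in perfect subsets
#'
#' @param perfect_subsets Non-empty list of protein id vectors (e.g.
#'   `subset_ranking$perfect_subsets`).
#' @param omnibus_p Optional named numeric vector of omnibus p-values used
#'   as the secondary (ascending) tie-break key; ties after that break by
#'   name order.
#' @return A list with `ranking` (data frame `protein`, `frequency`,
#'   ordered), `union` (all proteins in any perfect subset) and
#'   `more_than_once` (proteins occurring in more than one subset).
#' @export
rank_by_frequency <- function(perfect_subsets, omnibus_p = NULL) {
  if (length(perfect_subsets) == 0L) {
    stop("no perfect subsets to rank", call. = FALSE)
  }
  all_ids <- unlist(perfect_subsets, use.names = FALSE)
  freq <- table(all_ids)
  ids <- names(freq)
  p2 <- if (is.null(omnibus_p)) rep(0, length(ids))
        else {
          p <- omnibus_p[ids]
          p[is.na(p)] <- Inf
          p
        }
  ord <- order(-as.integer(freq), p2, ids)
  ranking <- data.frame(protein = ids[ord],
                        frequency = as.integer(freq)[ord],
                        stringsAsFactors = FALSE)
  list(ranking = ranking,
       union = ranking$protein,
       more_than_once = ranking$protein[ranking$frequency > 1])
}

#' Export LD1/LD2 sample coordinates for a bi-plot
#'
#' @param fit An [fit_lda()] result with at least 1 discriminant.
#' @param labels Optional labels overriding those stored in the fit.
#' @return Data frame with `sample`, `group`, `LD1` and (for 3 or more
#'   classes) `LD2`.
#' @export
biplot_export <- function(fit, labels = NULL) {
  stopifnot(inherits(fit, "lda_fit"))
  g <- labels %||% fit$labels
  scores <- fit$scores
  out <- data.frame(sample = rownames(scores) %||%
                      sprintf("S%02d", seq_len(nrow(scores))),
                    group = as.character(g),
                    LD1 = scores[, 1],
                    stringsAsFactors = FALSE)
  if (ncol(scores) >= 2) out$LD2 <- scores[, 2]
  rownames(out) <- NULL
  out
}

#' Centroid separation summary of an LDA fit
#'
#' Mean pairwise Euclidean distance between class centroids in discriminant
#' space — a numeric stand-in for visually checking bi-plot group overlap.
#'
#' @param fit An [fit_lda()] result.
#' @return A single number: the mean pairwise centroid distance.
#' @export
centroid_separation <- function(fit) {
  stopifnot(inherits(fit, "lda_fit"))
  cent <- apply(fit$scores, 2, tapply, fit$labels, mean)
  mean(stats::dist(cent))
}
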