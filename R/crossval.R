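#' Specification of the repeated cross-validation stage
#'
#' The predictive-power evaluation: for each feature set, a stratified
#' 70/30 train/test split per partitioning seed, repeated (3 repeats)
#' 4-fold stratified cross-validation of a three-class multinomial logistic
#' model on the training side (reported, no tuning), a refit on the full
#' training side, and confusion-matrix accuracy on the untouched 30 percent
#' test side.
#'
#' @param folds Number of inner CV folds (default 4).
#' @param repeats Number of inner CV repeats (default 3).
#' @param train_fraction Outer training fraction (default 0.70).
#' @param seeds Integer vector of partitioning seeds (default
#'   `base_seed + 0:9`, ten seeds).
#' @param base_seed Base used when `seeds` is not given.
#' @param decay Fixed mild L2 penalty of the multinomial fit; small-sample
#'   multinomial fits on separable data do not converge unpenalized.
#' @param perfect_rule `"all_seeds"` (a feature set is perfect iff its test
#'   accuracy is 1 for every seed, default) or `"mean"` (mean test accuracy
#'   across seeds equals 1 — equivalent in exact arithmetic, kept as an
#'   explicit switch).
#' @return An object of class `cv_spec`.
#' @export
cv_spec <- function(folds = 4, repeats = 3, train_fraction = 0.70,
                    seeds = NULL, base_seed = 1L, decay = 0.01,
                    perfect_rule = c("all_seeds", "mean")) {
  perfect_rule <- match.arg(perfect_rule)
  if (!is_count(folds, min = 2)) stop("`folds` must be >= 2", call. = FALSE)
  if (!is_count(repeats)) stop("`repeats` must be >= 1", call. = FALSE)
  if (!is_number(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  seeds <- seeds %||% (as.integer(base_seed) + 0:9)
  if (length(seeds) < 1) stop("need at least one seed", call. = FALSE)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 train_fraction = train_fraction,
                 seeds = as.integer(seeds), decay = decay,
                 perfect_rule = perfect_rule),
            class = "cv_spec")
}

#' Stratified train/test partition
#'
#' Per class, `round(train_fraction * n)` samples (clamped so both sides
#' keep at least one sample of every class) go to the training side after a
#' seeded within-class shuffle; the remainder form the test side. For
#' groups of 11/6/9 at fraction 0.7 the training side is 8/4/6 and the test
#' side 3/2/3.
#'
#' @param labels Factor (or coercible) of class labels, each class with at
#'   least 2 samples.
#' @param train_fraction Fraction in (0, 1).
#' @param seed Integer seed; identical seed gives an identical partition.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_partition <- function(labels, train_fraction, seed) {
  g <- droplevels(as.factor(labels))
  if (any(table(g) < 2)) {
    stop("every class needs at least 2 samples to appear on both sides",
         call. = FALSE)
  }
  with_seed(seed, {
    train <- integer(0)
    for (cl in levels(g)) {
      idx <- which(g == cl)
      n_tr <- round(train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train <- c(train, sample(idx)[seq_len(n_tr)])
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(g), train))
  })
}

# Per-class deal of indices into k stratified folds (seeded shuffle).
stratified_folds <- function(labels, k, seed) {
  g <- droplevels(as.factor(labels))
  with_seed(seed, {
    fold <- integer(length(g))
    for (cl in levels(g)) {
      idx <- sample(which(g == cl))
      fold[idx] <- rep_len(sample(k), length(idx))
    }
    fold
  })
}

# Multinomial logistic fit with fixed mild L2; stronger regularization is
# retried once on non-convergence. Features are standardized with
# training-side statistics so the penalty acts on comparable coefficients
# (log2 abundances sit far from zero, which would otherwise push the
# penalized intercepts off the data).
fit_multinom <- function(x, y, decay) {
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- scale(x, center = center, scale = scale_)
  df <- data.frame(y = y, xs, check.names = FALSE)
  fit <- nnet::multinom(y ~ ., data = df, decay = decay, trace = FALSE,
                        maxit = 500)
  if (fit$convergence != 0) {
    fit <- nnet::multinom(y ~ ., data = df, decay = decay * 10,
                          trace = FALSE, maxit = 1000)
    attr(fit, "retried") <- TRUE
  }
  list(fit = fit, center = center, scale = scale_)
}

predict_multinom <- function(model, x) {
  xs <- scale(x, center = model$center, scale = model$scale)
  as.character(stats::predict(model$fit,
                              newdata = data.frame(xs,
                                                   check.names = FALSE)))
}

#' Evaluate one feature set under one partitioning seed
#'
#' @param pm A complete [protein_matrix()] (or plain matrix, proteins in
#'   rows, with `labels` supplied).
#' @param features Protein ids forming the feature set (1 or more).
#' @param spec A [cv_spec()].
#' @param seed Partitioning seed.
#' @param labels Optional labels for a plain matrix.
#' @return A one-row data frame: `features`, `seed`, `cv_accuracy` (mean
#'   over the `repeats * folds` inner fold fits) and `test_accuracy`
#'   (confusion-matrix accuracy on the held-out test side).
#' @export
evaluate_feature_set <- function(pm, features, spec, seed, labels = NULL) {
  stopifnot(inherits(spec, "cv_spec"))
  if (inherits(pm, "protein_matrix")) {
    mat <- pm$assay
    labels <- labels %||% pm$design$group
  } else {
    mat <- as.matrix(pm)
    if (is.null(labels)) stop("`labels` required for a plain matrix",
                              call. = FALSE)
  }
  absent <- setdiff(features, rownames(mat))
  if (length(absent)) stopf("feature(s) absent from matrix: %s",
                            paste(absent, collapse = ", "))
  g <- droplevels(as.factor(labels))
  X <- t(mat[features, , drop = FALSE])
  colnames(X) <- make.names(features)

  part <- stratified_partition(g, spec$train_fraction, seed)
  x_tr <- X[part$train, , drop = FALSE]; y_tr <- droplevels(g[part$train])
  x_te <- X[part$test, , drop = FALSE];  y_te <- g[part$test]

  # inner repeated stratified CV on the training side (reporting only)
  fold_acc <- numeric(0)
  for (rep_i in seq_len(spec$repeats)) {
    fold <- stratified_folds(y_tr, spec$folds,
                             seed = stage_seed(seed, 100L + rep_i))
    for (f in seq_len(spec$folds)) {
      hold <- fold == f
      if (all(hold) || !any(hold)) next
      if (nlevels(droplevels(y_tr[!hold])) < nlevels(y_tr)) next
      fit <- fit_multinom(x_tr[!hold, , drop = FALSE], y_tr[!hold],
                          spec$decay)
      pred <- predict_multinom(fit, x_tr[hold, , drop = FALSE])
      fold_acc <- c(fold_acc, mean(pred == as.character(y_tr[hold])))
    }
  }
  fit <- fit_multinom(x_tr, y_tr, spec$decay)
  pred <- predict_multinom(fit, x_te)
  data.frame(features = paste(features, collapse = "+"),
             seed = seed,
             cv_accuracy = mean(fold_acc),
             test_accuracy = mean(pred == as.character(y_te)),
             stringsAsFactors = FALSE)
}

#' Enumerate all candidate pairs and count perfect feature sets
#'
#' Evaluates every pair of candidate proteins (all `choose(n, 2)`
#' combinations) with [evaluate_feature_set()] under every seed of the
#' spec, flags the pairs whose held-out test accuracy satisfies the perfect
#' rule, and tallies per-protein occurrence among the perfect pairs.
#'
#' @param pm A complete [protein_matrix()] (or plain matrix plus `labels`).
#' @param candidates At least 2 candidate protein ids.
#' @param spec A [cv_spec()].
#' @param labels Optional labels for a plain matrix.
#' @param include_singles Also evaluate every single-protein feature set
#'   (default `TRUE`; singles are reported but only pairs enter the
#'   perfect-pair count).
#' @return An object of class `cv_outcome`: `outcomes` (per feature set:
#'   size, mean/min test accuracy across seeds, mean inner CV accuracy,
#'   `perfect`), `per_seed` (raw rows), `n_perfect_pairs`, and `frequency`
#'   (data frame of protein occurrence counts among perfect pairs, summing
#'   to twice the number of perfect pairs).
#' @export
enumerate_pairs_and_count_perfect <- function(pm, candidates, spec,
                                              labels = NULL,
                                              include_singles = TRUE) {
  stopifnot(inherits(spec, "cv_spec"))
  if (length(candidates) < 2) stop("need at least 2 candidates",
                                   call. = FALSE)
  sets <- c(
    if (include_singles) lapply(candidates, identity) else list(),
    utils::combn(candidates, 2, simplify = FALSE)
  )
  per_seed <- vector("list", length(sets) * length(spec$seeds))
  k <- 0L
  for (fs in sets) {
    for (s in spec$seeds) {
      k <- k + 1L
      per_seed[[k]] <- evaluate_feature_set(pm, fs, spec, s, labels = labels)
    }
  }
  per_seed <- do.call(rbind, per_seed)
  agg <- do.call(rbind, lapply(split(per_seed, per_seed$features), function(d)
    data.frame(features = d$features[1L],
               size = length(strsplit(d$features[1L], "+", fixed = TRUE)[[1L]]),
               mean_cv_accuracy = mean(d$cv_accuracy),
               mean_test_accuracy = mean(d$test_accuracy),
               min_test_accuracy = min(d$test_accuracy),
               stringsAsFactors = FALSE)))
  agg$perfect <- if (spec$perfect_rule == "all_seeds") {
    agg$min_test_accuracy == 1
  } else {
    agg$mean_test_accuracy == 1
  }
  rownames(agg) <- NULL
  perfect_pairs <- agg$features[agg$perfect & agg$size == 2]
  members <- unlist(strsplit(perfect_pairs, "+", fixed = TRUE))
  freq <- sort(table(members), decreasing = TRUE)
  structure(
    list(outcomes = agg[order(-agg$mean_test_accuracy), , drop = FALSE],
         per_seed = per_seed,
         n_perfect_pairs = length(perfect_pairs),
         perfect_pairs = perfect_pairs,
         frequency = data.frame(protein = names(freq),
                                n_perfect_pairs = as.integer(freq),
                                stringsAsFactors = FALSE),
         spec = spec),
    class = "cv_outcome"
  )
}

#' @export
print.cv_outcome <- function(x, ...) {
  cat(sprintf(
    "cv_outcome: %d feature sets x %d seeds; %d perfect pair(s) (%s rule)\n",
    nrow(x$outcomes), length(x$spec$seeds), x$n_perfect_pairs,
    x$spec$perfect_rule))
  if (x$n_perfect_pairs > 0) {
    top <- utils::head(x$frequency, 3)
    cat("  top proteins in perfect pairs:",
        paste(sprintf("%s (%d)", top$protein, top$n_perfect_pairs),
              collapse = ", "), "\n")
  }
  invisible(x)
}
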