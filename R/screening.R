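#' Pearson pair-correlation screen
#'
#' All pairwise Pearson correlations between candidate proteins over the
#' pooled samples (all groups together), with the pairs exceeding a signed
#' threshold listed separately — strong positive co-abundance suggests
#' redundant panel members.
#'
#' @param pm A complete [protein_matrix()] or plain numeric matrix
#'   (proteins in rows, samples in columns).
#' @param candidates Protein ids to screen; defaults to all rows.
#' @param threshold Signed correlation threshold for a "strong" pair
#'   (default 0.6; negative correlations never qualify).
#' @return An object of class `correlation_screen`: `r` (symmetric
#'   correlation matrix, unit diagonal) and `strong_pairs` (data frame
#'   `protein_a`, `protein_b`, `r`, sorted by descending r).
#' @export
pearson_pair_screen <- function(pm, candidates = NULL, threshold = 0.6) {
  mat <- if (inherits(pm, "protein_matrix")) pm$assay else as.matrix(pm)
  candidates <- candidates %||% rownames(mat)
  absent <- setdiff(candidates, rownames(mat))
  if (length(absent)) stopf("candidate(s) absent from matrix: %s",
                            paste(absent, collapse = ", "))
  x <- t(mat[candidates, , drop = FALSE])   # samples x proteins
  if (nrow(x) < 3) stop("need at least 3 samples", call. = FALSE)
  if (anyNA(x)) stop("screen expects a complete (imputed) matrix",
                     call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warnf("zero-variance protein(s), correlations undefined: %s",
          paste(candidates[sds == 0], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  vals <- r[upper.tri(r)]
  keep <- !is.na(vals) & vals > threshold
  strong <- data.frame(protein_a = rownames(r)[ut[keep, 1]],
                       protein_b = colnames(r)[ut[keep, 2]],
                       r = vals[keep], stringsAsFactors = FALSE)
  strong <- strong[order(-strong$r), , drop = FALSE]
  rownames(strong) <- NULL
  structure(list(r = r, strong_pairs = strong, threshold = threshold),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("correlation_screen: %d proteins, %d pair(s) with r > %g\n",
              nrow(x$r), nrow(x$strong_pairs), x$threshold))
  invisible(x)
}

#' ROC area under the curve by the rank statistic
#'
#' AUC with a fixed orientation: the probability that a randomly chosen
#' positive-class score exceeds a randomly chosen negative-class score,
#' ties counting one half. The orientation is never flipped, so an AUC
#' below 0.5 reports a marker whose abundance decreases in the positive
#' class.
#'
#' @param scores Numeric scores (e.g. protein abundance).
#' @param labels Logical vector (or coercible), `TRUE` for the positive
#'   (disease) class; both classes must be present.
#' @return The AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(labels) || anyNA(scores)) {
    stop("scores and labels must be complete and of equal length",
         call. = FALSE)
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores)  # midranks: ties contribute 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Best achievable two-class accuracy over score thresholds
#'
#' Maximum confusion-matrix accuracy over all midpoint thresholds between
#' sorted distinct scores (plus the two trivial all-one-class rules), in
#' both orientations. Always at least the majority-class rate.
#'
#' @inheritParams roc_auc
#' @return The best threshold accuracy in \[0, 1\].
#' @export
accuracy_at_best_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(labels) || anyNA(scores)) {
    stop("scores and labels must be complete and of equal length",
         call. = FALSE)
  }
  if (all(labels) || !any(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  s <- sort(unique(scores))
  cuts <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  n <- length(labels)
  best <- 0
  for (cut in cuts) {
    acc_hi <- mean((scores > cut) == labels)   # positive above threshold
    best <- max(best, acc_hi, 1 - acc_hi)      # and the flipped rule
  }
  best
}

#' Per-protein ROC screening table
#'
#' For each candidate protein, two-class ROC metrics for the contrasts
#' N vs P and N vs D with the disease group (P or D) as the positive class
#' and abundance as the score: AUC (fixed orientation) and best-threshold
#' accuracy.
#'
#' @param pm A complete [protein_matrix()].
#' @param candidates Protein ids (rows) to screen.
#' @param accuracy_rule `"best_threshold"` (default) or `"lda"`
#'   (resubstitution accuracy of a single-feature two-class LDA), two
#'   readings of a per-protein accuracy column.
#' @return Data frame, one row per candidate: `protein`, `auc_N_vs_P`,
#'   `accuracy_N_vs_P`, `auc_N_vs_D`, `accuracy_N_vs_D`.
#' @export
screening_table <- function(pm, candidates,
                            accuracy_rule = c("best_threshold", "lda")) {
  stopifnot(inherits(pm, "protein_matrix"))
  accuracy_rule <- match.arg(accuracy_rule)
  absent <- setdiff(candidates, rownames(pm$assay))
  if (length(absent)) stopf("candidate(s) absent from matrix: %s",
                            paste(absent, collapse = ", "))
  g <- pm$design$group
  one_acc <- function(scores, lab) {
    if (accuracy_rule == "best_threshold") {
      accuracy_at_best_threshold(scores, lab)
    } else {
      lda_resub_accuracy(matrix(scores, ncol = 1),
                         factor(ifelse(lab, "pos", "neg")))
    }
  }
  rows <- lapply(candidates, function(id) {
    v <- pm$assay[id, ]
    out <- list(protein = id)
    for (disease in c("P", "D")) {
      sel <- g %in% c("N", disease)
      lab <- g[sel] == disease
      sc <- v[sel]
      out[[paste0("auc_N_vs_", disease)]] <- roc_auc(sc, lab)
      out[[paste0("accuracy_N_vs_", disease)]] <- one_acc(sc, lab)
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[, c("protein", "accuracy_N_vs_D", "auc_N_vs_D",
          "accuracy_N_vs_P", "auc_N_vs_P")]
}
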