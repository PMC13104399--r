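# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive re-implementations, kept free of any
# package internals they are used to check.

# Small three-group design: 4 N, 3 P, 3 D.
small_design <- function() {
  group_design(sprintf("S%02d", 1:10), rep(c("N", "P", "D"), c(4, 3, 3)))
}

# Cohort-sized design: 11 N, 6 P, 9 D.
cohort_design <- function() {
  group_design(sprintf("S%02d", 1:26), rep(c("N", "P", "D"), c(11, 6, 9)))
}

# Linear-scale matrix with two flagged artifact rows and one missing cell.
small_pm <- function() {
  set.seed(101)
  design <- small_design()
  assay <- matrix(2^rnorm(50, 20, 1), nrow = 5,
                  dimnames = list(sprintf("PR%02d", 1:5), design$sample_id))
  assay[2, 3] <- NA
  rowdata <- data.frame(
    protein_group_id = rownames(assay),
    gene_names = paste0("G", 1:5),
    reverse = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    potential_contaminant = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    only_identified_by_site = FALSE,
    stringsAsFactors = FALSE
  )
  protein_matrix(assay, design, rowdata = rowdata)
}

# Complete log2-scale matrix with `n_marker` strongly separating proteins
# and `n_null` noise proteins. Marker shift patterns cycle through
# P-only up, D-only up, and graded P/D up, so a single marker cannot
# separate all three groups but complementary pairs can.
separable_pm <- function(n_marker = 3, n_null = 3, noise = 0.05,
                         seed = 7, design = cohort_design()) {
  set.seed(seed)
  g <- design$group
  patterns <- list(c(N = 0, P = 6, D = 0),
                   c(N = 0, P = 0, D = 6),
                   c(N = 0, P = 3, D = 6))
  rows <- lapply(seq_len(n_marker), function(i) {
    shift <- patterns[[(i - 1L) %% 3L + 1L]]
    20 + shift[as.character(g)] + rnorm(length(g), 0, noise)
  })
  null_rows <- lapply(seq_len(n_null), function(i) rnorm(length(g), 20, 1))
  assay <- do.call(rbind, c(rows, null_rows))
  dimnames(assay) <- list(
    c(sprintf("MARK%02d", seq_len(n_marker)),
      sprintf("NULL%02d", seq_len(n_null))),
    design$sample_id
  )
  protein_matrix(assay, design, log2 = TRUE)
}

# Independent Holm step-down oracle: sort, multiply by decreasing factors,
# enforce monotonicity by running maximum, cap at 1.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Independent AUC oracle: exhaustive positive-negative pair counting,
# ties worth one half.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Independent subset-search oracle built on MASS::lda resubstitution.
mass_resub_accuracy <- function(x, g) {
  fit <- suppressWarnings(MASS::lda(x, grouping = g))
  pred <- stats::predict(fit, x)$class
  mean(pred == g)
}

naive_subset_search <- function(mat, labels, candidates, sizes) {
  g <- factor(labels)
  out <- list()
  for (k in sizes) {
    for (ix in utils::combn(seq_along(candidates), k, simplify = FALSE)) {
      ids <- candidates[ix]
      acc <- mass_resub_accuracy(t(mat[ids, , drop = FALSE]), g)
      out[[paste(ids, collapse = "+")]] <- acc
    }
  }
  out
}
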