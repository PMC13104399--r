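#' Distribution-aware differential abundance testing
#'
#' Per protein, the omnibus test is chosen by a normality/homoscedasticity
#' decision tree (Shapiro-Wilk within each group, Levene across groups),
#' the matching pairwise post hoc family is applied to the three group
#' contrasts, and Holm step-down adjustment is applied across the three
#' contrasts within the protein.
#'
#' @name differential
NULL

CONTRASTS <- c("N-P", "N-D", "P-D")

# Shapiro-Wilk p with edge handling: n < 3 cannot be tested (treated as
# consistent with normality); a constant group is treated as non-normal.
shapiro_p <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) return(NA_real_)
  if (stats::sd(x) == 0) return(0)
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
}

levene_p <- function(values_by_group) {
  y <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group), lengths(values_by_group)))
  tryCatch(
    car::leveneTest(y, g, center = mean)[1, "Pr(>F)"],
    error = function(e) NA_real_
  )
}

#' Choose the omnibus and pairwise test family for one protein
#'
#' Decision tree: all groups consistent with normality (Shapiro-Wilk
#' p > `alpha_gate` in every testable group) and homoscedastic (Levene
#' p > `alpha_gate`) chooses the classic (Fisher) one-way ANOVA with pooled
#' two-sample t pairwise tests; normal but heteroscedastic chooses Welch's
#' ANOVA with Games-Howell pairwise tests; any non-normal group chooses the
#' Kruskal-Wallis rank sum test with Dunn pairwise tests.
#'
#' @param values_by_group Named list of numeric vectors (groups N, P, D),
#'   each with at least 2 values.
#' @param alpha_gate Gate level for the auxiliary tests (default 0.05).
#' @return A list with `test` (`"fisher_anova"`, `"welch_anova"` or
#'   `"kruskal_wallis"`), `normality_p` (named per group), `levene_p`, and
#'   `degenerate` (`TRUE` when all values are identical, in which case
#'   `test` is `NA`).
#' @export
choose_tests <- function(values_by_group, alpha_gate = 0.05) {
  check_three_groups(values_by_group)
  all_vals <- unlist(values_by_group, use.names = FALSE)
  if (stats::sd(all_vals) == 0) {
    return(list(test = NA_character_,
                normality_p = vapply(values_by_group, shapiro_p, 0),
                levene_p = NA_real_, degenerate = TRUE))
  }
  np <- vapply(values_by_group, shapiro_p, 0)
  lp <- levene_p(values_by_group)
  normal <- all(is.na(np) | np > alpha_gate)
  test <- if (!normal) "kruskal_wallis"
          else if (!is.na(lp) && lp <= alpha_gate) "welch_anova"
          else "fisher_anova"
  list(test = test, normality_p = np, levene_p = lp, degenerate = FALSE)
}

check_three_groups <- function(values_by_group) {
  if (length(values_by_group) != 2L && length(values_by_group) != 3L) {
    stop("expected a named list of 2 or 3 groups", call. = FALSE)
  }
  if (length(values_by_group) != 3L) {
    stop("three groups are required for the omnibus test", call. = FALSE)
  }
  if (any(lengths(lapply(values_by_group, stats::na.omit)) < 2)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  invisible(TRUE)
}

#' Omnibus three-group p-value
#'
#' @param values_by_group Named list of three numeric vectors.
#' @param test One of `"fisher_anova"`, `"welch_anova"`,
#'   `"kruskal_wallis"` (as chosen by [choose_tests()]).
#' @return The omnibus p-value.
#' @export
omnibus_pvalue <- function(values_by_group, test) {
  check_three_groups(values_by_group)
  y <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group), lengths(values_by_group)))
  switch(test,
    fisher_anova = stats::oneway.test(y ~ g, var.equal = TRUE)$p.value,
    welch_anova = stats::oneway.test(y ~ g, var.equal = FALSE)$p.value,
    kruskal_wallis = stats::kruskal.test(y, g)$p.value,
    stopf("unknown test: %s", test)
  )
}

# Games-Howell pairwise p for two groups within a k-group family:
# Welch t statistic referred to the studentized range distribution.
games_howell_p <- function(x, y, k) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) return(if (mean(x) == mean(y)) 1 else 0)
  t_stat <- abs(mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  stats::ptukey(t_stat * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
}

# Dunn pairwise z tests on the pooled Kruskal-Wallis ranking, with the
# standard ties correction.
dunn_pvalues <- function(values_by_group) {
  y <- unlist(values_by_group, use.names = FALSE)
  g <- rep(names(values_by_group), lengths(values_by_group))
  n <- length(y)
  r <- rank(y)
  ties <- table(y)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  labs <- names(values_by_group)
  out <- numeric(0)
  for (cn in utils::combn(labs, 2, simplify = FALSE)) {
    i <- cn[1]; j <- cn[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- if (se == 0) 0 else (mean_rank[[i]] - mean_rank[[j]]) / se
    out[paste(i, j, sep = "-")] <- 2 * stats::pnorm(-abs(z))
  }
  out
}

#' Pairwise contrasts with Holm adjustment
#'
#' Computes the three pairwise contrasts (N-P, N-D, P-D) with the post hoc
#' family matching the omnibus choice — pooled-variance Student t for
#' `fisher_anova`, Games-Howell for `welch_anova`, Dunn for
#' `kruskal_wallis` — attaches log2 fold changes (difference of group means
#' on the log2 scale, second group minus first), and applies Holm step-down
#' adjustment across the three contrasts within the protein.
#'
#' @inheritParams omnibus_pvalue
#' @return A data frame with columns `contrast`, `p_raw`, `p_holm`,
#'   `log2_fc`.
#' @export
pairwise_holm <- function(values_by_group, test) {
  check_three_groups(values_by_group)
  labs <- names(values_by_group)
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  p_raw <- vapply(pairs, function(cn) {
    x <- values_by_group[[cn[1]]]
    y <- values_by_group[[cn[2]]]
    switch(test,
      fisher_anova = tryCatch(
        stats::t.test(x, y, var.equal = TRUE)$p.value,
        error = function(e) if (mean(x) == mean(y)) 1 else 0),
      welch_anova = games_howell_p(x, y, k = length(values_by_group)),
      kruskal_wallis = NA_real_,  # filled below from the pooled ranking
      stopf("unknown test: %s", test))
  }, 0)
  if (test == "kruskal_wallis") {
    dp <- dunn_pvalues(values_by_group)
    p_raw <- dp[vapply(pairs, paste, "", collapse = "-")]
  }
  fc <- vapply(pairs, function(cn) {
    mean(values_by_group[[cn[2]]]) - mean(values_by_group[[cn[1]]])
  }, 0)
  data.frame(
    contrast = vapply(pairs, paste, "", collapse = "-"),
    p_raw = unname(p_raw),
    p_holm = stats::p.adjust(p_raw, method = "holm"),
    log2_fc = fc,
    stringsAsFactors = FALSE
  )
}

#' Differential testing of every protein in a matrix
#'
#' Runs [choose_tests()], [omnibus_pvalue()] and [pairwise_holm()] for each
#' protein of a complete (imputed) log2-scale matrix against the three-group
#' design.
#'
#' @param pm A complete log2-scale [protein_matrix()] (run
#'   [preprocess_pipeline()] first).
#' @param alpha_gate Gate level for the Shapiro-Wilk/Levene decision tree.
#' @return A data frame of class `differential_table`, one row per
#'   non-degenerate protein: identifiers, chosen test, per-group normality
#'   p, Levene p, omnibus p, and per-contrast raw p, Holm-adjusted p and
#'   log2 fold change. Degenerate (zero-variance) proteins are excluded and
#'   listed in the `degenerate` attribute.
#' @export
differential_table <- function(pm, alpha_gate = 0.05) {
  stopifnot(inherits(pm, "protein_matrix"))
  if (anyNA(pm$assay)) {
    stop("differential_table needs a complete (imputed) matrix",
         call. = FALSE)
  }
  ids <- rownames(pm$assay)
  g <- pm$design$group
  rows <- vector("list", length(ids))
  degenerate <- character(0)
  for (i in seq_along(ids)) {
    vbg <- split(pm$assay[i, ], g)
    ch <- choose_tests(vbg, alpha_gate)
    if (ch$degenerate) {
      degenerate <- c(degenerate, ids[i])
      next
    }
    op <- omnibus_pvalue(vbg, ch$test)
    pw <- pairwise_holm(vbg, ch$test)
    row <- data.frame(
      protein = ids[i],
      gene = pm$rowdata$gene_names[i],
      test = ch$test,
      normality_p_N = ch$normality_p[["N"]],
      normality_p_P = ch$normality_p[["P"]],
      normality_p_D = ch$normality_p[["D"]],
      levene_p = ch$levene_p,
      omnibus_p = op,
      stringsAsFactors = FALSE
    )
    for (k in seq_len(nrow(pw))) {
      key <- gsub("-", "_", pw$contrast[k])
      row[[paste0("p_", key)]] <- pw$p_raw[k]
      row[[paste0("padj_", key)]] <- pw$p_holm[k]
      row[[paste0("fc_", key)]] <- pw$log2_fc[k]
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  if (length(degenerate)) {
    message(sprintf("differential_table: %d degenerate protein(s) skipped",
                    length(degenerate)))
  }
  attr(out, "degenerate") <- degenerate
  class(out) <- c("differential_table", class(out))
  out
}

#' Select significantly changed proteins
#'
#' A protein is selected iff its omnibus p-value is below `alpha` and (by
#' default) at least one Holm-adjusted pairwise contrast is also below
#' `alpha`. The result is ordered by ascending omnibus p.
#'
#' @param results A [differential_table()].
#' @param alpha Significance threshold (default 0.05).
#' @param require_pairwise Require at least one significant Holm-adjusted
#'   pairwise contrast (default `TRUE`).
#' @return Character vector of selected protein identifiers, ordered by
#'   ascending omnibus p.
#' @export
select_significant <- function(results, alpha = 0.05,
                               require_pairwise = TRUE) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]",
                                    call. = FALSE)
  if (alpha == 1) {  # disable both gates: Holm p-values cap at exactly 1
    return(results$protein[order(results$omnibus_p)])
  }
  keep <- results$omnibus_p < alpha
  if (require_pairwise) {
    padj <- as.matrix(results[, grep("^padj_", names(results)), drop = FALSE])
    keep <- keep & apply(padj < alpha, 1, any)
  }
  sel <- results[keep, , drop = FALSE]
  sel$protein[order(sel$omnibus_p)]
}

#' Volcano export for one contrast
#'
#' Per protein: log2 fold change, -log10 of the non-adjusted pairwise p,
#' and the colour-coding category used in volcano plots — `"significant &
#' up"` / `"significant & down"` for raw p below `alpha` with |log2 FC|
#' above `fc_cut`, otherwise `"ns"`.
#'
#' @param results A [differential_table()].
#' @param contrast One of `"N-P"`, `"N-D"`, `"P-D"`.
#' @param alpha Significance threshold on the raw pairwise p (default 0.05).
#' @param fc_cut Absolute log2 fold-change cut (default 1).
#' @return Data frame with columns `protein`, `gene`, `log2_fc`,
#'   `neg_log10_p`, `category`.
#' @export
volcano_table <- function(results, contrast, alpha = 0.05, fc_cut = 1) {
  if (!contrast %in% CONTRASTS) {
    stopf("unknown contrast '%s' (expected one of %s)", contrast,
          paste(CONTRASTS, collapse = ", "))
  }
  key <- gsub("-", "_", contrast)
  p <- results[[paste0("p_", key)]]
  fc <- results[[paste0("fc_", key)]]
  category <- ifelse(p < alpha & fc > fc_cut, "significant & up",
              ifelse(p < alpha & fc < -fc_cut, "significant & down", "ns"))
  data.frame(protein = results$protein, gene = results$gene,
             log2_fc = fc, neg_log10_p = -log10(p), category = category,
             stringsAsFactors = FALSE)
}

#' Two-group test reusing the distribution-aware decision tree
#'
#' The two-sample branch used for qPCR group comparisons: both groups
#' consistent with normality chooses Student's t (pooled) when Levene
#' accepts homoscedasticity, otherwise Welch's t; any non-normal group
#' chooses the Wilcoxon rank sum test.
#'
#' @param x,y Numeric vectors (two groups, each with at least 2 values).
#' @param alpha_gate Gate level for the auxiliary tests.
#' @return List with `test` (`"student_t"`, `"welch_t"` or
#'   `"wilcoxon"`) and `p`.
#' @export
two_group_test <- function(x, y, alpha_gate = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  np <- c(shapiro_p(x), shapiro_p(y))
  normal <- all(is.na(np) | np > alpha_gate)
  if (!normal) {
    p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    return(list(test = "wilcoxon", p = p))
  }
  lp <- levene_p(list(a = x, b = y))
  if (!is.na(lp) && lp <= alpha_gate) {
    list(test = "welch_t", p = stats::t.test(x, y)$p.value)
  } else {
    list(test = "student_t",
         p = stats::t.test(x, y, var.equal = TRUE)$p.value)
  }
}
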