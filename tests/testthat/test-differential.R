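test_that("test choice follows the normality/homoscedasticity decision tree", {
  set.seed(201)
  # closed-form oracle under an exact three-group null: each Shapiro-Wilk
  # gate and the Levene gate passes with probability 0.95 independently,
  # so Fisher ANOVA is chosen with probability ~0.95^4 = 0.8145
  n_rep <- 300
  picks <- replicate(n_rep, {
    vbg <- list(N = rnorm(30), P = rnorm(30), D = rnorm(30))
    choose_tests(vbg)$test
  })
  frac_fisher <- mean(picks == "fisher_anova")
  expect_gt(frac_fisher, 0.8145 - 4 * sqrt(0.8145 * 0.1855 / n_rep))
  expect_lt(frac_fisher, 0.8145 + 4 * sqrt(0.8145 * 0.1855 / n_rep))
  # heavy-tailed group routes to Kruskal-Wallis with high probability
  picks_kw <- replicate(100, {
    vbg <- list(N = rnorm(30), P = rnorm(30), D = rcauchy(30))
    choose_tests(vbg)$test
  })
  expect_gt(mean(picks_kw == "kruskal_wallis"), 0.9)
  # normal but strongly heteroscedastic: Welch branch dominates
  picks_w <- replicate(100, {
    vbg <- list(N = rnorm(30, sd = 1), P = rnorm(30, sd = 6),
                D = rnorm(30, sd = 1))
    choose_tests(vbg)$test
  })
  expect_gt(mean(picks_w == "welch_anova"), 0.8)
  # identical values: degenerate flag
  res <- choose_tests(list(N = rep(1, 5), P = rep(1, 5), D = rep(1, 5)))
  expect_true(res$degenerate)
  expect_true(is.na(res$test))
})

test_that("omnibus p-values are uniform under the null and powerful under shift", {
  set.seed(202)
  p_null <- replicate(400, {
    vbg <- list(N = rnorm(10), P = rnorm(10), D = rnorm(10))
    omnibus_pvalue(vbg, "fisher_anova")
  })
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.01)
  # one group shifted by 10 sd: overwhelming evidence
  vbg <- list(N = rnorm(10), P = rnorm(10), D = rnorm(10, 10))
  expect_lt(omnibus_pvalue(vbg, "fisher_anova"), 1e-6)
  expect_lt(omnibus_pvalue(vbg, "welch_anova"), 1e-6)
  expect_lt(omnibus_pvalue(vbg, "kruskal_wallis"), 1e-4)
  # two groups violate the three-group contract
  expect_error(omnibus_pvalue(list(N = rnorm(5), P = rnorm(5)),
                              "fisher_anova"), "three groups")
})

test_that("Holm adjustment matches the independent step-down oracle", {
  # worked cases
  expect_equal(holm_oracle(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_oracle(c(0.5, 0.6, 0.9)), c(1, 1, 1))
  expect_equal(holm_oracle(0.2), 0.2)  # m = 1: adjusted equals raw
  # property: implementation's adjusted p equals the oracle, 1000 draws
  set.seed(203)
  for (i in 1:1000) {
    p <- runif(sample(2:6, 1))
    expect_equal(stats::p.adjust(p, method = "holm"), holm_oracle(p))
  }
  # pairwise_holm wires the oracle-checked adjustment across 3 contrasts
  set.seed(204)
  vbg <- list(N = rnorm(8), P = rnorm(8, 1), D = rnorm(8, 2))
  pw <- pairwise_holm(vbg, "fisher_anova")
  expect_equal(pw$p_holm, holm_oracle(pw$p_raw))
  expect_true(all(pw$p_holm >= pw$p_raw))
})

test_that("pairwise families match the omnibus choice and fold changes are antisymmetric", {
  set.seed(205)
  vbg <- list(N = rnorm(8, 20), P = rnorm(8, 21), D = rnorm(8, 22))
  for (test in c("fisher_anova", "welch_anova", "kruskal_wallis")) {
    pw <- pairwise_holm(vbg, test)
    expect_equal(pw$contrast, c("N-P", "N-D", "P-D"))
    expect_true(all(pw$p_raw >= 0 & pw$p_raw <= 1))
    # fold change = second group mean minus first
    expect_equal(pw$log2_fc[1], mean(vbg$P) - mean(vbg$N))
  }
  # antisymmetry: reversing a contrast flips the sign
  fc_nd <- pairwise_holm(vbg, "fisher_anova")$log2_fc[2]
  vbg_rev <- list(N = vbg$D, P = vbg$P, D = vbg$N)
  fc_rev <- pairwise_holm(vbg_rev, "fisher_anova")$log2_fc[2]
  expect_equal(fc_rev, -fc_nd)
  # pooled t branch agrees with stats::t.test
  expect_equal(pairwise_holm(vbg, "fisher_anova")$p_raw[1],
               t.test(vbg$N, vbg$P, var.equal = TRUE)$p.value)
  # Dunn z-approximation agrees with a direct hand computation (no ties)
  x <- list(N = c(1, 5, 9), P = c(2, 6, 10), D = c(20, 30, 40))
  r <- rank(unlist(x))
  mr <- tapply(r, rep(names(x), each = 3), mean)
  n <- 9
  se <- sqrt((n * (n + 1) / 12) * (2 / 3))
  z_nd <- (mr[["N"]] - mr[["D"]]) / se
  expect_equal(pairwise_holm(x, "kruskal_wallis")$p_raw[2],
               2 * pnorm(-abs(z_nd)))
})

test_that("selection rule keeps planted effects and controls the null", {
  sim <- generate_dataset(synthetic_spec(n_proteins = 200,
                                         n_differential = 4,
                                         effect_log2 = 4, seed = 51))
  pp <- preprocess_pipeline(sim$matrix, preprocess_params(seed = 52))
  res <- differential_table(pp$matrix)
  sel <- select_significant(res)
  expect_true(all(sim$truth$planted_ids %in% sel))
  # ordered by ascending omnibus p
  p_by_id <- setNames(res$omnibus_p, res$protein)
  expect_false(is.unsorted(p_by_id[sel]))
  # alpha = 1 selects every non-degenerate protein
  expect_length(select_significant(res, alpha = 1), nrow(res))
  # null matrix: selected fraction at most alpha
  null_sim <- generate_dataset(synthetic_spec(n_proteins = 400,
                                              n_differential = 0,
                                              missing_slope = 0,
                                              missing_mid = -Inf,
                                              seed = 53))
  null_pp <- preprocess_pipeline(null_sim$matrix,
                                 preprocess_params(seed = 54))
  null_res <- differential_table(null_pp$matrix)
  frac <- length(select_significant(null_res)) / nrow(null_res)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
  # the pairwise gate can only shrink the omnibus selection
  expect_lte(length(select_significant(null_res)),
             length(select_significant(null_res,
                                       require_pairwise = FALSE)))
})

test_that("volcano export applies the colour-coding rule and conserves rows", {
  res <- data.frame(protein = c("a", "b", "c"), gene = c("A", "B", "C"),
                    omnibus_p = c(0.001, 0.5, 0.001),
                    p_N_P = c(0.001, 0.5, 0.01),
                    padj_N_P = c(0.003, 1, 0.03),
                    fc_N_P = c(2, 0.5, -1.5),
                    stringsAsFactors = FALSE)
  v <- volcano_table(res, "N-P")
  expect_equal(v$category, c("significant & up", "ns", "significant & down"))
  expect_equal(v$neg_log10_p, -log10(res$p_N_P))
  expect_equal(nrow(v), nrow(res))
  expect_error(volcano_table(res, "X-Y"), "unknown contrast")
})

test_that("degenerate proteins are excluded and logged, not assigned NaN", {
  design <- small_design()
  assay <- rbind(const = rep(5, 10),
                 ok = c(rnorm(4, 20), rnorm(3, 22), rnorm(3, 24)))
  colnames(assay) <- design$sample_id
  pm <- protein_matrix(assay, design, log2 = TRUE)
  expect_message(res <- differential_table(pm), "degenerate")
  expect_equal(attr(res, "degenerate"), "const")
  expect_equal(res$protein, "ok")
  expect_false(anyNA(res$omnibus_p))
})

test_that("two-group branch picks t, Welch t or Wilcoxon appropriately", {
  set.seed(206)
  expect_equal(two_group_test(rnorm(20), rnorm(20))$test, "student_t")
  expect_equal(two_group_test(rnorm(40, sd = 1),
                              rnorm(40, sd = 8))$test, "welch_t")
  expect_equal(two_group_test(rcauchy(40), rnorm(40))$test, "wilcoxon")
})
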