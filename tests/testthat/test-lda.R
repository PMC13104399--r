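test_that("LDA fit matches the independent MASS oracle", {
  pm <- separable_pm(n_marker = 2, n_null = 2, noise = 1, seed = 61)
  x <- t(pm$assay)
  g <- pm$design$group
  fit <- fit_lda(x, g)
  mass <- MASS::lda(x, grouping = g)
  # proportion of trace
  expect_equal(unname(fit$ld_proportions),
               unname(mass$svd^2 / sum(mass$svd^2)), tolerance = 1e-8)
  # resubstitution predictions and confusion-matrix accuracy
  mass_pred <- predict(mass, x)$class
  expect_equal(fit$accuracy, mean(mass_pred == g))
  # scores agree up to per-axis sign
  mass_scores <- predict(mass, x)$x
  for (j in 1:2) {
    expect_equal(abs(cor(fit$scores[, j], mass_scores[, j])), 1,
                 tolerance = 1e-6)
  }
})

test_that("discriminant count, trace proportions and rank bounds hold", {
  set.seed(62)
  # two classes: exactly one discriminant with proportion 1
  x <- matrix(rnorm(40), 20, 2)
  g2 <- rep(c("a", "b"), 10)
  fit2 <- fit_lda(x, g2)
  expect_equal(ncol(fit2$scaling), 1)
  expect_equal(unname(fit2$ld_proportions), 1)
  # three classes, many features: at most 2 discriminants, proportions
  # sum to 1 and are non-increasing
  pm <- separable_pm(n_marker = 3, n_null = 4, noise = 0.5, seed = 63)
  fit3 <- fit_lda(t(pm$assay), pm$design$group)
  expect_equal(ncol(fit3$scaling), 2)
  expect_equal(sum(fit3$ld_proportions), 1, tolerance = 1e-9)
  expect_true(all(diff(fit3$ld_proportions) <= 0))
})

test_that("planted separable fixture reaches accuracy 1; permuted labels near chance", {
  pm <- separable_pm(n_marker = 2, n_null = 0, noise = 0.05, seed = 64)
  fit <- fit_lda(t(pm$assay), pm$design$group)
  expect_equal(fit$accuracy, 1)
  # label permutation: accuracy near the majority-class rate
  set.seed(65)
  null_acc <- replicate(30, {
    g_perm <- sample(pm$design$group)
    fit_lda(t(pm$assay), g_perm)$accuracy
  })
  expect_lt(mean(null_acc), 11 / 26 + 0.2)
})

test_that("singular within-class scatter is ridge-regularized, not fatal", {
  design <- small_design()
  assay <- rbind(a = c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3),
                 b = 2 * c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3))  # collinear
  colnames(assay) <- design$sample_id
  fit <- fit_lda(t(assay), design$group)
  expect_true(fit$used_ridge)
  expect_equal(fit$accuracy, 1)
})

test_that("binomial coefficients are exact", {
  expect_identical(comb_count(23, 5), 33649)
  expect_identical(comb_count(23, 2), 253)
  expect_identical(comb_count(10, 0), 1)
  expect_identical(comb_count(7, 7), 1)
  expect_error(comb_count(3, 4), "exceeds")
  expect_error(comb_count(-1, 0), "non-negative")
})

test_that("subset search is exhaustive and agrees with the naive oracle", {
  pm <- separable_pm(n_marker = 3, n_null = 4, noise = 1.5, seed = 66)
  candidates <- rownames(pm$assay)  # 7 candidates
  sr <- subset_search(pm, candidates = candidates, sizes = 2:3)
  # enumeration completeness at each size
  expect_equal(sum(sr$evaluated$size == 2), comb_count(7, 2))
  expect_equal(sum(sr$evaluated$size == 3), comb_count(7, 3))
  # subset-for-subset agreement with an independent MASS-based search
  oracle <- naive_subset_search(pm$assay, pm$design$group, candidates, 2:3)
  expect_equal(length(oracle), nrow(sr$evaluated))
  got <- setNames(sr$evaluated$accuracy, sr$evaluated$subset)
  for (key in names(oracle)) {
    expect_equal(unname(got[key]), oracle[[key]])
  }
  # determinism
  sr2 <- subset_search(pm, candidates = candidates, sizes = 2:3)
  expect_identical(sr$evaluated, sr2$evaluated)
})

test_that("minimal perfect subsets are found exactly", {
  # MARK01+MARK02 separate perfectly; nulls do not
  pm <- separable_pm(n_marker = 2, n_null = 4, noise = 0.05, seed = 67)
  sr <- subset_search(pm, sizes = 2:3)
  expect_equal(sr$minimal_size, 2)
  perfect_pairs <- vapply(sr$perfect_subsets, paste, "", collapse = "+")
  expect_true("MARK01+MARK02" %in% perfect_pairs)
  # single markers cannot separate all three groups here
  sr1 <- subset_search(pm, sizes = 1:2)
  expect_equal(sr1$minimal_size, 2)
  # null fixture: no perfect subset, warning not error
  null_pm <- separable_pm(n_marker = 0, n_null = 5, noise = 1, seed = 68)
  expect_warning(sr0 <- subset_search(null_pm, sizes = 2:3), "no perfect")
  expect_true(is.na(sr0$minimal_size))
  expect_length(sr0$perfect_subsets, 0)
})

test_that("frequency ranking counts occurrences with deterministic tie-breaks", {
  # hand case: {A,B}, {A,C} -> A twice, then B and C once
  r <- rank_by_frequency(list(c("A", "B"), c("A", "C")),
                         omnibus_p = c(A = 0.01, B = 0.03, C = 0.02))
  expect_equal(r$ranking$protein, c("A", "C", "B"))  # tie broken by p
  expect_equal(r$ranking$frequency, c(2, 1, 1))
  expect_equal(r$more_than_once, "A")
  # counting identity: frequencies sum to size * n_subsets
  set.seed(69)
  subsets <- replicate(9, sample(LETTERS[1:15], 5), simplify = FALSE)
  r9 <- rank_by_frequency(subsets)
  expect_equal(sum(r9$ranking$frequency), 45)
  expect_lte(length(r9$union), 45)
  # single subset: all frequency 1, ">1" set empty
  r1 <- rank_by_frequency(list(c("X", "Y")))
  expect_equal(r1$ranking$frequency, c(1, 1))
  expect_length(r1$more_than_once, 0)
  expect_error(rank_by_frequency(list()), "no perfect subsets")
})

test_that("biplot export carries LD1/LD2 per sample and separates planted groups", {
  pm <- separable_pm(n_marker = 3, n_null = 2, noise = 0.3, seed = 70)
  fit <- fit_lda(t(pm$assay), pm$design$group)
  bp <- biplot_export(fit)
  expect_equal(nrow(bp), 26)
  expect_named(bp, c("sample", "group", "LD1", "LD2"))
  # centroids separated on LD1 for the planted fixture
  cent <- tapply(bp$LD1, bp$group, mean)
  expect_gt(max(cent) - min(cent), 5)
  expect_gt(centroid_separation(fit), 5)
  # coordinates invariant up to sign under feature reordering
  fit_rev <- fit_lda(t(pm$assay[rev(rownames(pm$assay)), ]),
                     pm$design$group)
  expect_equal(abs(cor(fit$scores[, 1], fit_rev$scores[, 1])), 1,
               tolerance = 1e-6)
  # two-class fit: LD2 column absent
  keep <- pm$design$group != "P"
  design2 <- group_design(pm$design$sample_id[keep],
                          as.character(pm$design$group[keep]))
  fit2 <- fit_lda(t(pm$assay[, keep]), design2$group)
  expect_false("LD2" %in% names(biplot_export(fit2)))
})
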