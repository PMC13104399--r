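test_that("flag removal drops flagged rows with per-category counts", {
  pm <- small_pm()  # rows 3 (reverse) and 4 (contaminant) flagged
  res <- remove_flagged(pm)
  expect_equal(nrow(res$matrix$assay), 3)
  expect_equal(unname(res$counts["reverse"]), 1)
  expect_equal(unname(res$counts["potential_contaminant"]), 1)
  expect_equal(unname(res$counts["total_removed"]), 2)
  # a doubly flagged row is removed once; category counts may overlap
  pm$rowdata$potential_contaminant[3] <- TRUE
  res2 <- remove_flagged(pm)
  expect_equal(unname(res2$counts["total_removed"]), 2)
  expect_equal(unname(res2$counts["reverse"]), 1)
  expect_equal(unname(res2$counts["potential_contaminant"]), 2)
  # no flags: identity
  pm$rowdata[c("reverse", "potential_contaminant",
               "only_identified_by_site")] <- FALSE
  expect_equal(remove_flagged(pm)$matrix$assay, pm$assay)
})

test_that("column normalization hits the target sum and is scale invariant", {
  design <- group_design(c("a", "b"), c("N", "P"))
  assay <- matrix(c(1e10, 4e10, 2e10, 8e10), nrow = 2,
                  dimnames = list(c("p1", "p2"), c("a", "b")))
  pm <- protein_matrix(assay, design)
  out <- normalize_and_log(pm, 1e11)
  # column [1e10, 4e10] scales to [2e10, 8e10]
  expect_equal(2^out$assay[, "a"], c(p1 = 2e10, p2 = 8e10))
  # scalar-multiple columns become identical
  expect_equal(out$assay[, "a"], out$assay[, "b"], ignore_attr = TRUE)
  # post-condition: linear column sums equal the target
  expect_equal(colSums(2^out$assay), c(a = 1e11, b = 1e11),
               tolerance = 1e-9)
})

test_that("normalization leaves missing cells missing and excludes them from sums", {
  pm <- small_pm()
  clean <- remove_flagged(pm)$matrix
  out <- normalize_and_log(clean, 1e11)
  expect_identical(is.na(out$assay), is.na(clean$assay))
  expect_equal(colSums(2^out$assay, na.rm = TRUE),
               rep(1e11, 10), tolerance = 1e-9, ignore_attr = TRUE)
  # all-missing column is fatal
  broken <- clean
  broken$assay[, 1] <- NA
  expect_error(normalize_and_log(broken, 1e11), "no observed values")
})

test_that("validity filter applies the ceiling rule per group", {
  design <- cohort_design()  # 11 / 6 / 9 => need 10 / 6 / 9 at 90%
  g <- design$group
  make_row <- function(valid_by_group) {
    row <- rep(NA_real_, 26)
    for (lev in names(valid_by_group)) {
      idx <- which(g == lev)[seq_len(valid_by_group[[lev]])]
      row[idx] <- 20
    }
    row
  }
  assay <- rbind(
    retained = make_row(c(N = 10, P = 0, D = 0)),  # 10 >= ceil(0.9*11)
    removed = make_row(c(N = 9, P = 5, D = 8)),    # 9<10, 5<6, 8<9
    full = rep(20, 26)
  )
  colnames(assay) <- design$sample_id
  pm <- protein_matrix(assay, design, log2 = TRUE)
  res <- filter_min_valid(pm, 0.9)
  expect_identical(rownames(res$matrix$assay), c("retained", "full"))
  expect_equal(res$n_removed, 1)
  # fully observed proteins survive any fraction
  expect_true("full" %in% rownames(filter_min_valid(pm, 1)$matrix$assay))
  # order independence and idempotence
  perm <- sample(nrow(assay))
  res_perm <- filter_min_valid(
    protein_matrix(assay[perm, ], design, log2 = TRUE), 0.9)
  expect_setequal(rownames(res_perm$matrix$assay),
                  rownames(res$matrix$assay))
  expect_identical(filter_min_valid(res$matrix, 0.9)$matrix$assay,
                   res$matrix$assay)
})

test_that("imputation draws from the downshifted per-sample normal", {
  # one sample, ~1e5 missing cells: moments within 1% of N(m-1.8s, (0.3s)^2)
  set.seed(42)
  observed <- rnorm(1000, 20, 2)
  assay <- matrix(c(observed, rep(NA_real_, 1e5)), ncol = 1,
                  dimnames = list(NULL, "s1"))
  pm <- protein_matrix(assay, group_design("s1", "N"), log2 = TRUE)
  out <- impute_downshifted_normal(pm, width = 0.3, downshift = 1.8,
                                   seed = 5)
  m_s <- mean(observed); s_s <- sd(observed)
  imputed <- out$assay[is.na(assay[, 1]), 1]
  expect_lt(abs(mean(imputed) - (m_s - 1.8 * s_s)) / abs(m_s - 1.8 * s_s),
            0.01)
  expect_lt(abs(sd(imputed) - 0.3 * s_s) / (0.3 * s_s), 0.01)
  # observed cells untouched; determinism; complete matrix unchanged
  expect_identical(unname(out$assay[!is.na(assay[, 1]), 1]), observed)
  rerun <- impute_downshifted_normal(pm, seed = 5)
  expect_identical(rerun$assay, out$assay)
  complete <- protein_matrix(matrix(observed, ncol = 1,
                                    dimnames = list(NULL, "s1")),
                             group_design("s1", "N"), log2 = TRUE)
  expect_identical(impute_downshifted_normal(complete, seed = 1)$assay,
                   complete$assay)
})

test_that("imputation rejects samples with fewer than two observed values", {
  assay <- matrix(c(20, NA, NA, 21, 22, 23), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  pm <- protein_matrix(assay, group_design(c("a", "b"), c("N", "P")),
                       log2 = TRUE)
  expect_error(impute_downshifted_normal(pm), "fewer than 2")
})

test_that("the preprocessing pipeline applies flags, normalize, filter, impute in order", {
  sim <- generate_dataset(synthetic_spec(n_proteins = 400, seed = 31))
  params <- preprocess_params(seed = 32)
  res <- preprocess_pipeline(sim$matrix, params)
  expect_s3_class(res$report, "preprocess_report")
  expect_true(res$report$n_input >= res$report$n_after_flag_removal)
  expect_true(res$report$n_after_flag_removal > res$report$n_after_filter)
  expect_false(anyNA(res$matrix$assay))
  expect_true(res$matrix$log2)
  # rerun with same seed: identical final matrix
  res2 <- preprocess_pipeline(sim$matrix, params)
  expect_identical(res2$matrix$assay, res$matrix$assay)
  # imputation happens after filtering: every retained protein satisfies
  # the validity rule on pre-imputation data
  nl <- normalize_and_log(remove_flagged(sim$matrix)$matrix,
                          params$scale_total)
  kept <- filter_min_valid(nl, 0.9)$matrix
  expect_identical(rownames(res$matrix$assay), rownames(kept$assay))
  # invalid fraction is rejected at construction
  expect_error(preprocess_params(min_valid_fraction = 0), "in \\(0, 1\\]")
})
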