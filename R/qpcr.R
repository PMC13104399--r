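#' Relative expression by the 2^-DeltaDeltaCt method
#'
#' Per sample: technical Ct replicates of the target and reference genes
#' are averaged; `DeltaCt = mean(target Ct) - mean(reference Ct)`;
#' `DeltaDeltaCt = DeltaCt - mean(DeltaCt over the control group)` (the
#' calibrator is the arithmetic mean DeltaCt of the control group); relative
#' expression is `2^-DeltaDeltaCt`. By construction the geometric mean of
#' the control-group fold changes is 1, and shifting every Ct value by a
#' constant leaves the result unchanged.
#'
#' @param records Data frame with columns `sample`, `group`, `ct_rep1`,
#'   `ct_rep2`, `ref_rep1`, `ref_rep2` (see [generate_qpcr_dataset()]).
#'   Technical replicate columns may contain `NA`; a sample with no usable
#'   reference Ct is excluded with a warning.
#' @param control_group Label of the calibrator group (must be non-empty in
#'   `records`).
#' @param ct_range Plausible Ct range; values outside it are rejected.
#' @return Data frame with columns `sample`, `group`, `delta_ct`,
#'   `delta_delta_ct`, `rel_expr`.
#' @export
ddct_fold_change <- function(records, control_group,
                             ct_range = c(0, 45)) {
  needed <- c("sample", "group", "ct_rep1", "ct_rep2", "ref_rep1",
              "ref_rep2")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stopf("records lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!control_group %in% records$group) {
    stopf("control group '%s' has no samples", control_group)
  }
  cts <- as.matrix(records[, c("ct_rep1", "ct_rep2", "ref_rep1",
                               "ref_rep2")])
  out_of_range <- cts[!is.na(cts)]
  if (any(out_of_range < ct_range[1] | out_of_range > ct_range[2])) {
    stopf("Ct value outside plausible range [%g, %g]", ct_range[1],
          ct_range[2])
  }
  target <- rowMeans(records[, c("ct_rep1", "ct_rep2")], na.rm = TRUE)
  ref <- rowMeans(records[, c("ref_rep1", "ref_rep2")], na.rm = TRUE)
  usable <- is.finite(target) & is.finite(ref)
  if (!all(usable)) {
    warnf("excluding %d sample(s) without usable target/reference Ct: %s",
          sum(!usable), paste(records$sample[!usable], collapse = ", "))
  }
  rec <- records[usable, , drop = FALSE]
  dct <- target[usable] - ref[usable]
  calibrator <- mean(dct[rec$group == control_group])
  ddct <- dct - calibrator
  data.frame(sample = rec$sample, group = rec$group,
             delta_ct = dct, delta_delta_ct = ddct,
             rel_expr = 2^(-ddct), stringsAsFactors = FALSE)
}

#' Compare qPCR relative expression between two groups
#'
#' Applies the distribution-aware two-group branch ([two_group_test()]) to
#' the per-sample `DeltaDeltaCt` values (equivalently, log2 relative
#' expression) of two groups.
#'
#' @param fold_table Output of [ddct_fold_change()].
#' @param group_a,group_b Group labels to compare.
#' @param alpha_gate Gate level of the normality/variance decision tree.
#' @return List with `test`, `p`, and `log2_fc` (mean log2 relative
#'   expression of `group_b` minus `group_a`).
#' @export
compare_qpcr_groups <- function(fold_table, group_a, group_b,
                                alpha_gate = 0.05) {
  x <- -fold_table$delta_delta_ct[fold_table$group == group_a]
  y <- -fold_table$delta_delta_ct[fold_table$group == group_b]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  res <- two_group_test(x, y, alpha_gate)
  c(res, list(log2_fc = mean(y) - mean(x)))
}

#' Read a qPCR Ct table
#'
#' Tab-separated with header: `sample`, `group`, `gene`, `ct_rep1`,
#' `ct_rep2`, `ref_rep1`, `ref_rep2`.
#'
#' @param path Path to the TSV.
#' @return Data frame of Ct records.
#' @export
read_qpcr_table <- function(path) {
  if (!file.exists(path)) stopf("qPCR table not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
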