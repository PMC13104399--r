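#' Parameters of the preprocessing stage
#'
#' Mirrors the Perseus workflow applied to label-free iBAQ data: artifact
#' removal, column-sum normalization to a fixed total, log2 transform,
#' group-wise validity filtering, and per-sample downshifted-normal
#' imputation of the remaining (left-censored) missing values.
#'
#' @param scale_total Target linear-scale column sum after normalization
#'   (default `1e11`, i.e. each sample column is divided by its sum over
#'   non-missing cells and multiplied by 10^11).
#' @param min_valid_fraction Fraction in (0, 1]: a protein is kept iff in at
#'   least one group the count of non-missing values reaches
#'   `ceiling(min_valid_fraction * group size)` (default 0.90).
#' @param impute_width Sd of the imputation distribution as a multiple of
#'   the per-sample observed sd (Perseus default 0.3).
#' @param impute_downshift Downward shift of the imputation distribution
#'   mean as a multiple of the per-sample observed sd (Perseus default 1.8).
#' @param seed Integer seed for the imputation draws.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(scale_total = 1e11,
                              min_valid_fraction = 0.90,
                              impute_width = 0.3,
                              impute_downshift = 1.8,
                              seed = 1L) {
  if (!is_number(scale_total) || scale_total <= 0) {
    stop("`scale_total` must be positive", call. = FALSE)
  }
  if (!is_number(min_valid_fraction) || min_valid_fraction <= 0 ||
      min_valid_fraction > 1) {
    stop("`min_valid_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (!is_number(impute_width) || impute_width <= 0) {
    stop("`impute_width` must be positive", call. = FALSE)
  }
  if (!is_number(impute_downshift) || impute_downshift <= 0) {
    stop("`impute_downshift` must be positive", call. = FALSE)
  }
  structure(list(scale_total = scale_total,
                 min_valid_fraction = min_valid_fraction,
                 impute_width = impute_width,
                 impute_downshift = impute_downshift,
                 seed = as.integer(seed)),
            class = "preprocess_params")
}

#' Remove flagged artifact proteins
#'
#' Drops rows flagged as reverse-database hits, potential contaminants or
#' proteins only identified by a modification site. A row carrying several
#' flags is removed (and counted in the total) once; per-category counts may
#' overlap.
#'
#' @param pm A [protein_matrix()].
#' @return A list with `matrix` (the cleaned [protein_matrix()]) and
#'   `counts`: named integer vector with per-flag counts and `total_removed`.
#' @export
remove_flagged <- function(pm) {
  stopifnot(inherits(pm, "protein_matrix"))
  rd <- pm$rowdata
  drop <- rd$reverse | rd$potential_contaminant | rd$only_identified_by_site
  counts <- c(reverse = sum(rd$reverse),
              potential_contaminant = sum(rd$potential_contaminant),
              only_identified_by_site = sum(rd$only_identified_by_site),
              total_removed = sum(drop))
  out <- subset_proteins(pm, !drop)
  if (nrow(out$assay) == 0L) warnf("all proteins removed by artifact flags")
  list(matrix = out, counts = counts)
}

#' Normalize column sums and log2-transform
#'
#' Each sample column is scaled so that its linear-scale sum over
#' non-missing cells equals `scale_total` (equalizing sample loading), then
#' non-missing cells are log2-transformed. Missing cells stay missing and
#' are excluded from the sums.
#'
#' @param pm A [protein_matrix()] on linear scale.
#' @param scale_total Target column sum (see [preprocess_params()]).
#' @return A log2-scale [protein_matrix()].
#' @export
normalize_and_log <- function(pm, scale_total = 1e11) {
  stopifnot(inherits(pm, "protein_matrix"))
  if (pm$log2) stop("matrix is already log2-transformed", call. = FALSE)
  assay <- pm$assay
  sums <- colSums(assay, na.rm = TRUE)
  if (any(sums <= 0 | !is.finite(sums))) {
    stopf("column(s) with no observed values: %s",
          paste(colnames(assay)[sums <= 0 | !is.finite(sums)],
                collapse = ", "))
  }
  assay <- sweep(assay, 2, scale_total / sums, `*`)
  assay <- log2(assay)
  protein_matrix(assay, pm$design, rowdata = pm$rowdata, log2 = TRUE)
}

#' Filter proteins by group-wise validity
#'
#' Retains a protein iff at least one group has
#' `valid count >= ceiling(min_valid_fraction * group size)` — "at least 90
#' percent non-missing in at least one subject group" under the default.
#' For groups of 11/6/9 the default requires 10/6/9 valid values.
#'
#' @param pm A [protein_matrix()].
#' @param min_valid_fraction Fraction in (0, 1].
#' @return A list with `matrix` (filtered) and `n_retained`/`n_removed`.
#' @export
filter_min_valid <- function(pm, min_valid_fraction = 0.90) {
  stopifnot(inherits(pm, "protein_matrix"))
  if (min_valid_fraction <= 0 || min_valid_fraction > 1) {
    stop("`min_valid_fraction` must be in (0, 1]", call. = FALSE)
  }
  g <- pm$design$group
  need <- ceiling(min_valid_fraction * group_counts(pm$design))
  valid <- !is.na(pm$assay)
  keep <- rep(FALSE, nrow(pm$assay))
  for (lev in levels(g)) {
    cnt <- rowSums(valid[, g == lev, drop = FALSE])
    keep <- keep | cnt >= need[[lev]]
  }
  list(matrix = subset_proteins(pm, keep),
       n_retained = sum(keep), n_removed = sum(!keep))
}

#' Impute missing values from a downshifted normal distribution
#'
#' Perseus-style imputation "into the normal data distribution of each
#' sample": for sample `s` with observed mean `m_s` and sd `sigma_s`, every
#' missing cell of `s` is replaced by an independent draw from
#' `Normal(m_s - downshift * sigma_s, (width * sigma_s)^2)`. This models
#' left-censored missingness: non-detected proteins are assumed to sit
#' below the detection limit, in the low tail of the sample's intensity
#' distribution. Observed cells are never touched.
#'
#' @param pm A log2-scale [protein_matrix()]; every sample needs at least 2
#'   observed values.
#' @param width,downshift Multipliers of the per-sample sd (defaults 0.3
#'   and 1.8).
#' @param seed Integer seed; the same input and seed give identical output.
#' @return The imputed [protein_matrix()] with an `impute_params` attribute:
#'   a data frame of per-sample observed mean/sd, the imputation mean/sd
#'   used, and the number of imputed cells.
#' @export
impute_downshifted_normal <- function(pm, width = 0.3, downshift = 1.8,
                                      seed = 1L) {
  stopifnot(inherits(pm, "protein_matrix"))
  if (!pm$log2) stop("imputation expects a log2-scale matrix", call. = FALSE)
  assay <- pm$assay
  n_valid <- colSums(!is.na(assay))
  if (any(n_valid < 2)) {
    stopf("sample(s) with fewer than 2 observed values: %s",
          paste(colnames(assay)[n_valid < 2], collapse = ", "))
  }
  m <- colMeans(assay, na.rm = TRUE)
  s <- apply(assay, 2, stats::sd, na.rm = TRUE)
  info <- data.frame(sample = colnames(assay), observed_mean = m,
                     observed_sd = s,
                     impute_mean = m - downshift * s,
                     impute_sd = width * s,
                     n_imputed = colSums(is.na(assay)),
                     row.names = NULL, stringsAsFactors = FALSE)
  with_seed(seed, {
    for (j in seq_len(ncol(assay))) {
      miss <- which(is.na(assay[, j]))
      if (length(miss)) {
        assay[miss, j] <- stats::rnorm(length(miss),
                                       mean = m[j] - downshift * s[j],
                                       sd = width * s[j])
      }
    }
  })
  out <- protein_matrix(assay, pm$design, rowdata = pm$rowdata, log2 = TRUE)
  attr(out, "impute_params") <- info
  out
}

#' Run the full preprocessing stage
#'
#' Applies, in order: artifact-flag removal, column-sum normalization plus
#' log2 transform, group-validity filtering, and downshifted-normal
#' imputation — so imputed values can never rescue a protein past the
#' filter. Emits a report of the protein funnel.
#'
#' @param pm A raw (linear-scale) [protein_matrix()] from
#'   [read_protein_groups()] or [generate_dataset()].
#' @param params A [preprocess_params()].
#' @return A list with `matrix` (complete, log2-scale, imputed) and
#'   `report` (class `preprocess_report`).
#' @export
preprocess_pipeline <- function(pm, params = preprocess_params()) {
  stopifnot(inherits(pm, "protein_matrix"),
            inherits(params, "preprocess_params"))
  n_input <- nrow(pm$assay)
  fl <- remove_flagged(pm)
  nl <- normalize_and_log(fl$matrix, params$scale_total)
  missing_before <- colSums(is.na(nl$assay))
  fi <- filter_min_valid(nl, params$min_valid_fraction)
  im <- impute_downshifted_normal(fi$matrix, width = params$impute_width,
                                  downshift = params$impute_downshift,
                                  seed = params$seed)
  report <- structure(
    list(n_input = n_input,
         n_after_flag_removal = nrow(fl$matrix$assay),
         n_after_filter = fi$n_retained,
         flag_counts = fl$counts,
         missing_per_sample = missing_before,
         impute_params = attr(im, "impute_params"),
         params = params),
    class = "preprocess_report"
  )
  list(matrix = im, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf(
    "preprocess_report: %d proteins in -> %d after flag removal -> %d after %g%% validity filter\n",
    x$n_input, x$n_after_flag_removal, x$n_after_filter,
    100 * x$params$min_valid_fraction))
  cat(sprintf("  flags removed: reverse %d, contaminant %d, by-site %d (total %d)\n",
              x$flag_counts[["reverse"]],
              x$flag_counts[["potential_contaminant"]],
              x$flag_counts[["only_identified_by_site"]],
              x$flag_counts[["total_removed"]]))
  cat(sprintf("  imputed cells: %d\n", sum(x$impute_params$n_imputed)))
  invisible(x)
}
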