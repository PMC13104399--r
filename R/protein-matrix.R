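#' Construct a sample-to-group design
#'
#' A `group_design` maps sample identifiers to one of the three disease
#' groups used throughout the pipeline: `N` (non-diabetic), `P`
#' (pre-diabetic) and `D` (type 2 diabetic). The sample order is preserved
#' and defines the column order of any matrix built against the design.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param group Character or factor vector of group labels, one per sample;
#'   labels must be in `N`, `P`, `D`.
#' @return An object of class `group_design`: a list with `sample_id` and
#'   `group` (a factor with levels `N`, `P`, `D`).
#' @export
group_design <- function(sample_id, group) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group)) {
    stopf("sample_id (%d) and group (%d) lengths differ",
          length(sample_id), length(group))
  }
  if (anyDuplicated(sample_id)) {
    stopf("duplicate sample id: %s",
          paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(group), c("N", "P", "D"))
  if (length(bad)) {
    stopf("unknown group label(s): %s (expected N, P or D)",
          paste(bad, collapse = ", "))
  }
  structure(
    list(sample_id = sample_id,
         group = factor(group, levels = c("N", "P", "D"))),
    class = "group_design"
  )
}

#' @export
print.group_design <- function(x, ...) {
  cat("group_design:", length(x$sample_id), "samples (",
      paste(sprintf("%s=%d", levels(x$group), table(x$group)), collapse = ", "),
      ")\n")
  invisible(x)
}

group_counts <- function(design) {
  tab <- table(design$group)
  stats::setNames(as.integer(tab), names(tab))
}

#' Construct a protein abundance matrix
#'
#' The central container of the pipeline: a proteins-by-samples numeric
#' matrix in which `NA` encodes a missing (non-detected) measurement,
#' together with per-protein metadata (identifier, gene names and the three
#' MaxQuant artifact flags) and the sample-to-group design.
#'
#' @param assay Numeric matrix, proteins in rows, samples in columns.
#'   Missing measurements are `NA`. Column names must equal
#'   `design$sample_id` in order; row names are protein group identifiers.
#' @param design A [group_design()].
#' @param rowdata Optional data frame of per-protein metadata with columns
#'   `protein_group_id`, `gene_names`, `reverse`, `potential_contaminant`,
#'   `only_identified_by_site`. Defaults are derived from row names with all
#'   flags `FALSE`.
#' @param log2 Logical; `TRUE` once the assay holds log2-transformed values.
#' @return An object of class `protein_matrix`.
#' @export
protein_matrix <- function(assay, design, rowdata = NULL, log2 = FALSE) {
  if (!is.matrix(assay) || !is.numeric(assay)) {
    stop("`assay` must be a numeric matrix", call. = FALSE)
  }
  if (!inherits(design, "group_design")) {
    stop("`design` must be a group_design", call. = FALSE)
  }
  if (is.null(colnames(assay))) colnames(assay) <- design$sample_id
  if (!identical(colnames(assay), design$sample_id)) {
    stop("assay column names must match design sample ids (in order)",
         call. = FALSE)
  }
  if (is.null(rownames(assay))) {
    rownames(assay) <- sprintf("protein_%04d", seq_len(nrow(assay)))
  }
  if (anyDuplicated(rownames(assay))) {
    stopf("duplicate protein group id: %s",
          rownames(assay)[duplicated(rownames(assay))][1L])
  }
  if (is.null(rowdata)) {
    rowdata <- data.frame(
      protein_group_id = rownames(assay),
      gene_names = rownames(assay),
      reverse = FALSE,
      potential_contaminant = FALSE,
      only_identified_by_site = FALSE,
      stringsAsFactors = FALSE
    )
  }
  needed <- c("protein_group_id", "gene_names", "reverse",
              "potential_contaminant", "only_identified_by_site")
  missing_cols <- setdiff(needed, names(rowdata))
  if (length(missing_cols)) {
    stopf("rowdata lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(rowdata) != nrow(assay)) {
    stop("rowdata and assay row counts differ", call. = FALSE)
  }
  structure(
    list(assay = assay, rowdata = rowdata, design = design,
         log2 = isTRUE(log2)),
    class = "protein_matrix"
  )
}

#' @export
dim.protein_matrix <- function(x) dim(x$assay)

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix: %d proteins x %d samples (%s scale)\n",
              nrow(x$assay), ncol(x$assay),
              if (x$log2) "log2" else "linear"))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x$assay)),
              100 * mean(is.na(x$assay))))
  print(x$design)
  invisible(x)
}

# Row subset keeping metadata and design aligned.
subset_proteins <- function(pm, idx) {
  protein_matrix(pm$assay[idx, , drop = FALSE], pm$design,
                 rowdata = pm$rowdata[idx, , drop = FALSE], log2 = pm$log2)
}

# Per-protein abundance vectors split by group, in level order N, P, D.
values_by_group <- function(pm, protein) {
  split(pm$assay[protein, ], pm$design$group)
}

# Leading accession of a semicolon-joined protein group, used for display.
display_name <- function(protein_group_id) {
  vapply(strsplit(protein_group_id, ";", fixed = TRUE), `[[`, "", 1L)
}
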