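#' Read a sample sheet into a group design
#'
#' The sample sheet is a two-column tab-separated file with a header row,
#' columns `sample_id` and `group`, one row per sample. Group labels must
#' be `N`, `P` or `D`.
#'
#' @param path Path to the TSV sample sheet.
#' @return A [group_design()].
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stopf("sample sheet not found: %s", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if (nrow(tab) == 0L) stopf("sample sheet is empty: %s", path)
  needed <- c("sample_id", "group")
  if (!all(needed %in% names(tab))) {
    stopf("sample sheet must have columns 'sample_id' and 'group', found: %s",
          paste(names(tab), collapse = ", "))
  }
  group_design(tab$sample_id, tab$group)
}

#' Write a sample sheet
#' @param design A [group_design()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(design, path) {
  stopifnot(inherits(design, "group_design"))
  write_table(data.frame(sample_id = design$sample_id,
                         group = as.character(design$group)), path)
}

#' Read a MaxQuant proteinGroups table
#'
#' Parses the tab-separated `proteinGroups.txt` dialect: one row per protein
#' group, artifact flags marked `+` in the `Reverse`,
#' `Potential contaminant` and `Only identified by site` columns, and one
#' `iBAQ <sample>` intensity column per sample. Cells equal to 0 or empty
#' are recorded as missing, not as zero abundance (MaxQuant writes 0 for
#' non-detected proteins and log2 of 0 is undefined). No rows are silently
#' dropped; the returned object carries every input row.
#'
#' @param path Path to the proteinGroups TSV.
#' @param design A [group_design()]; every design sample must have a
#'   matching `iBAQ <sample>` column.
#' @return A [protein_matrix()] on linear intensity scale with metadata
#'   flags attached. The number of rows read is reported via `message()`.
#' @export
read_protein_groups <- function(path, design) {
  stopifnot(inherits(design, "group_design"))
  if (!file.exists(path)) stopf("proteinGroups file not found: %s", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  id_col <- if ("Protein IDs" %in% names(tab)) "Protein IDs" else
    stopf("missing 'Protein IDs' column in %s", path)
  ibaq_cols <- paste("iBAQ", design$sample_id)
  absent <- ibaq_cols[!ibaq_cols %in% names(tab)]
  if (length(absent)) {
    stopf("design sample(s) without an iBAQ column: %s",
          paste(sub("^iBAQ ", "", absent), collapse = ", "))
  }
  ids <- as.character(tab[[id_col]])
  if (anyDuplicated(ids)) {
    stopf("duplicate protein group id in %s: %s", path,
          ids[duplicated(ids)][1L])
  }
  flag <- function(col) {
    if (!col %in% names(tab)) return(rep(FALSE, nrow(tab)))
    x <- as.character(tab[[col]])   # an all-empty column reads as NA
    x[is.na(x)] <- ""
    trimws(x) == "+"
  }
  assay <- as.matrix(tab[, ibaq_cols, drop = FALSE])
  suppressWarnings(storage.mode(assay) <- "double")
  assay[!is.finite(assay) | assay == 0] <- NA_real_  # 0/empty => missing
  dimnames(assay) <- list(ids, design$sample_id)
  rowdata <- data.frame(
    protein_group_id = ids,
    gene_names = if ("Gene names" %in% names(tab))
      as.character(tab[["Gene names"]]) else display_name(ids),
    reverse = flag("Reverse"),
    potential_contaminant = flag("Potential contaminant"),
    only_identified_by_site = flag("Only identified by site"),
    stringsAsFactors = FALSE
  )
  message(sprintf("read_protein_groups: %d rows read from %s", nrow(tab),
                  path))
  protein_matrix(assay, design, rowdata = rowdata, log2 = FALSE)
}

#' Write a protein matrix in the proteinGroups TSV dialect
#'
#' Inverse of [read_protein_groups()]: flags are written as `+`/empty and
#' missing intensities as 0, so a round trip through
#' [read_protein_groups()] reproduces values and the missingness mask.
#'
#' @param pm A [protein_matrix()] on linear intensity scale.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(pm, path) {
  stopifnot(inherits(pm, "protein_matrix"))
  if (pm$log2) stop("write_protein_groups expects linear-scale intensities",
                    call. = FALSE)
  mark <- function(x) ifelse(x, "+", "")
  assay <- pm$assay
  assay[is.na(assay)] <- 0
  out <- data.frame(
    `Protein IDs` = pm$rowdata$protein_group_id,
    `Gene names` = pm$rowdata$gene_names,
    Reverse = mark(pm$rowdata$reverse),
    `Potential contaminant` = mark(pm$rowdata$potential_contaminant),
    `Only identified by site` = mark(pm$rowdata$only_identified_by_site),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  ints <- as.data.frame(signif(assay, 6))
  names(ints) <- paste("iBAQ", colnames(assay))
  write_table(cbind(out, ints), path)
}

#' Write a tabular result as TSV
#'
#' All tabular pipeline outputs go through this writer: tab-separated with a
#' header row, missing values rendered as `NA`, floating point values at 6
#' significant digits, column order as given.
#'
#' @param table A data frame or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  tab <- as.data.frame(table, stringsAsFactors = FALSE)
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 6)
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ok <- tryCatch({
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("cannot write %s: %s", path, conditionMessage(ok))
  invisible(path)
}
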