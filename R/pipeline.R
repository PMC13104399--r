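#' Configure an end-to-end pipeline run
#'
#' Exactly one input source: either a synthetic data specification or a
#' pair of file paths (proteinGroups table + sample sheet).
#'
#' @param synthetic A [synthetic_spec()], or `NULL` when reading files.
#' @param protein_groups,sample_sheet File paths, or `NULL` when
#'   simulating.
#' @param preprocess A [preprocess_params()].
#' @param alpha Significance threshold of the selection rule.
#' @param subset_sizes Sizes for the exhaustive LDA search (default `2:5`).
#' @param cor_threshold Pearson threshold of the pair screen (default 0.6).
#' @param cv A [cv_spec()].
#' @param max_lda_candidates Cap on the number of candidates entering the
#'   exhaustive subset search (the top of the significance ordering is
#'   kept); guards against a combinatorial blow-up on permissive selections.
#' @param out_dir Output directory for TSV/JSON exports.
#' @param seed Global seed; stage seeds are derived from it
#'   deterministically.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL,
                            protein_groups = NULL,
                            sample_sheet = NULL,
                            preprocess = NULL,
                            alpha = 0.05,
                            subset_sizes = 2:5,
                            cor_threshold = 0.6,
                            cv = NULL,
                            max_lda_candidates = 25L,
                            out_dir = tempfile("lfqpanel_run_"),
                            seed = 1L) {
  from_files <- !is.null(protein_groups) || !is.null(sample_sheet)
  if (is.null(synthetic) && !from_files) {
    stop("provide either `synthetic` or `protein_groups` + `sample_sheet`",
         call. = FALSE)
  }
  if (!is.null(synthetic) && from_files) {
    stop("provide exactly one input source, not both", call. = FALSE)
  }
  if (from_files && (is.null(protein_groups) || is.null(sample_sheet))) {
    stop("file input needs both `protein_groups` and `sample_sheet`",
         call. = FALSE)
  }
  seed <- as.integer(seed)
  structure(
    list(synthetic = synthetic,
         protein_groups = protein_groups, sample_sheet = sample_sheet,
         preprocess = preprocess %||% preprocess_params(
           seed = stage_seed(seed, 1L)),
         alpha = alpha,
         subset_sizes = subset_sizes,
         cor_threshold = cor_threshold,
         cv = cv %||% cv_spec(base_seed = stage_seed(seed, 2L)),
         max_lda_candidates = as.integer(max_lda_candidates),
         out_dir = out_dir, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full biomarker-panel discovery pipeline
#'
#' Stage order: ingest (simulate or read) -> preprocess (flags, normalize,
#' log2, validity filter, impute) -> differential testing and selection ->
#' exhaustive LDA subset search and frequency ranking -> Pearson/ROC
#' screening -> repeated cross-validated pair classification. Every stage's
#' tabular result is written under `config$out_dir` along with a JSON run
#' manifest recording all parameters, seeds and the protein funnel, so a
#' rerun with the same config is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result (`matrix`, `report`,
#'   `differential`, `significant`, `lda_all`, `subset_ranking`,
#'   `frequency`, `correlation`, `roc`, `cv`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  truth <- NULL
  raw <- stage("ingest", {
    if (!is.null(config$synthetic)) {
      sim <- generate_dataset(config$synthetic)
      truth <- sim$truth
      write_ground_truth(truth, out("ground_truth.json"))
      sim$matrix
    } else {
      design <- read_sample_sheet(config$sample_sheet)
      read_protein_groups(config$protein_groups, design)
    }
  })

  pp <- stage("preprocess", preprocess_pipeline(raw, config$preprocess))
  write_table(pp$report$impute_params, out("impute_params.tsv"))

  diff <- stage("differential", differential_table(pp$matrix))
  write_table(as.data.frame(diff), out("differential_table.tsv"))
  for (ct in CONTRASTS) {
    write_table(volcano_table(diff, ct, alpha = config$alpha),
                out(sprintf("volcano_%s.tsv", gsub("-", "_", ct))))
  }
  significant <- stage("differential",
                       select_significant(diff, alpha = config$alpha))
  writeLines(significant, out("significant_proteins.txt"))

  candidates <- utils::head(significant, config$max_lda_candidates)
  lda_all <- ranking <- freq <- NULL
  if (length(candidates) >= 2) {
    lda_all <- stage("lda", fit_lda(t(pp$matrix$assay[candidates, ,
                                                      drop = FALSE]),
                                    pp$matrix$design$group))
    write_table(biplot_export(lda_all), out("lda_biplot.tsv"))
    ranking <- stage("lda", subset_search(pp$matrix,
                                          candidates = candidates,
                                          sizes = config$subset_sizes))
    write_table(ranking$evaluated[ranking$evaluated$accuracy == 1, ,
                                  drop = FALSE],
                out("perfect_subsets.tsv"))
    if (!is.na(ranking$minimal_size)) {
      omnibus <- stats::setNames(diff$omnibus_p, diff$protein)
      freq <- rank_by_frequency(ranking$perfect_subsets, omnibus)
      write_table(freq$ranking, out("subset_frequency.tsv"))
    }
  }

  screen <- roc <- NULL
  if (length(candidates) >= 2) {
    screen <- stage("screening",
                    pearson_pair_screen(pp$matrix, candidates,
                                        threshold = config$cor_threshold))
    write_table(screen$strong_pairs, out("strong_correlations.tsv"))
    roc <- stage("screening", screening_table(pp$matrix, candidates))
    write_table(roc, out("roc_table.tsv"))
  }

  cv <- NULL
  if (length(candidates) >= 2) {
    cv <- stage("crossval",
                enumerate_pairs_and_count_perfect(pp$matrix, candidates,
                                                  config$cv))
    write_table(cv$outcomes, out("cv_outcomes.tsv"))
    write_table(cv$frequency, out("cv_frequency.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lfqpanel")),
    seed = config$seed,
    input = if (!is.null(config$synthetic)) "synthetic" else "files",
    synthetic = if (!is.null(config$synthetic))
      config$synthetic[setdiff(names(config$synthetic), "affected_group")],
    preprocess = unclass(config$preprocess),
    alpha = config$alpha,
    subset_sizes = config$subset_sizes,
    cor_threshold = config$cor_threshold,
    cv = unclass(config$cv),
    max_lda_candidates = config$max_lda_candidates,
    funnel = list(n_input = pp$report$n_input,
                  n_after_flag_removal = pp$report$n_after_flag_removal,
                  n_after_filter = pp$report$n_after_filter,
                  n_significant = length(significant),
                  n_lda_candidates = length(candidates))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(matrix = pp$matrix, report = pp$report, truth = truth,
                 differential = diff, significant = significant,
                 lda_all = lda_all, subset_ranking = ranking,
                 frequency = freq, correlation = screen, roc = roc,
                 cv = cv, manifest = manifest,
                 out_dir = config$out_dir))
}
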