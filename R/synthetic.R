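#' Specify a synthetic three-group proteomics dataset
#'
#' Defines the generative model used by [generate_dataset()]: protein-level
#' log2 mean intensities drawn from `Normal(base_mu, base_sigma^2)`, sample
#' measurements drawn around them with residual sd `noise_sigma`, a small
#' planted set of group-differential proteins, and left-censored (MNAR)
#' missingness from a logistic detection-probability curve in log2
#' intensity, so low-abundance measurements are preferentially lost — the
#' regime in which downshifted-normal imputation is the appropriate model.
#'
#' Defaults emulate the study cohort this pipeline targets: 26 samples in
#' groups of 11 (N), 6 (P) and 9 (D); 3963 quantified proteins of which
#' roughly half carry enough missing values to be removed by the 90 percent
#' group-validity filter; 23 planted differential proteins.
#'
#' @param n_per_group Named integer vector `c(N=, P=, D=)`, each at least 2.
#' @param n_proteins Total number of proteins.
#' @param n_differential Number of planted differential proteins
#'   (`<= n_proteins`).
#' @param effect_log2 Signed log2 mean shift for each planted protein;
#'   scalar (recycled) or vector of length `n_differential`. When
#'   `affected_group` is `NULL` the sign convention is applied after group
#'   assignment: shifts in group P are upward, shifts in group D downward,
#'   mirroring the dominant directions seen in duodenal T2D proteomes.
#' @param affected_group Group label(s) receiving the shift, `"P"` or
#'   `"D"` per planted protein; `NULL` to sample uniformly.
#' @param base_mu,base_sigma Mean and sd of the protein-level log2
#'   intensity distribution (iBAQ-like, so typical values near 2^23).
#' @param noise_sigma Within-protein residual sd in log2 units.
#' @param missing_slope,missing_mid Logistic detection curve: a cell with
#'   latent log2 intensity `x` is detected with probability
#'   `plogis(missing_slope * (x - missing_mid))`. `missing_slope = 0` with
#'   `missing_mid = -Inf` switches missingness off entirely.
#' @param seed Integer seed controlling all draws.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_group = c(N = 11, P = 6, D = 9),
                           n_proteins = 3963,
                           n_differential = 23,
                           effect_log2 = 2.5,
                           affected_group = NULL,
                           base_mu = 23,
                           base_sigma = 3,
                           noise_sigma = 0.5,
                           missing_slope = 1,
                           missing_mid = 21.5,
                           seed = 1L) {
  if (length(n_per_group) != 3L || is.null(names(n_per_group))) {
    stop("`n_per_group` must be a named vector of three counts (N, P, D)",
         call. = FALSE)
  }
  n_per_group <- n_per_group[c("N", "P", "D")]
  if (anyNA(n_per_group) || any(n_per_group < 2) ||
      any(n_per_group != floor(n_per_group))) {
    stop("group sizes must be integers >= 2", call. = FALSE)
  }
  if (!is_count(n_proteins)) stop("`n_proteins` must be a positive integer",
                                  call. = FALSE)
  if (!is_count(n_differential, min = 0)) {
    stop("`n_differential` must be a non-negative integer", call. = FALSE)
  }
  if (n_differential > n_proteins) {
    stop("`n_differential` must not exceed `n_proteins`", call. = FALSE)
  }
  if (!(length(effect_log2) %in% c(1L, max(1L, n_differential)))) {
    stop("`effect_log2` must be scalar or length n_differential",
         call. = FALSE)
  }
  if (!is.null(affected_group)) {
    if (!all(affected_group %in% c("P", "D"))) {
      stop("`affected_group` labels must be 'P' or 'D'", call. = FALSE)
    }
    if (!(length(affected_group) %in% c(1L, max(1L, n_differential)))) {
      stop("`affected_group` must be scalar or length n_differential",
           call. = FALSE)
    }
  }
  if (!is_number(base_sigma) || base_sigma <= 0) {
    stop("`base_sigma` must be positive", call. = FALSE)
  }
  if (!is_number(noise_sigma) || noise_sigma < 0) {
    stop("`noise_sigma` must be non-negative", call. = FALSE)
  }
  if (!is_number(missing_slope) || missing_slope < 0) {
    stop("`missing_slope` must be >= 0 (detection improves with intensity)",
         call. = FALSE)
  }
  structure(
    list(n_per_group = stats::setNames(as.integer(n_per_group),
                                       c("N", "P", "D")),
         n_proteins = as.integer(n_proteins),
         n_differential = as.integer(n_differential),
         effect_log2 = effect_log2,
         affected_group = affected_group,
         base_mu = base_mu, base_sigma = base_sigma,
         noise_sigma = noise_sigma,
         missing_slope = missing_slope, missing_mid = missing_mid,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic proteomics dataset with planted effects
#'
#' Draws a proteins-by-samples iBAQ-like intensity matrix under a
#' [synthetic_spec()] and returns it together with the ground truth needed
#' for parameter-recovery tests: planted protein identities, their per-group
#' latent means, per-contrast directions, and the complete latent
#' (pre-missingness) log2 matrix.
#'
#' Planted proteins are chosen from a mid-to-high abundance band: abundant
#' enough to be detected reliably at the unshifted level (per-cell
#' detection probability at least 0.95, so the validity filter keeps the
#' marker through its unaffected groups), but below the top abundance
#' decile, because a several-fold shift of a loading-dominant protein would
#' perturb the column-sum normalization of the affected samples and induce
#' apparent shifts in every other protein. A marker shifted downward may
#' gain missing values in its affected group — the left-censoring regime
#' the downstream imputation is built for.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `matrix` (a [protein_matrix()] on linear
#'   intensity scale with `NA` for non-detected cells) and `truth` (class
#'   `ground_truth`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    ng <- spec$n_per_group
    n_samples <- sum(ng)
    groups <- rep(names(ng), ng)
    sample_id <- sprintf("S%02d", seq_len(n_samples))
    design <- group_design(sample_id, groups)

    protein_id <- sprintf("PROT%04d", seq_len(spec$n_proteins))
    mu <- stats::rnorm(spec$n_proteins, spec$base_mu, spec$base_sigma)

    # planted proteins: group shift assignment, then eligibility by
    # post-shift detection probability
    nd <- spec$n_differential
    eff <- rep_len(spec$effect_log2, nd)
    grp_aff <- if (nd == 0L) character(0)
      else if (is.null(spec$affected_group)) {
        g <- sample(c("P", "D"), nd, replace = TRUE)
        # sign convention only when user passed the default magnitude form
        eff <- abs(eff) * ifelse(g == "P", 1, -1)
        g
      } else rep_len(spec$affected_group, nd)

    planted_idx <- integer(0)
    if (nd > 0L) {
      # plant in a mid-to-high abundance band: reliably detected at the
      # unshifted level (so the validity filter keeps the protein through
      # its unaffected groups) but below the top decile, where a several-
      # fold shift would distort the column-sum normalization of every
      # other protein in the affected group
      detected_ok <- if (spec$missing_slope == 0) rep(TRUE, length(mu))
        else stats::plogis(spec$missing_slope *
                             (mu - spec$missing_mid)) >= 0.95
      eligible <- which(detected_ok & mu <= stats::quantile(mu, 0.90))
      if (length(eligible) < nd) {
        eligible <- order(mu, decreasing = TRUE)[seq_len(min(nd * 2L,
                                                             spec$n_proteins))]
      }
      planted_idx <- sort(sample(eligible, nd))
    }

    shift <- matrix(0, spec$n_proteins, 3,
                    dimnames = list(protein_id, c("N", "P", "D")))
    if (nd > 0L) {
      for (j in seq_len(nd)) shift[planted_idx[j], grp_aff[j]] <- eff[j]
    }
    true_means <- mu + shift  # proteins x groups, log2 scale

    grp_col <- match(groups, c("N", "P", "D"))
    latent <- true_means[, grp_col, drop = FALSE] +
      matrix(stats::rnorm(spec$n_proteins * n_samples, 0, spec$noise_sigma),
             spec$n_proteins, n_samples)
    dimnames(latent) <- list(protein_id, sample_id)

    if (spec$missing_slope == 0 && is.infinite(spec$missing_mid) &&
        spec$missing_mid < 0) {
      detected <- matrix(TRUE, spec$n_proteins, n_samples)
    } else {
      p_det <- stats::plogis(spec$missing_slope * (latent - spec$missing_mid))
      detected <- matrix(stats::runif(length(latent)) < p_det,
                         spec$n_proteins, n_samples)
    }
    assay <- 2^latent
    assay[!detected] <- NA_real_
    dimnames(assay) <- dimnames(latent)

    truth <- structure(
      list(planted_ids = protein_id[planted_idx],
           affected_group = grp_aff,
           effect_log2 = eff,
           direction = if (nd > 0L) ifelse(eff > 0, "up", "down")
                       else character(0),
           true_group_means = true_means[planted_idx, , drop = FALSE],
           latent_log2 = latent,
           missing_params = list(slope = spec$missing_slope,
                                 mid = spec$missing_mid),
           spec = spec),
      class = "ground_truth"
    )
    list(matrix = protein_matrix(assay, design), truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d planted proteins (%s)\n",
              length(x$planted_ids),
              paste(sprintf("%s %s in %s", x$planted_ids, x$direction,
                            x$affected_group), collapse = "; ")))
  invisible(x)
}

#' Generate a synthetic qPCR Ct table
#'
#' Emits per-sample target and reference Ct values with duplicate technical
#' replicates, constructed so that at zero noise the 2^-DeltaDeltaCt
#' computation of [ddct_fold_change()] recovers `true_fold_changes` exactly.
#' The first group of `n_per_group` is the control (calibrator) group and
#' its true fold change is forced to 1.
#'
#' @param n_per_group Named integer vector of samples per group.
#' @param true_fold_changes Named positive numeric vector of per-group fold
#'   changes relative to the control group; names must match
#'   `names(n_per_group)`.
#' @param ct_noise_sd Non-negative sd of measurement noise added to every
#'   individual Ct replicate.
#' @param seed Integer seed.
#' @param gene,reference_gene Labels written into the table.
#' @return A data frame with columns `sample`, `group`, `gene`,
#'   `ct_rep1`, `ct_rep2`, `ref_rep1`, `ref_rep2`.
#' @export
generate_qpcr_dataset <- function(n_per_group,
                                  true_fold_changes,
                                  ct_noise_sd = 0,
                                  seed = 1L,
                                  gene = "TARGET",
                                  reference_gene = "REF") {
  if (is.null(names(n_per_group)) || is.null(names(true_fold_changes))) {
    stop("`n_per_group` and `true_fold_changes` must be named", call. = FALSE)
  }
  if (!setequal(names(n_per_group), names(true_fold_changes))) {
    stop("group names of `n_per_group` and `true_fold_changes` differ",
         call. = FALSE)
  }
  if (any(true_fold_changes <= 0)) {
    stop("fold changes must be positive", call. = FALSE)
  }
  if (!is_number(ct_noise_sd) || ct_noise_sd < 0) {
    stop("`ct_noise_sd` must be non-negative", call. = FALSE)
  }
  fc <- true_fold_changes[names(n_per_group)]
  fc[1L] <- 1  # control group defines the calibrator
  with_seed(seed, {
    ref_base <- 20   # typical reference-gene Ct
    dct_base <- 5    # control-group target minus reference Ct
    rows <- lapply(seq_along(n_per_group), function(g) {
      n <- n_per_group[[g]]
      dct <- dct_base - log2(fc[[g]])
      data.frame(
        group = names(n_per_group)[g],
        ct_true = ref_base + dct,
        ref_true = ref_base,
        stringsAsFactors = FALSE
      )[rep(1L, n), ]
    })
    tab <- do.call(rbind, rows)
    n_tot <- nrow(tab)
    noise <- function() stats::rnorm(n_tot, 0, ct_noise_sd)
    out <- data.frame(
      sample = sprintf("Q%02d", seq_len(n_tot)),
      group = tab$group,
      gene = gene,
      ct_rep1 = tab$ct_true + noise(),
      ct_rep2 = tab$ct_true + noise(),
      ref_rep1 = tab$ref_true + noise(),
      ref_rep2 = tab$ref_true + noise(),
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}

#' Write the ground truth of a synthetic dataset as a JSON sidecar
#'
#' @param truth A `ground_truth` object from [generate_dataset()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  payload <- list(
    planted_ids = truth$planted_ids,
    affected_group = truth$affected_group,
    effect_log2 = truth$effect_log2,
    direction = truth$direction,
    true_group_means = as.data.frame(truth$true_group_means),
    missing_params = truth$missing_params
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
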