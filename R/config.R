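#' Pipeline configuration
#'
#' Houses every tunable threshold of the pipeline with its default. The
#' printed analysis thresholds are: a copy-number call needs a segment-mean
#' fold difference of more than 0.1 (log2 scale) against the reference; a
#' recurrent aberration needs a within-sample carrier frequency of at least
#' 0.05 in at least two samples of a tissue type; co-expressed functional
#' gene clusters are excluded over 1 Mb windows at a gene-ontology
#' enrichment P below 0.05; cluster markers need Wilcoxon P below 0.001 and
#' a log2 fold difference above 1; immune cells carrying more than 200
#' aberrant genes are reassigned as undetermined; survival stratification
#' splits at the 70th percentile of the focal cluster proportion.
#'
#' @param cna_fold_cutoff segment-mean |log2 ratio| that a gain/loss call
#'   must exceed (strict inequality).
#' @param recurrence_freq minimum within-sample carrier frequency for a gene
#'   to count toward recurrence.
#' @param recurrence_min_samples minimum number of samples at or above
#'   `recurrence_freq`.
#' @param cluster_window_bp width (bp) of the sliding window used for the
#'   functional gene-cluster exclusion.
#' @param go_p_cutoff one-sided hypergeometric P threshold for window
#'   enrichment.
#' @param marker_p,marker_fold Wilcoxon marker thresholds (P; log2 fold).
#' @param perm_p permutation P threshold for differential calls.
#' @param burden_undetermined immune cells with a CNA burden strictly above
#'   this many genes are flagged undetermined.
#' @param high_group_percentile percentile (0-100) defining the high group in
#'   survival stratification.
#' @param n_permutations label permutations for permutation t-tests.
#' @param rng_seed integer seed applied by stages that draw random numbers.
#' @param smoothing_window centered moving-average window (genes) for the
#'   relative expression track.
#' @param cbs_alpha,cbs_n_perm,cbs_min_width segmentation controls: split
#'   acceptance level, permutations per split decision, and minimum segment
#'   width in genes.
#' @param cbs_undo_sd sd-undo merge threshold for adjacent segments (as in
#'   DNAcopy's `undo.splits = "sdundo"`); `NULL` disables the merge.
#' @param step_fold minimum per-step log2 fold for stepwise-gene calls.
#' @param expr_min,absent_max detection-fraction thresholds for
#'   ligand-receptor interdependence ("expressed" / "absent").
#' @param lr_min_increase minimum overall increase in ligand detection
#'   fraction from the first to the last tissue.
#' @param cis_r_min,cis_burden_min carcinoma-in-situ call thresholds:
#'   minimum Pearson correlation to the mean malignant track and minimum
#'   CNA burden in genes.
#' @param min_expressed_mean genes with mean count below this are dropped
#'   from the copy-number track (standard low-expression filter).
#' @param top_k_markers markers per cluster used for the signature matrix.
#' @param ntp_n_perm,ntp_fdr_max nearest-template prediction controls.
#' @param survival_horizon optional follow-up truncation (same unit as the
#'   survival times); `NULL` for no truncation.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cna_fold_cutoff = 0.1,
                            recurrence_freq = 0.05,
                            recurrence_min_samples = 2,
                            cluster_window_bp = 1e6,
                            go_p_cutoff = 0.05,
                            marker_p = 0.001,
                            marker_fold = 1.0,
                            perm_p = 0.001,
                            burden_undetermined = 200,
                            high_group_percentile = 70,
                            n_permutations = 10000,
                            rng_seed = 1L,
                            smoothing_window = 101,
                            cbs_alpha = 0.01,
                            cbs_n_perm = 1000,
                            cbs_min_width = 5,
                            cbs_undo_sd = 4,
                            step_fold = 0.25,
                            expr_min = 0.25,
                            absent_max = 0.05,
                            lr_min_increase = 0.1,
                            cis_r_min = 0.3,
                            cis_burden_min = 50,
                            min_expressed_mean = 0.1,
                            top_k_markers = 50,
                            ntp_n_perm = 1000,
                            ntp_fdr_max = 0.05,
                            survival_horizon = NULL) {
  cfg <- list(cna_fold_cutoff = cna_fold_cutoff,
              recurrence_freq = recurrence_freq,
              recurrence_min_samples = recurrence_min_samples,
              cluster_window_bp = cluster_window_bp,
              go_p_cutoff = go_p_cutoff,
              marker_p = marker_p,
              marker_fold = marker_fold,
              perm_p = perm_p,
              burden_undetermined = burden_undetermined,
              high_group_percentile = high_group_percentile,
              n_permutations = as.integer(n_permutations),
              rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
              smoothing_window = as.integer(smoothing_window),
              cbs_alpha = cbs_alpha,
              cbs_n_perm = as.integer(cbs_n_perm),
              cbs_min_width = as.integer(cbs_min_width),
              cbs_undo_sd = cbs_undo_sd,
              step_fold = step_fold,
              expr_min = expr_min,
              absent_max = absent_max,
              lr_min_increase = lr_min_increase,
              cis_r_min = cis_r_min,
              cis_burden_min = cis_burden_min,
              min_expressed_mean = min_expressed_mean,
              top_k_markers = as.integer(top_k_markers),
              ntp_n_perm = as.integer(ntp_n_perm),
              ntp_fdr_max = ntp_fdr_max,
              survival_horizon = survival_horizon)

  pos <- c("cna_fold_cutoff", "recurrence_freq", "recurrence_min_samples",
           "cluster_window_bp", "go_p_cutoff", "marker_p", "marker_fold",
           "perm_p", "burden_undetermined", "n_permutations",
           "smoothing_window", "cbs_alpha", "cbs_n_perm", "cbs_min_width",
           "step_fold", "expr_min", "ntp_n_perm", "ntp_fdr_max",
           "top_k_markers")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      stop("config field '", nm, "' must be a positive scalar", call. = FALSE)
    }
  }
  if (cfg$high_group_percentile <= 0 || cfg$high_group_percentile >= 100) {
    stop("high_group_percentile must lie in (0, 100)", call. = FALSE)
  }
  if (cfg$n_permutations < 100) {
    stop("n_permutations must be at least 100", call. = FALSE)
  }
  if (cfg$absent_max < 0 || cfg$absent_max >= 1) {
    stop("absent_max must lie in [0, 1)", call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
#' @method print pipeline_config
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else format(x[[nm]])))
  }
  invisible(x)
}
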