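#' Permutation t-test
#'
#' Welch t statistic on the observed labels with a label-permutation null.
#' When the number of distinct group-A label assignments `choose(n, n_a)` is
#' at most `n_permutations`, the null is enumerated exactly and the p-value
#' is the fraction of all assignments (including the observed one) reaching
#' `|t*| >= |t_obs|`; otherwise `n_permutations` random assignments are
#' sampled and `p = (1 + exceedances) / (1 + n_permutations)`.
#'
#' @param values_a,values_b numeric vectors (each of length >= 2).
#' @param n_permutations permutation budget.
#' @param rng_seed optional seed for the sampled path.
#' @return list with `t_stat`, `perm_p`, `n_permutations`, `method`
#'   (`"exact"` or `"sampled"`).
#' @export
permuted_t_test <- function(values_a, values_b, n_permutations = 10000,
                            rng_seed = NULL) {
  na <- length(values_a)
  nb <- length(values_b)
  if (na < 2 || nb < 2) {
    stop("both groups must have at least 2 values", call. = FALSE)
  }
  pooled <- c(values_a, values_b)
  if (sd(pooled) == 0) {
    return(list(t_stat = 0, perm_p = 1, n_permutations = n_permutations,
                method = "degenerate"))
  }
  welch <- function(ia) {
    a <- pooled[ia]
    b <- pooled[-ia]
    d <- sqrt(var(a) / na + var(b) / nb)
    if (d == 0) {
      if (mean(a) == mean(b)) return(0)
      return(sign(mean(a) - mean(b)) * Inf)
    }
    (mean(a) - mean(b)) / d
  }
  t_obs <- welch(seq_len(na))
  total <- choose(na + nb, na)
  if (total <= n_permutations) {
    combos <- combn(na + nb, na)
    ts <- apply(combos, 2, welch)
    p <- sum(abs(ts) >= abs(t_obs) - 1e-12) / total
    return(list(t_stat = t_obs, perm_p = p,
                n_permutations = as.integer(total), method = "exact"))
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  # canonical orientation (smaller group first) so that the sampled label
  # permutations -- and hence the p-value -- are identical under group swap
  flip <- na > nb
  res <- if (flip) {
    cpp_perm_welch(values_b, values_a, as.integer(n_permutations))
  } else {
    cpp_perm_welch(values_a, values_b, as.integer(n_permutations))
  }
  list(t_stat = if (flip) -res$t else res$t,
       perm_p = (1 + res$count) / (1 + n_permutations),
       n_permutations = as.integer(n_permutations), method = "sampled")
}

# Gene-wise sampled permutation Welch t between two cell groups on a dense
# matrix; shared label permutations across genes. Returns a data.frame of
# t_stat, perm_p and the mean difference (a - b).
.perm_t_matrix <- function(X, cells_a, cells_b, n_permutations) {
  ia <- match(cells_a, colnames(X))
  ib <- match(cells_b, colnames(X))
  res <- cpp_perm_welch_matrix(X, ia - 1L, ib - 1L,
                               as.integer(n_permutations))
  data.frame(gene_id = rownames(X), t_stat = res[, 1],
             perm_p = (1 + res[, 2]) / (1 + n_permutations),
             fold_diff = rowMeans(X[, ia, drop = FALSE]) -
               rowMeans(X[, ib, drop = FALSE]),
             mean_a = rowMeans(X[, ia, drop = FALSE]),
             mean_b = rowMeans(X[, ib, drop = FALSE]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# One rank-sum contrast. Exact (via wilcox.test) for small untied samples,
# vectorized normal approximation with tie correction otherwise.
.rank_sum_p <- function(X, in_cells) {
  n <- ncol(X)
  n1 <- sum(in_cells)
  n2 <- n - n1
  if (n <= 100) {
    return(apply(X, 1, function(v) {
      suppressWarnings(wilcox.test(v[in_cells], v[!in_cells])$p.value)
    }))
  }
  R <- t(apply(X, 1, rank))
  W <- rowSums(R[, in_cells, drop = FALSE]) - n1 * (n1 + 1) / 2
  ties_term <- apply(X, 1, function(v) {
    tt <- table(v)
    sum(tt^3 - tt)
  })
  mu <- n1 * n2 / 2
  sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - ties_term / (n * (n - 1))))
  z <- W - mu
  corr <- sign(z) * 0.5
  z <- (z - corr) / sigma
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma == 0] <- 1
  pmin(p, 1)
}

#' Wilcoxon rank-sum cluster markers
#'
#' One-vs-rest differential expression per cluster. A gene is a marker for a
#' cluster when the rank-sum P is below `marker_p` and the log2 fold
#' difference (mean in-cluster minus mean out-of-cluster, log-normalized
#' scale) exceeds `marker_fold` in favor of the cluster.
#'
#' @param cm a [cell_matrix()] (normalized internally if counts).
#' @param cluster_labels per-cell labels; defaults to
#'   `cm$cell_meta$cluster_label`.
#' @param config a [pipeline_config()] supplying `marker_p` and
#'   `marker_fold`.
#' @return data.frame of markers: cluster, gene_id, p, fold (log2),
#'   mean_in, mean_out.
#' @export
wilcoxon_markers <- function(cm, cluster_labels = NULL,
                             config = pipeline_config()) {
  stopifnot(inherits(cm, "cell_matrix"))
  if (is.null(cluster_labels)) cluster_labels <- cm$cell_meta$cluster_label
  stopifnot(length(cluster_labels) == ncol(cm$values))
  clusters <- unique(cluster_labels)
  if (length(clusters) < 2) stop("need >= 2 clusters", call. = FALSE)
  X <- as.matrix(normalize_cells(cm)$values)
  out <- list()
  for (cl in clusters) {
    in_cells <- cluster_labels == cl
    if (sum(in_cells) < 3) {
      warning("cluster '", cl, "' has < 3 cells; skipped")
      next
    }
    p <- .rank_sum_p(X, in_cells)
    fold <- rowMeans(X[, in_cells, drop = FALSE]) -
      rowMeans(X[, !in_cells, drop = FALSE])
    sel <- p < config$marker_p & fold > config$marker_fold
    if (!any(sel)) next
    out[[cl]] <- data.frame(cluster = cl, gene_id = rownames(X)[sel],
                            p = p[sel], fold = fold[sel],
                            mean_in = rowMeans(X[sel, in_cells,
                                                 drop = FALSE]),
                            mean_out = rowMeans(X[sel, !in_cells,
                                                  drop = FALSE]),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(out) == 0) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cluster, res$p, -res$fold), ]
}

#' Copy-number-dependent genes
#'
#' Genes whose smoothed copy-number track AND expression are both
#' differentially altered between two cell groups, in the same direction:
#' both permutation P below `perm_p`, expression |log2 fold| above
#' `marker_fold`, track |difference| above `cna_fold_cutoff`, and matching
#' signs (concomitant dosage and transcription change).
#'
#' @param result a [infer_cna()] result (supplies the tracks).
#' @param cm the expression [cell_matrix()].
#' @param cells_a,cells_b disjoint cell-id groups (e.g. LP CIS cells vs NL
#'   epithelial cells).
#' @param config a [pipeline_config()]; `rng_seed` fixes the permutations.
#' @return data.frame of reported genes (gene_id, cna_fold_diff,
#'   cna_perm_p, expr_fold_diff, expr_perm_p, concordant); the full
#'   per-gene table is attached as attribute `"all"`.
#' @export
cna_dependent_genes <- function(result, cm, cells_a, cells_b,
                                config = pipeline_config()) {
  if (length(intersect(cells_a, cells_b)) > 0) {
    stop("cell groups overlap", call. = FALSE)
  }
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  tr <- .perm_t_matrix(result$tracks, cells_a, cells_b,
                       config$n_permutations)
  X <- as.matrix(normalize_cells(cm)$values)[rownames(result$tracks), ,
                                             drop = FALSE]
  ex <- .perm_t_matrix(X, cells_a, cells_b, config$n_permutations)
  all_tab <- data.frame(gene_id = tr$gene_id,
                        cna_fold_diff = tr$fold_diff,
                        cna_perm_p = tr$perm_p,
                        expr_fold_diff = ex$fold_diff,
                        expr_perm_p = ex$perm_p,
                        stringsAsFactors = FALSE)
  all_tab$concordant <- sign(all_tab$cna_fold_diff) ==
    sign(all_tab$expr_fold_diff)
  sel <- all_tab$cna_perm_p < config$perm_p &
    all_tab$expr_perm_p < config$perm_p &
    abs(all_tab$expr_fold_diff) > config$marker_fold &
    abs(all_tab$cna_fold_diff) > config$cna_fold_cutoff &
    all_tab$concordant
  out <- all_tab[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- all_tab
  out
}

#' Stepwise-expressed genes across progression
#'
#' A gene is stepwise-up for a cell type when its mean log-normalized
#' expression increases at every adjacent tissue step of the progression
#' order (default NL, LP, CA), each step exceeding `step_fold` log2 units
#' with permutation P below `perm_p`; stepwise-down is symmetric.
#'
#' @param cm a [cell_matrix()].
#' @param cell_type cell type to analyse (must exist in every listed
#'   tissue).
#' @param tissues progression order.
#' @param config a [pipeline_config()]; `rng_seed` fixes the permutations.
#' @return data.frame of stepwise genes with per-tissue means and
#'   `direction`; full table in attribute `"all"`.
#' @export
stepwise_genes <- function(cm, cell_type, tissues = c("NL", "LP", "CA"),
                           config = pipeline_config()) {
  stopifnot(inherits(cm, "cell_matrix"))
  groups <- lapply(tissues, function(tt) {
    cells_where(cm, tissue = tt, cell_type = cell_type)
  })
  names(groups) <- tissues
  empty <- tissues[lengths(groups) == 0]
  if (length(empty) > 0) {
    stop("cell type '", cell_type, "' missing in tissue(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  X <- as.matrix(normalize_cells(cm)$values)
  steps <- vector("list", length(tissues) - 1)
  for (s in seq_len(length(tissues) - 1)) {
    steps[[s]] <- .perm_t_matrix(X, groups[[s + 1]], groups[[s]],
                                 config$n_permutations)
  }
  means <- sapply(groups, function(cells) {
    rowMeans(X[, cells, drop = FALSE])
  })
  colnames(means) <- paste0("mean_", tissues)
  sig <- sapply(steps, function(d) d$perm_p < config$perm_p)
  diffs <- sapply(steps, function(d) d$fold_diff)
  up <- rowSums(sig & diffs > config$step_fold) == length(steps)
  down <- rowSums(sig & diffs < -config$step_fold) == length(steps)
  all_tab <- data.frame(gene_id = rownames(X), means,
                        direction = ifelse(up, "up",
                                           ifelse(down, "down", "none")),
                        stringsAsFactors = FALSE, row.names = NULL)
  for (s in seq_along(steps)) {
    all_tab[[paste0("p_step", s)]] <- steps[[s]]$perm_p
    all_tab[[paste0("fold_step", s)]] <- steps[[s]]$fold_diff
  }
  out <- all_tab[all_tab$direction != "none", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- all_tab
  out
}
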