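#' Non-negative least squares (Lawson-Hanson)
#'
#' Minimizes `||A x - b||` subject to `x >= 0` by the classic active-set
#' algorithm.
#'
#' @param A numeric matrix (rows >= cols recommended).
#' @param b numeric right-hand side.
#' @param tol numerical tolerance on the dual feasibility check.
#' @return list with `x` (coefficients) and `residual` (the 2-norm of
#'   `b - A x`).
#' @export
nnls_fit <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  scale <- max(abs(crossprod(A, b)), 1)
  for (iter in seq_len(30 * n)) {
    w <- drop(crossprod(A, b - A %*% x))
    free <- which(!passive)
    if (length(free) == 0 || max(w[free]) <= tol * scale) break
    passive[free[which.max(w[free])]] <- TRUE
    repeat {
      s <- numeric(n)
      P <- which(passive)
      fit <- qr(A[, P, drop = FALSE])
      s[P] <- qr.coef(fit, b)
      s[P][is.na(s[P])] <- 0
      if (all(s[P] > tol)) {
        x <- s
        break
      }
      neg <- P[s[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
  }
  list(x = x, residual = sqrt(sum((b - A %*% x)^2)))
}

#' Build a cluster signature matrix from single cells
#'
#' Markers are the union over clusters of the `top_k` genes by one-vs-rest
#' Wilcoxon ranking (ascending p, ties broken by descending log2 fold)
#' among genes satisfying the marker rule (P below `marker_p`, log2 fold
#' above `marker_fold` in favor of the cluster); signature entries are
#' per-cluster mean linear-scale expression of the marker genes.
#'
#' @param cm a counts-scale [cell_matrix()].
#' @param cluster_labels per-cell labels; default
#'   `cm$cell_meta$cluster_label`.
#' @param top_k markers per cluster (default 50).
#' @param min_cells clusters below this size are excluded with a warning
#'   (default 20).
#' @param marker_p,marker_fold the marker thresholds (defaults 0.001 and
#'   1 log2 unit, the published marker rule).
#' @return list of class `signature_matrix`: `values` (marker genes x
#'   clusters, linear scale), `markers` (list of per-cluster marker ids).
#' @export
build_signature <- function(cm, cluster_labels = NULL, top_k = 50,
                            min_cells = 20, marker_p = 0.001,
                            marker_fold = 1) {
  stopifnot(inherits(cm, "cell_matrix"))
  if (is.null(cluster_labels)) cluster_labels <- cm$cell_meta$cluster_label
  counts <- as.matrix(cm$values)
  keep <- names(which(table(cluster_labels) >= min_cells))
  dropped <- setdiff(unique(cluster_labels), keep)
  if (length(dropped) > 0) {
    warning("cluster(s) below ", min_cells, " cells excluded: ",
            paste(dropped, collapse = ", "))
  }
  if (length(keep) < 2) {
    stop("need >= 2 clusters of at least ", min_cells, " cells",
         call. = FALSE)
  }
  X <- as.matrix(normalize_cells(cm)$values)
  markers <- list()
  for (cl in keep) {
    in_cells <- cluster_labels == cl
    p <- .rank_sum_p(X, in_cells)
    fold <- rowMeans(X[, in_cells, drop = FALSE]) -
      rowMeans(X[, !in_cells, drop = FALSE])
    cand <- which(p < marker_p & fold > marker_fold)
    if (length(cand) == 0) {
      stop("marker selection failed: cluster '", cl,
           "' has no distinguishing over-expressed gene", call. = FALSE)
    }
    ord <- cand[order(p[cand], -fold[cand])]
    markers[[cl]] <- rownames(X)[utils::head(ord, top_k)]
  }
  genes <- sort(unique(unlist(markers)))
  sig <- sapply(keep, function(cl) {
    rowMeans(counts[genes, cluster_labels == cl, drop = FALSE])
  })
  rownames(sig) <- genes
  if (any(colSums(sig) == 0)) {
    stop("signature has an all-zero column", call. = FALSE)
  }
  structure(list(values = sig, markers = markers, top_k = top_k),
            class = "signature_matrix")
}

#' Estimate cluster proportions in bulk samples
#'
#' Per bulk sample, a non-negative least squares fit of the bulk profile on
#' the signature columns over the shared genes, with the coefficients
#' normalized to sum to one. Proportions are invariant to scaling a bulk
#' sample by a positive constant.
#'
#' @param bulk genes x samples matrix of linear-scale bulk expression.
#' @param signature a [build_signature()] result or a plain genes x
#'   clusters matrix.
#' @param min_overlap minimum genes shared between bulk and signature.
#' @return list of class `proportion_table`: `proportions` (samples x
#'   clusters, rows summing to 1) and `residual` (per-sample fit residual
#'   norm).
#' @export
estimate_proportions <- function(bulk, signature, min_overlap = 50) {
  sig <- if (inherits(signature, "signature_matrix")) signature$values else
    as.matrix(signature)
  genes <- intersect(rownames(bulk), rownames(sig))
  if (length(genes) < min_overlap) {
    stop("only ", length(genes), " gene(s) shared between bulk and ",
         "signature; need >= ", min_overlap, call. = FALSE)
  }
  A <- sig[genes, , drop = FALSE]
  B <- as.matrix(bulk)[genes, , drop = FALSE]
  props <- matrix(NA_real_, ncol(B), ncol(A),
                  dimnames = list(colnames(B), colnames(A)))
  residual <- setNames(numeric(ncol(B)), colnames(B))
  for (s in seq_len(ncol(B))) {
    fit <- nnls_fit(A, B[, s])
    total <- sum(fit$x)
    if (total == 0) {
      warning("all-zero fit for sample ", colnames(B)[s])
      props[s, ] <- NA_real_
    } else {
      props[s, ] <- fit$x / total
    }
    residual[s] <- fit$residual
  }
  structure(list(proportions = props, residual = residual),
            class = "proportion_table")
}

#' Nearest-template prediction
#'
#' Assigns each profile to the template with the smallest cosine distance
#' (1 - cosine similarity) over that template's marker genes. Significance
#' of an assignment is estimated by re-computing the distance after random
#' gene-label permutations of the profile; p-values are
#' Benjamini-Hochberg-adjusted across profiles and assignments with FDR
#' above `fdr_max` are reported unassigned.
#'
#' @param profiles genes x cells (or bulk samples) matrix.
#' @param templates a [build_signature()] result, or a genes x clusters
#'   matrix (all its genes then serve as every template's markers).
#' @param n_perm gene-label permutations per profile.
#' @param fdr_max FDR ceiling for an assignment.
#' @param rng_seed optional seed.
#' @return data.frame: id, template (NA when unassigned), distance, p, fdr.
#' @export
ntp_assign <- function(profiles, templates, n_perm = 1000, fdr_max = 0.05,
                       rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (inherits(templates, "signature_matrix")) {
    tmpl <- templates$values
    markers <- templates$markers
  } else {
    tmpl <- as.matrix(templates)
    markers <- setNames(rep(list(rownames(tmpl)), ncol(tmpl)),
                        colnames(tmpl))
  }
  profiles <- as.matrix(profiles)
  cos_dist <- function(a, b) {
    na <- sqrt(sum(a^2))
    nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(1)
    1 - sum(a * b) / (na * nb)
  }
  n_cells <- ncol(profiles)
  out <- data.frame(id = colnames(profiles),
                    template = NA_character_, distance = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (ci in seq_len(n_cells)) {
    prof <- profiles[, ci]
    d <- rep(NA_real_, ncol(tmpl))
    for (k in seq_len(ncol(tmpl))) {
      m <- markers[[colnames(tmpl)[k]]]
      hit <- m[m %in% names(prof)]
      if (length(hit) < length(m) / 2) next  # too many missing markers
      d[k] <- cos_dist(prof[hit], tmpl[hit, k])
    }
    if (all(is.na(d))) next
    best <- which.min(d)
    m <- markers[[colnames(tmpl)[best]]]
    hit <- m[m %in% names(prof)]
    null_d <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      null_d[b] <- cos_dist(sample(prof, length(hit)), tmpl[hit, best])
    }
    out$template[ci] <- colnames(tmpl)[best]
    out$distance[ci] <- d[best]
    out$p[ci] <- (1 + sum(null_d <= d[best] + 1e-12)) / (1 + n_perm)
  }
  out$fdr <- p.adjust(out$p, method = "BH")
  unassign <- !is.na(out$fdr) & out$fdr > fdr_max
  out$template[unassign] <- NA_character_
  out
}
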