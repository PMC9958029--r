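#' Gene filters for expression-based copy-number inference
#'
#' Removes genes whose expression moves for reasons other than DNA dosage:
#' (a) genes on the sex chromosomes, (b) genes with immune-related RNA
#' biotypes (immunoglobulin and T-cell-receptor segments, `IG_*`/`TR_*`),
#' and (c) chromosomal gene clusters that are functionally co-expressed —
#' any window of `cluster_window_bp` (anchored at each gene's midpoint,
#' spanning `[mid, mid + window)`) in which a gene-ontology term is enriched
#' by a one-sided hypergeometric test at `P < go_p_cutoff` with at least 3
#' window genes annotated to the term; the window genes annotated to the
#' enriched term are excluded.
#'
#' @param gene_meta gene annotation (as in [cell_matrix()]), with a
#'   `go_terms` list column.
#' @param go_background optional named list mapping term id to a character
#'   vector of gene ids (genome-wide background); defaults to the map
#'   implied by `gene_meta$go_terms` with all `gene_meta` genes as the
#'   background universe.
#' @param config a [pipeline_config()].
#' @return integer vector of retained row indices into `gene_meta`, with a
#'   `removed` attribute summarizing counts per filter.
#' @export
filter_gene_set <- function(gene_meta, go_background = NULL,
                            config = pipeline_config()) {
  n <- nrow(gene_meta)
  rank <- chrom_rank(gene_meta$chrom)
  drop_sex <- !is.na(rank) & rank >= 23L
  drop_bio <- grepl("^(IG_|TR_)", gene_meta$biotype)

  go <- gene_meta$go_terms
  if (is.null(go)) go <- replicate(n, character(0), simplify = FALSE)
  if (is.null(go_background)) {
    flat <- data.frame(
      gene = rep(as.character(gene_meta$gene_id), lengths(go)),
      term = unlist(go, use.names = FALSE), stringsAsFactors = FALSE)
    go_background <- split(flat$gene, flat$term)
    n_background <- n
  } else {
    n_background <- length(unique(unlist(go_background, use.names = FALSE)))
  }
  term_sizes <- lengths(go_background)

  drop_go <- rep(FALSE, n)
  mid <- (gene_meta$start_bp + gene_meta$end_bp) / 2
  for (chr in unique(gene_meta$chrom[!drop_sex])) {
    idx <- which(gene_meta$chrom == chr)
    idx <- idx[order(mid[idx])]
    m <- mid[idx]
    for (a in seq_along(idx)) {
      win <- idx[m >= m[a] & m < m[a] + config$cluster_window_bp]
      if (length(win) < 3) next
      terms <- unlist(go[win], use.names = FALSE)
      if (length(terms) == 0) next
      tab <- table(terms)
      tab <- tab[tab >= 3]
      for (term in names(tab)) {
        K <- term_sizes[[term]]
        if (is.null(K) || is.na(K)) next
        k <- tab[[term]]
        p <- phyper(k - 1, K, n_background - K, length(win),
                    lower.tail = FALSE)
        if (p < config$go_p_cutoff) {
          hit <- win[vapply(go[win], function(g) term %in% g, logical(1))]
          drop_go[hit] <- TRUE
        }
      }
    }
  }

  retained <- which(!(drop_sex | drop_bio | drop_go))
  if (length(retained) == 0) {
    stop("degenerate input: no genes retained after copy-number filters",
         call. = FALSE)
  }
  attr(retained, "removed") <- c(sex = sum(drop_sex),
                                 immune_biotype = sum(drop_bio & !drop_sex),
                                 go_cluster = sum(drop_go & !drop_sex &
                                                    !drop_bio))
  retained
}

#' Reference-relative smoothed expression track
#'
#' Subtracts the reference-cell mean from each gene's log-normalized
#' expression, clips the raw ratios to \[-3, 3\], and smooths with a
#' centered moving average of `window` genes within each chromosome (the
#' window is truncated at chromosome ends). The reference is intended to be
#' the immune cells of normal tissue, whose DNA copy number is taken as
#' diploid.
#'
#' @param matrix a log-normalized [cell_matrix()] (already restricted to the
#'   retained gene set).
#' @param reference_cells cell ids of the diploid reference (at least 20).
#' @param cells cell ids to compute tracks for (default: all).
#' @param window moving-average window in genes (odd recommended).
#' @param clip absolute bound applied to raw log ratios before smoothing.
#' @param center `"none"` (default), `"median"`, or `"mode"`: optionally
#'   re-center each cell's raw ratio vector before smoothing, absorbing the
#'   per-cell compositional offset against the reference. `"mode"` centers
#'   on the densest ratio value (the dominant neutral state), which stays
#'   calibrated even when a large fraction of the genome is aberrant,
#'   where the median would be dragged toward the gains.
#' @return numeric matrix (genes x cells) of smoothed log2 ratios.
#' @export
relative_track <- function(matrix, reference_cells, cells = NULL,
                           window = 101, clip = 3,
                           center = c("none", "median", "mode")) {
  center <- match.arg(center)
  stopifnot(inherits(matrix, "cell_matrix"))
  if (matrix$scale != "lognorm") {
    stop("relative_track expects log-normalized expression; ",
         "call normalize_cells() first", call. = FALSE)
  }
  if (length(reference_cells) < 20) {
    stop("insufficient reference: need >= 20 reference cells, got ",
         length(reference_cells), call. = FALSE)
  }
  if (is.null(cells)) cells <- colnames(matrix$values)
  ref_mean <- Matrix::rowMeans(matrix$values[, reference_cells,
                                             drop = FALSE])
  raw <- as.matrix(matrix$values[, cells, drop = FALSE]) - ref_mean
  raw[raw > clip] <- clip
  raw[raw < -clip] <- -clip
  out <- raw
  half <- (window - 1) %/% 2
  chroms <- matrix$gene_meta$chrom
  for (chr in unique(chroms)) {
    rows <- which(chroms == chr)
    ng <- length(rows)
    cs <- apply(raw[rows, , drop = FALSE], 2, cumsum)
    cs <- rbind(0, cs)
    lo <- pmax(seq_len(ng) - half, 1L)
    hi <- pmin(seq_len(ng) + half, ng)
    out[rows, ] <- (cs[hi + 1L, , drop = FALSE] -
                      cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  }
  # Per-cell re-centering is done on the smoothed track (centering commutes
  # with the moving average), where the neutral bulk separates cleanly from
  # gained/lost stretches.
  if (center == "median") {
    out <- sweep(out, 2, apply(out, 2, stats::median))
  } else if (center == "mode") {
    out <- sweep(out, 2, apply(out, 2, function(v) {
      d <- stats::density(v, bw = 0.02, n = 512)
      m0 <- d$x[which.max(d$y)]
      mean(v[abs(v - m0) < 0.05])  # refine on the neutral bulk
    }))
  }
  out
}

.cbs_rec <- function(x, lo, hi, alpha, n_perm, min_width) {
  n <- hi - lo + 1
  if (n < max(2L, 2L * min_width)) return(integer(0))
  res <- cpp_cbs_split(x[lo:hi], n_perm, alpha)
  if (!res$accept) return(integer(0))
  i <- res$i
  j <- res$j
  bps <- integer(0)
  pieces <- list()
  if (i > 0) {
    bps <- c(bps, lo + i - 1L)
    pieces <- c(pieces, list(c(lo, lo + i - 1L)))
  }
  pieces <- c(pieces, list(c(lo + i, lo + j - 1L)))
  if (j < n) {
    bps <- c(bps, lo + j - 1L)
    pieces <- c(pieces, list(c(lo + j, hi)))
  }
  for (pc in pieces) {
    bps <- c(bps, .cbs_rec(x, pc[1], pc[2], alpha, n_perm, min_width))
  }
  bps
}

.merge_short <- function(start, end, x, min_width) {
  means <- mapply(function(s, e) mean(x[s:e]), start, end)
  repeat {
    len <- end - start + 1
    if (length(start) <= 1 || all(len >= min_width)) break
    s <- which(len < min_width)[which.min(len[which(len < min_width)])]
    left_d <- if (s > 1) abs(means[s] - means[s - 1]) else Inf
    right_d <- if (s < length(start)) abs(means[s] - means[s + 1]) else Inf
    into <- if (left_d <= right_d) s - 1L else s + 1L
    lo <- min(start[s], start[into])
    hi <- max(end[s], end[into])
    keep <- setdiff(seq_along(start), c(s, into))
    ins <- sum(keep < s & keep < into)
    start <- append(start[keep], lo, after = ins)
    end <- append(end[keep], hi, after = ins)
    means <- append(means[keep], mean(x[lo:hi]), after = ins)
  }
  data.frame(start = start, end = end, mean = means)
}

# DNAcopy-style "sdundo" merge: iteratively merge the adjacent segment
# pair whose mean difference is smallest relative to its noise scale, while
# that standardized difference stays below undo_sd. The per-gene noise sd
# of the (pre-smoothing) signal is estimated from first differences of the
# smoothed track: diff of a w-gene moving average has sd sigma*sqrt(2)/w.
.undo_merge <- function(seg, x, undo_sd, window, sigma = NULL) {
  # DNAcopy's sdundo rule: undo a split whenever the two segment means
  # differ by less than undo_sd times the per-point sd. When no noise scale
  # is supplied it is estimated from first differences of the smoothed
  # track (sd sigma_s * sqrt(2/w)); a caller holding the unsmoothed values
  # can pass a cleaner estimate, since ramps around true breakpoints
  # contaminate smoothed-track differences.
  if (is.null(sigma)) sigma <- stats::mad(diff(x)) * sqrt(window / 2)
  if (!is.finite(sigma) || sigma <= 0) return(seg)
  repeat {
    if (nrow(seg) <= 1) break
    dmean <- abs(diff(seg$mean))
    k <- which.min(dmean)
    if (dmean[k] >= undo_sd * sigma) break
    seg$end[k] <- seg$end[k + 1]
    seg$mean[k] <- mean(x[seg$start[k]:seg$end[k]])
    seg <- seg[-(k + 1), , drop = FALSE]
  }
  rownames(seg) <- NULL
  seg
}

# Breakpoint refinement against the unsmoothed ratios. Smoothing localizes
# a breakpoint only to about half a window; the raw values pin it to a gene
# or two. Each boundary may move up to half a window, to the position
# minimizing the squared error against the two adjacent segment levels.
.refine_breakpoints <- function(seg, raw, window) {
  if (nrow(seg) <= 1 || window <= 1) return(seg)
  half <- as.integer(window)
  for (k in seq_len(nrow(seg) - 1)) {
    b <- seg$end[k]
    lo <- max(seg$start[k], b - half)
    hi <- min(seg$end[k + 1] - 1L, b + half)
    if (lo >= hi) next
    m1 <- seg$mean[k]
    m2 <- seg$mean[k + 1]
    cand <- lo:hi
    sse <- vapply(cand, function(p) {
      zone <- lo:(hi + 1L)
      sum((raw[zone[zone <= p]] - m1)^2) +
        sum((raw[zone[zone > p]] - m2)^2)
    }, 0)
    best <- cand[which.min(sse)]
    seg$end[k] <- best
    seg$start[k + 1] <- best + 1L
  }
  seg
}

#' Circular binary segmentation of one chromosome's track
#'
#' Recursively finds the arc maximizing the standardized mean-difference
#' statistic between the inside and outside of the arc, accepts the split
#' when its permutation P (over `n_perm` value permutations) is below
#' `alpha`, and recurses into the resulting pieces. Segments shorter than
#' `min_width` genes are then merged into the neighboring segment with the
#' closer mean. Deterministic under the caller's RNG seed; arc ties break
#' toward the smallest start then smallest end.
#'
#' Optionally, spurious splits can be undone the way DNAcopy's
#' `undo.splits = "sdundo"` does: adjacent segments whose means differ by
#' less than `undo_sd` noise standard errors are merged. This counters the
#' over-segmentation that a value-permutation null produces on smoothed
#' (autocorrelated) tracks.
#'
#' @param track ordered smoothed values of one chromosome.
#' @param alpha split acceptance level.
#' @param n_perm permutations per split decision.
#' @param min_width minimum segment width (genes).
#' @param undo_sd if non-NULL, the sd-undo merge threshold (e.g. the default 4).
#' @param window the smoothing window the track was built with (used only
#'   to estimate the per-gene noise scale for the sd-undo merge).
#' @param sigma optional per-point noise sd of the smoothed track for the
#'   sd-undo merge, overriding the internal estimate.
#' @return data.frame with columns `start`, `end` (1-based gene positions
#'   within the track) and `mean`.
#' @export
segment_track <- function(track, alpha = 0.01, n_perm = 1000,
                          min_width = 5, undo_sd = NULL, window = 1,
                          sigma = NULL) {
  n <- length(track)
  if (n < 2 * min_width) {
    warning("track has fewer than 2*min_width genes; returning one segment")
    return(data.frame(start = 1L, end = n, mean = mean(track)))
  }
  bps <- sort(unique(.cbs_rec(track, 1L, n, alpha, n_perm,
                              as.integer(min_width))))
  start <- c(1L, bps + 1L)
  end <- c(bps, n)
  seg <- .merge_short(start, end, track, min_width)
  if (!is.null(undo_sd)) {
    seg <- .undo_merge(seg, track, undo_sd, window, sigma)
  }
  seg
}

#' Call gains and losses on segments
#'
#' A segment is a gain when its mean log2 ratio exceeds `cutoff`, a loss
#' when it lies below `-cutoff` (strict inequalities: "more than" the fold
#' difference cutoff), and neutral otherwise.
#'
#' @param segments data.frame from [segment_track()].
#' @param cutoff fold-difference cutoff on the segment mean (default 0.1).
#' @return `segments` with an added `call` column (gain/loss/neutral).
#' @export
call_cna <- function(segments, cutoff = 0.1) {
  segments$call <- ifelse(segments$mean > cutoff, "gain",
                          ifelse(segments$mean < -cutoff, "loss", "neutral"))
  segments
}

#' Aberrant-gene burden of a called profile
#'
#' Number of genes lying in non-neutral segments.
#'
#' @param segments called segments (one cell; any number of chromosomes).
#' @return integer gene count.
#' @export
cna_burden <- function(segments) {
  sel <- segments$call != "neutral"
  sum(segments$end[sel] - segments$start[sel] + 1L)
}

#' Infer per-cell copy-number profiles from expression
#'
#' The full inference path: apply the gene filters ([filter_gene_set()] plus
#' a low-expression filter on mean counts), log-normalize, compute
#' reference-relative smoothed tracks against the immune cells of normal
#' tissue, segment each cell's track per chromosome by circular binary
#' segmentation, and call gains/losses against the fold cutoff.
#'
#' @param cm a counts-scale (or already log-normalized) [cell_matrix()].
#' @param config a [pipeline_config()]; `rng_seed` fixes the segmentation
#'   permutations.
#' @param cells cell ids to profile (default: all cells).
#' @param reference_cells diploid reference cell ids; default immune cells
#'   (NK/T, B/plasma, macrophage, dendritic, mast) in NL tissue.
#' @param retained optional precomputed retained gene indices.
#' @return list of class `cna_result`: `tracks` (retained genes x cells
#'   smoothed matrix), `segments` (data.frame with cell_id, chrom, start,
#'   end as positions within the retained gene order, global bp bounds,
#'   mean, call), `burden` (named per-cell vector), `gene_meta` (retained
#'   gene annotation), `retained` (indices into `cm$gene_meta`).
#' @export
infer_cna <- function(cm, config = pipeline_config(), cells = NULL,
                      reference_cells = NULL, retained = NULL) {
  stopifnot(inherits(cm, "cell_matrix"))
  if (is.null(reference_cells)) {
    reference_cells <- cells_where(cm, tissue = "NL",
                                   cell_type = IMMUNE_CELL_TYPES)
  }
  if (is.null(retained)) {
    retained <- filter_gene_set(cm$gene_meta, config = config)
    if (cm$scale == "counts" && config$min_expressed_mean > 0) {
      # a gene silent in the diploid reference carries no dosage signal:
      # its log ratio is pinned near zero whatever the copy state
      expressed <- Matrix::rowMeans(cm$values) >= config$min_expressed_mean &
        Matrix::rowMeans(cm$values[, reference_cells, drop = FALSE]) >=
          config$min_expressed_mean
      retained <- retained[expressed[retained]]
    }
  }
  if (is.null(cells)) cells <- colnames(cm$values)
  cmn <- normalize_cells(cm)
  sub <- subset_cells(cmn, genes = retained)
  tracks <- relative_track(sub, reference_cells, cells,
                           window = config$smoothing_window,
                           center = "none")
  raw <- relative_track(sub, reference_cells, cells, window = 1,
                        center = "none")
  # per-cell raw noise scale; breakpoints touch too few differences to
  # disturb this estimate, unlike on the smoothed track
  sigma_cell <- apply(raw, 2, function(v) stats::mad(diff(v)) / sqrt(2)) /
    sqrt(config$smoothing_window)

  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  chroms <- sub$gene_meta$chrom
  chrom_levels <- unique(chroms)
  chrom_rows <- lapply(chrom_levels, function(chr) which(chroms == chr))
  # accumulate plain vectors; building one data.frame per cell-chromosome
  # dominates runtime otherwise
  nslot <- length(cells) * length(chrom_levels)
  acc <- vector("list", nslot)
  slot <- 0
  for (ci in seq_along(cells)) {
    for (k in seq_along(chrom_levels)) {
      rows <- chrom_rows[[k]]
      segs <- suppressWarnings(
        segment_track(tracks[rows, ci], alpha = config$cbs_alpha,
                      n_perm = config$cbs_n_perm,
                      min_width = config$cbs_min_width,
                      undo_sd = config$cbs_undo_sd,
                      window = config$smoothing_window,
                      sigma = sigma_cell[ci]))
      segs <- .refine_breakpoints(segs, raw[rows, ci],
                                  config$smoothing_window)
      # refined boundaries shift mass between segments; recompute means on
      # the smoothed track so they still conserve the track mean
      segs$mean <- vapply(seq_len(nrow(segs)), function(r) {
        mean(tracks[rows[segs$start[r]:segs$end[r]], ci])
      }, 0)
      slot <- slot + 1
      acc[[slot]] <- list(ci = ci, k = k, start = rows[segs$start],
                          end = rows[segs$end], mean = segs$mean)
    }
  }
  ns <- vapply(acc, function(a) length(a$start), 0L)
  acc_start <- unlist(lapply(acc, `[[`, "start"), use.names = FALSE)
  acc_end <- unlist(lapply(acc, `[[`, "end"), use.names = FALSE)
  segments <- data.frame(
    cell_id = rep(cells[vapply(acc, `[[`, 0L, "ci")], ns),
    chrom = rep(chrom_levels[vapply(acc, `[[`, 0L, "k")], ns),
    start = acc_start,
    end = acc_end,
    start_bp = sub$gene_meta$start_bp[acc_start],
    end_bp = sub$gene_meta$end_bp[acc_end],
    mean = unlist(lapply(acc, `[[`, "mean"), use.names = FALSE),
    stringsAsFactors = FALSE)
  # Per-cell neutral-state calibration. The reference-relative track of a
  # cell carries a compositional offset (library renormalization shifts
  # every gene's log ratio when part of the genome is amplified or lost).
  # Segment means cluster tightly, so the densest gene-weighted segment
  # mean identifies the neutral level; segmentation is shift-invariant, so
  # shifting after CBS is exact.
  seg_len <- segments$end - segments$start + 1L
  # Calls use a boundary-trimmed interior mean: the moving average
  # contaminates up to floor(window/2) genes on each side of a breakpoint
  # with the neighboring segment's level, so those genes are excluded from
  # the level estimate (segment membership and the reported full mean,
  # which conserves the track mean, are unchanged).
  half <- config$smoothing_window %/% 2L
  col_of <- match(segments$cell_id, cells)
  trim <- pmin(half, pmax(0L, (seg_len - config$cbs_min_width) %/% 2L))
  call_mean <- vapply(seq_len(nrow(segments)), function(r) {
    mean(tracks[(segments$start[r] + trim[r]):(segments$end[r] - trim[r]),
                col_of[r]])
  }, 0)
  offset <- vapply(seq_along(cells), function(ci) {
    sel <- col_of == ci
    expanded <- rep(call_mean[sel], seg_len[sel])
    d <- stats::density(expanded, bw = 0.03, n = 512)
    m0 <- d$x[which.max(d$y)]
    near <- sel & abs(call_mean - m0) < 0.06
    if (!any(near)) return(m0)
    sum(call_mean[near] * seg_len[near]) / sum(seg_len[near])
  }, 0)
  segments$mean <- segments$mean - offset[col_of]
  call_mean <- call_mean - offset[col_of]
  tracks <- tracks - rep(offset, each = nrow(tracks))
  segments$call <- ifelse(call_mean > config$cna_fold_cutoff, "gain",
                          ifelse(call_mean < -config$cna_fold_cutoff,
                                 "loss", "neutral"))
  burden <- vapply(split(segments, segments$cell_id), cna_burden, 0)
  burden <- burden[cells]
  names(burden) <- cells

  structure(list(tracks = tracks, segments = segments, burden = burden,
                 gene_meta = sub$gene_meta, retained = retained,
                 config = config),
            class = "cna_result")
}

#' @export
#' @method print cna_result
print.cna_result <- function(x, ...) {
  cat(sprintf("cna_result: %d genes x %d cells; %d segments; mean burden %.1f\n",
              nrow(x$tracks), ncol(x$tracks), nrow(x$segments),
              mean(x$burden)))
  invisible(x)
}

#' Per-gene call matrix of a cna_result
#'
#' Expands segment calls to a genes x cells integer matrix
#' (+1 gain, -1 loss, 0 neutral).
#'
#' @param result a [infer_cna()] result.
#' @return integer matrix.
#' @export
cna_call_matrix <- function(result) {
  out <- matrix(0L, nrow(result$tracks), ncol(result$tracks),
                dimnames = dimnames(result$tracks))
  seg <- result$segments[result$segments$call != "neutral", , drop = FALSE]
  if (nrow(seg) > 0) {
    cols <- match(seg$cell_id, colnames(out))
    for (r in seq_len(nrow(seg))) {
      out[seg$start[r]:seg$end[r], cols[r]] <-
        if (seg$call[r] == "gain") 1L else -1L
    }
  }
  out
}

#' Recurrent copy-number aberrations of a tissue type
#'
#' Per gene and direction, the within-sample carrier frequency is the
#' fraction of the sample's profiled cells calling the gene in that
#' direction. A gene is recurrent when its frequency reaches
#' `recurrence_freq` in at least `recurrence_min_samples` samples of the
#' tissue type; maximal runs of consecutive recurrent genes on one
#' chromosome with the same direction are merged into regions.
#'
#' @param result a [infer_cna()] result covering the relevant cells.
#' @param cell_meta cell metadata (with `sample_id`, `tissue_type`,
#'   `cell_type`).
#' @param tissue_type tissue to analyse.
#' @param config a [pipeline_config()].
#' @param cell_types cell types whose cells enter the frequencies (default
#'   epithelial, i.e. the epithelial/malignant lineage).
#' @return data.frame of recurrent regions: tissue_type, chrom, start/end
#'   gene ids and bp bounds, n_genes, direction, n_samples_passing, and the
#'   mean within-region carrier frequency per sample (as a `freq_` column
#'   per sample).
#' @export
recurrent_cna <- function(result, cell_meta, tissue_type,
                          config = pipeline_config(),
                          cell_types = "epithelial") {
  meta <- cell_meta[match(colnames(result$tracks), cell_meta$cell_id), ]
  sel <- meta$tissue_type == tissue_type & meta$cell_type %in% cell_types
  samples <- unique(meta$sample_id[sel])
  if (length(samples) < 2) {
    stop("recurrence requires >= 2 samples in tissue type '", tissue_type,
         "'; found ", length(samples), call. = FALSE)
  }
  calls <- cna_call_matrix(result)[, sel, drop = FALSE]
  sample_of <- meta$sample_id[sel]
  gm <- result$gene_meta

  regions <- list()
  for (dir in c("gain", "loss")) {
    target <- if (dir == "gain") 1L else -1L
    freq <- sapply(samples, function(s) {
      rowMeans(calls[, sample_of == s, drop = FALSE] == target)
    })
    recurrent <- rowSums(freq >= config$recurrence_freq) >=
      config$recurrence_min_samples
    if (!any(recurrent)) next
    idx <- which(recurrent)
    run_id <- cumsum(c(TRUE, diff(idx) != 1L |
                         gm$chrom[idx[-1]] != gm$chrom[idx[-length(idx)]]))
    for (run in split(idx, run_id)) {
      f <- colMeans(freq[run, , drop = FALSE])
      row <- data.frame(tissue_type = tissue_type,
                        chrom = gm$chrom[run[1]],
                        start_gene = gm$gene_id[run[1]],
                        end_gene = gm$gene_id[run[length(run)]],
                        start_idx = run[1], end_idx = run[length(run)],
                        start_bp = gm$start_bp[run[1]],
                        end_bp = gm$end_bp[run[length(run)]],
                        n_genes = length(run), direction = dir,
                        n_samples_passing =
                          sum(f >= config$recurrence_freq),
                        stringsAsFactors = FALSE)
      for (s in samples) row[[paste0("freq_", s)]] <- f[[s]]
      regions[[length(regions) + 1]] <- row
    }
  }
  if (length(regions) == 0) {
    return(data.frame())
  }
  do.call(rbind, regions)
}

#' Compare aberrant-gene burden between two cell groups
#'
#' Group means of the per-cell burden plus a permutation P-value for the
#' mean difference (label permutations of the pooled burdens).
#'
#' @param burden_a,burden_b per-cell burdens of the two groups.
#' @param n_permutations label permutations.
#' @param rng_seed optional seed.
#' @return list with `mean_a`, `mean_b`, `diff`, `perm_p`.
#' @export
burden_contrast <- function(burden_a, burden_b, n_permutations = 10000,
                            rng_seed = NULL) {
  stopifnot(length(burden_a) >= 1, length(burden_b) >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  pooled <- c(burden_a, burden_b)
  na <- length(burden_a)
  obs <- mean(burden_a) - mean(burden_b)
  count <- 0L
  for (b in seq_len(n_permutations)) {
    ia <- sample.int(length(pooled), na)
    d <- mean(pooled[ia]) - mean(pooled[-ia])
    if (abs(d) >= abs(obs) - 1e-12) count <- count + 1L
  }
  list(mean_a = mean(burden_a), mean_b = mean(burden_b), diff = obs,
       perm_p = (1 + count) / (1 + n_permutations),
       n_permutations = n_permutations)
}
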