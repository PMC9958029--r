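CELL_TYPES <- c("epithelial", "fibroblast", "NK/T", "B/plasma",
                "macrophage", "endothelial")

#' Specification of a synthetic stepwise-progression cohort
#'
#' Describes a multi-patient cohort over the four stepwise tissue types
#' (NL normal, LP leukoplakia, CA primary carcinoma, LN nodal metastasis)
#' with planted ground truth: clonal copy-number segments that scale
#' expression multiplicatively, a carcinoma-in-situ (CIS) subclone among LP
#' epithelial cells, stepwise ligand programs in fibroblasts with matched
#' receptor programs in malignant cells, per-cell-type marker genes, and a
#' co-expressed functional gene cluster that mimics a copy-number gain.
#'
#' Counts are negative binomial around per-(gene, cell type, tissue) means;
#' a gene inside a carried copy-number segment has its mean multiplied by
#' the segment's `copy_ratio` (1.5 for a single-copy gain, 0.5 for a
#' single-copy loss — diploid dosage arithmetic) unless the gene is listed
#' as dosage-decoupled. Cell-type identity has two layers: a genome-wide
#' mild log-normal factor per (gene, type), and a small set of strong
#' markers confined to chromosome X and immunoglobulin-biotype genes so the
#' autosomal copy-number channel stays clean after the standard gene
#' filters — the idealization the real filters are designed to approximate.
#'
#' @param n_patients named integer vector of patients per tissue type.
#' @param cells_per_sample cells drawn per sample.
#' @param genes_per_chrom,n_autosomes,n_x_genes,gene_spacing_bp genome
#'   layout: `n_autosomes` autosomes carrying `genes_per_chrom` genes each
#'   at `gene_spacing_bp` spacing, plus `n_x_genes` genes on chrX.
#' @param mixtures 4 x 6 matrix of cell-type proportions per tissue
#'   (rows NL/LP/CA/LN); `NULL` for the built-in default.
#' @param cna_segments data.frame(chrom, start, end, direction, copy_ratio,
#'   carrier, carrier_fraction) with `start`/`end` as within-chromosome gene
#'   positions and `carrier` one of `"clone"` (all malignant + CIS cells) or
#'   `"hpvneg"` (HPV-negative malignant cells only); `NULL` for the default
#'   four 50-gene segments.
#' @param decoupled_genes within-clone gene ids whose expression ignores
#'   their copy state (dosage-decoupled); default 5 genes inside the chr1
#'   gain.
#' @param cis_fraction fraction of LP epithelial cells drawn from the
#'   malignant clone (the planted CIS subclone); 0 disables it.
#' @param n_hpv_pos_ca number of HPV-positive CA patients (the rest are
#'   negative; LP patients are always HPV-negative).
#' @param type_factor_sdlog sdlog of the genome-wide per-(gene,type)
#'   log-normal identity factor.
#' @param marker_fold,n_markers_per_type strong marker layer on chrX.
#' @param base_mean_meanlog,base_mean_sdlog log-normal law of gene base
#'   mean counts.
#' @param nb_size negative-binomial size (shared dispersion).
#' @param libsize_sdlog per-cell log-normal library-size factor.
#' @param mixture_concentration Dirichlet concentration for per-sample
#'   jitter of the tissue mixture.
#' @param go_n_terms number of generic gene-ontology terms scattered over
#'   the genome (plus one planted co-expression cluster term).
#' @param lig_step_mult,epi_step_mult per-tissue (NL, LP, CA, LN) mean
#'   multipliers of the stepwise fibroblast-ligand and epithelial programs.
#' @param rng_seed integer seed; `NULL` to use the current RNG state.
#' @return a validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = c(NL = 9, LP = 4, CA = 20, LN = 4),
                        cells_per_sample = 200,
                        genes_per_chrom = 140,
                        n_autosomes = 6,
                        n_x_genes = 72,
                        gene_spacing_bp = 150000,
                        mixtures = NULL,
                        cna_segments = NULL,
                        decoupled_genes = NULL,
                        cis_fraction = 0.10,
                        n_hpv_pos_ca = 6,
                        type_factor_sdlog = 0.02,
                        marker_fold = 6,
                        n_markers_per_type = 12,
                        base_mean_meanlog = log(90),
                        base_mean_sdlog = 0.4,
                        nb_size = 90,
                        libsize_sdlog = 0.15,
                        mixture_concentration = 100,
                        go_n_terms = 40,
                        lig_step_mult = c(1, 4, 16, 16),
                        epi_step_mult = c(1, 2, 4, 4),
                        rng_seed = 1L) {
  stopifnot(all(TISSUE_TYPES %in% names(n_patients)),
            all(n_patients >= 1), cells_per_sample >= 1,
            cis_fraction >= 0, cis_fraction < 1,
            nb_size > 0, n_autosomes >= 2, genes_per_chrom >= 20)
  if (is.null(mixtures)) {
    mixtures <- rbind(
      NL = c(0.35, 0.15, 0.22, 0.12, 0.09, 0.07),
      LP = c(0.35, 0.15, 0.22, 0.12, 0.09, 0.07),
      CA = c(0.40, 0.18, 0.22, 0.10, 0.06, 0.04),
      LN = c(0.30, 0.10, 0.32, 0.16, 0.07, 0.05))
    colnames(mixtures) <- CELL_TYPES
  }
  if (is.null(colnames(mixtures))) colnames(mixtures) <- CELL_TYPES
  if (is.null(rownames(mixtures))) rownames(mixtures) <- TISSUE_TYPES
  if (any(abs(rowSums(mixtures) - 1) > 1e-8) || any(mixtures < 0)) {
    stop("spec error: each tissue's cell-type mixture must be non-negative ",
         "and sum to 1", call. = FALSE)
  }
  if (is.null(cna_segments)) {
    # gains and losses balance in total transcript mass within each clone,
    # so the planted aberrations do not shift the compositional baseline of
    # the relative expression track
    cna_segments <- data.frame(
      chrom = c("chr1", "chr5", "chr3", "chr6"),
      start = c(46, 46, 46, 46),
      end = c(95, 95, 95, 95),
      direction = c("gain", "loss", "gain", "loss"),
      copy_ratio = c(1.5, 0.5, 1.5, 0.5),
      carrier = c("clone", "clone", "hpvneg", "hpvneg"),
      carrier_fraction = 1.0,
      stringsAsFactors = FALSE)
  }
  if (nrow(cna_segments) > 0) {
    stopifnot(all(cna_segments$copy_ratio > 0),
              all(cna_segments$direction %in% c("gain", "loss")),
              all(cna_segments$carrier %in% c("clone", "hpvneg")),
              all(cna_segments$start <= cna_segments$end),
              all(cna_segments$end <= genes_per_chrom),
              all(cna_segments$carrier_fraction > 0 &
                    cna_segments$carrier_fraction <= 1))
    # segments must not overlap within a clone
    by_chrom <- split(cna_segments, cna_segments$chrom)
    for (s in by_chrom) {
      if (nrow(s) > 1) {
        s <- s[order(s$start), ]
        if (any(s$start[-1] <= s$end[-nrow(s)])) {
          stop("spec error: overlapping CNA segments on ", s$chrom[1],
               call. = FALSE)
        }
      }
    }
  }
  if (is.null(decoupled_genes)) {
    decoupled_genes <- sprintf("G%04d", 66:70)
    has_chr1_seg <- nrow(cna_segments) > 0 &&
      any(cna_segments$chrom == "chr1" & cna_segments$start <= 66 &
            cna_segments$end >= 70)
    if (!has_chr1_seg) decoupled_genes <- character(0)
  }
  spec <- list(n_patients = n_patients[TISSUE_TYPES],
               cells_per_sample = as.integer(cells_per_sample),
               genes_per_chrom = as.integer(genes_per_chrom),
               n_autosomes = as.integer(n_autosomes),
               n_x_genes = as.integer(n_x_genes),
               gene_spacing_bp = gene_spacing_bp,
               mixtures = mixtures,
               cna_segments = cna_segments,
               decoupled_genes = decoupled_genes,
               cis_fraction = cis_fraction,
               n_hpv_pos_ca = as.integer(n_hpv_pos_ca),
               type_factor_sdlog = type_factor_sdlog,
               marker_fold = marker_fold,
               n_markers_per_type = as.integer(n_markers_per_type),
               base_mean_meanlog = base_mean_meanlog,
               base_mean_sdlog = base_mean_sdlog,
               nb_size = nb_size,
               libsize_sdlog = libsize_sdlog,
               mixture_concentration = mixture_concentration,
               go_n_terms = as.integer(go_n_terms),
               lig_step_mult = lig_step_mult,
               epi_step_mult = epi_step_mult,
               rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed))
  class(spec) <- "cohort_spec"
  spec
}

# Gene world: ids, coordinates, biotypes, GO terms, base means and the
# planted functional roles. Consumes RNG; call under the spec seed.
.build_gene_world <- function(spec) {
  gpc <- spec$genes_per_chrom
  n_auto <- spec$n_autosomes * gpc
  auto_ids <- sprintf("G%04d", seq_len(n_auto))
  x_ids <- sprintf("GX%02d", seq_len(spec$n_x_genes))
  gene_id <- c(auto_ids, x_ids)
  chrom <- c(rep(paste0("chr", seq_len(spec$n_autosomes)), each = gpc),
             rep("chrX", spec$n_x_genes))
  pos_in_chrom <- c(rep(seq_len(gpc), spec$n_autosomes),
                    seq_len(spec$n_x_genes))
  start_bp <- (pos_in_chrom - 1) * spec$gene_spacing_bp + 1
  end_bp <- start_bp + 2000
  n_genes <- length(gene_id)

  biotype <- rep("protein_coding", n_genes)
  # immunoglobulin locus on chr2 (B/plasma-dominant, excluded from CNA work)
  ig_idx <- if (spec$n_autosomes >= 2) (2 * gpc - 9):(2 * gpc) else integer(0)
  biotype[ig_idx] <- "IG_C_gene"

  # scattered generic GO terms + one planted co-expression cluster on chr4
  go_terms <- replicate(n_genes, character(0), simplify = FALSE)
  for (t in seq_len(spec$go_n_terms)) {
    size <- sample(5:25, 1)
    members <- sample(n_genes, size)
    term <- sprintf("GO:T%03d", t)
    for (g in members) go_terms[[g]] <- c(go_terms[[g]], term)
  }
  coexp_idx <- if (spec$n_autosomes >= 4) (3 * gpc + 41):(3 * gpc + 47) else integer(0)
  coexp_bg <- if (length(coexp_idx) > 0) {
    sample(setdiff(seq_len(n_genes), coexp_idx), 5)
  } else integer(0)
  for (g in c(coexp_idx, coexp_bg)) {
    go_terms[[g]] <- c(go_terms[[g]], "GO:COEXP")
  }

  base_mean <- rlnorm(n_genes, spec$base_mean_meanlog, spec$base_mean_sdlog)

  # ligand-receptor world: 50 pairs, ligands on chr2, receptors on chr4
  lr <- NULL
  epi_step_idx <- integer(0)
  if (spec$n_autosomes >= 4 && gpc >= 100) {
    lig_idx <- gpc + 11:60
    rec_idx <- 3 * gpc + 51:100
    class <- c(rep("interdependent", 5), rep("declining", 15),
               rep("autocrine", 15), rep("no_receptor", 15))
    lr <- data.frame(ligand = gene_id[lig_idx], receptor = gene_id[rec_idx],
                     class = class, stringsAsFactors = FALSE)
    base_mean[lig_idx] <- 0.8
    base_mean[rec_idx] <- ifelse(class == "no_receptor", 0.02, 1.0)
    # stepwise epithelial genes are scattered across chromosomes, away
    # from the planted segments, so their tissue-dependent program cannot
    # aggregate into a dosage-like signal on any one chromosome
    epi_step_idx <- c(120, gpc + 70, 2 * gpc + 120, 3 * gpc + 25,
                      5 * gpc + 10)
    base_mean[epi_step_idx] <- 1.5
  }
  base_mean[ig_idx] <- 0.5

  # strong markers: one block of chrX genes per cell type
  marker_idx <- vector("list", length(CELL_TYPES))
  names(marker_idx) <- CELL_TYPES
  for (k in seq_along(CELL_TYPES)) {
    lo <- (k - 1) * spec$n_markers_per_type + 1
    hi <- min(k * spec$n_markers_per_type, spec$n_x_genes)
    marker_idx[[k]] <- if (lo <= hi) n_auto + (lo:hi) else integer(0)
  }

  type_factor <- matrix(rlnorm(n_genes * length(CELL_TYPES), 0,
                               spec$type_factor_sdlog),
                        n_genes, length(CELL_TYPES),
                        dimnames = list(gene_id, CELL_TYPES))

  gene_meta <- data.frame(gene_id = gene_id, chrom = chrom,
                          start_bp = start_bp, end_bp = end_bp,
                          biotype = biotype, stringsAsFactors = FALSE)
  gene_meta$go_terms <- go_terms

  list(gene_meta = gene_meta, base_mean = base_mean,
       type_factor = type_factor, lr = lr, ig_idx = ig_idx,
       coexp_idx = coexp_idx, epi_step_idx = epi_step_idx,
       marker_idx = marker_idx, n_genes = n_genes)
}

# per-(gene, cell type, tissue) mean at library-size factor 1, no CNA
.type_tissue_mu <- function(spec, world, type, tissue) {
  mu <- world$base_mean * world$type_factor[, type]
  ti <- match(tissue, TISSUE_TYPES)
  if (!is.null(world$lr)) {
    gid <- world$gene_meta$gene_id
    step_up <- spec$lig_step_mult[ti]
    for (cl in unique(world$lr$class)) {
      li <- match(world$lr$ligand[world$lr$class == cl], gid)
      if (type == "fibroblast") {
        fac <- switch(cl,
                      interdependent = step_up,
                      no_receptor = step_up,
                      autocrine = 8 * c(1, 2, 4, 4)[ti],
                      declining = c(4, 3.2, 2.56, 2.56)[ti])
      } else {
        fac <- if (cl == "autocrine") 8 else 0.02
      }
      mu[li] <- mu[li] * fac
    }
    if (type == "epithelial" && length(world$epi_step_idx) > 0) {
      mu[world$epi_step_idx] <- mu[world$epi_step_idx] * spec$epi_step_mult[ti]
    }
  }
  if (type == "epithelial" && length(world$coexp_idx) > 0) {
    mu[world$coexp_idx] <- mu[world$coexp_idx] * 3
  }
  for (k in seq_along(CELL_TYPES)) {
    mi <- world$marker_idx[[k]]
    if (length(mi) == 0) next
    # markers are near-exclusive: strongly up in their own type and
    # near-silent elsewhere, like canonical cell-type markers
    mu[mi] <- mu[mi] * if (CELL_TYPES[k] == type) spec$marker_fold else 0.01
  }
  if (length(world$ig_idx) > 0) {
    mu[world$ig_idx] <- mu[world$ig_idx] *
      if (type == "B/plasma") 40 else 0.05
  }
  mu
}

#' Generate a synthetic stepwise-progression cohort
#'
#' Draws the full single-cell cohort described by a [cohort_spec()] and
#' returns both the observable data (a counts-scale [cell_matrix()]) and the
#' generating ground truth. Deterministic under `spec$rng_seed`.
#'
#' @param spec a [cohort_spec()].
#' @return a list with elements `matrix` (a [cell_matrix()]) and `truth`, a
#'   list holding: `cells` (per-cell true type, clone and CIS flag),
#'   `copy_state` (genes x cells integer matrix, -1/0/+1), `segments`
#'   (planted segments with global gene bounds), `lr` (pair table with the
#'   `interdependent` flag), `stepwise` (true stepwise genes per cell type),
#'   `type_means` (empirical genes x cell-type mean counts, the cluster
#'   profiles for bulk simulation), and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$rng_seed)) set.seed(spec$rng_seed)
  world <- .build_gene_world(spec)
  gid <- world$gene_meta$gene_id

  # samples and patients; LN patients pair with the first CA patients
  samples <- do.call(rbind, lapply(TISSUE_TYPES, function(tt) {
    n <- spec$n_patients[[tt]]
    data.frame(tissue_type = tt, sample_id = sprintf("%s%02d", tt, seq_len(n)),
               stringsAsFactors = FALSE)
  }))
  pat <- character(nrow(samples))
  offs <- 0
  for (tt in c("NL", "LP", "CA")) {
    sel <- samples$tissue_type == tt
    pat[sel] <- sprintf("P%02d", offs + seq_len(sum(sel)))
    offs <- offs + sum(sel)
  }
  ca_pat <- pat[samples$tissue_type == "CA"]
  sel <- samples$tissue_type == "LN"
  pat[sel] <- ca_pat[seq_len(sum(sel))]
  samples$patient_id <- pat
  hpv <- setNames(rep("neg", length(unique(pat))), unique(pat))
  if (spec$n_hpv_pos_ca > 0) {
    hpv[utils::tail(ca_pat, spec$n_hpv_pos_ca)] <- "pos"
  }
  samples$hpv_status <- hpv[samples$patient_id]

  # planted segments in global gene indices
  segs <- spec$cna_segments
  seg_rows <- NULL
  if (nrow(segs) > 0) {
    chrom_offset <- setNames((seq_len(spec$n_autosomes) - 1) *
                               spec$genes_per_chrom,
                             paste0("chr", seq_len(spec$n_autosomes)))
    seg_rows <- data.frame(
      chrom = segs$chrom,
      start_idx = chrom_offset[segs$chrom] + segs$start,
      end_idx = chrom_offset[segs$chrom] + segs$end,
      direction = segs$direction, copy_ratio = segs$copy_ratio,
      carrier = segs$carrier, carrier_fraction = segs$carrier_fraction,
      stringsAsFactors = FALSE)
    seg_rows$start_gene <- gid[seg_rows$start_idx]
    seg_rows$end_gene <- gid[seg_rows$end_idx]
  }
  decoupled_idx <- match(spec$decoupled_genes, gid)

  mu_tt <- sapply(TISSUE_TYPES, function(tt) {
    sapply(CELL_TYPES, function(ct) .type_tissue_mu(spec, world, ct, tt))
  }, simplify = "array")  # genes x type x tissue

  n_cells_total <- nrow(samples) * spec$cells_per_sample
  counts <- matrix(0L, world$n_genes, n_cells_total)
  copy_state <- matrix(0L, world$n_genes, n_cells_total)
  cell_rows <- vector("list", nrow(samples))
  col <- 0
  for (s in seq_len(nrow(samples))) {
    tt <- samples$tissue_type[s]
    n <- spec$cells_per_sample
    mix <- spec$mixtures[tt, CELL_TYPES]
    jitter <- rgamma(length(mix), shape = mix * spec$mixture_concentration)
    if (sum(jitter) == 0) jitter <- mix
    types <- sample(CELL_TYPES, n, replace = TRUE,
                    prob = jitter / sum(jitter))
    is_cis <- types == "epithelial" & tt == "LP" &
      runif(n) < spec$cis_fraction
    malignant <- types == "epithelial" & tt %in% c("CA", "LN")
    in_clone <- malignant | is_cis
    hpvneg_mal <- malignant & samples$hpv_status[s] == "neg"
    libsize <- rlnorm(n, 0, spec$libsize_sdlog)
    for (k in seq_len(n)) {
      col <- col + 1
      mu <- mu_tt[, types[k], tt]
      if (!is.null(seg_rows)) {
        for (r in seq_len(nrow(seg_rows))) {
          eligible <- if (seg_rows$carrier[r] == "clone") in_clone[k] else
            hpvneg_mal[k]
          if (!eligible) next
          if (seg_rows$carrier_fraction[r] < 1 &&
              runif(1) >= seg_rows$carrier_fraction[r]) next
          idx <- seg_rows$start_idx[r]:seg_rows$end_idx[r]
          copy_state[idx, col] <-
            if (seg_rows$direction[r] == "gain") 1L else -1L
          expr_idx <- setdiff(idx, decoupled_idx)
          mu[expr_idx] <- mu[expr_idx] * seg_rows$copy_ratio[r]
        }
      }
      counts[, col] <- rnbinom(world$n_genes, mu = mu * libsize[k],
                               size = spec$nb_size)
    }
    cell_rows[[s]] <- data.frame(
      cell_id = sprintf("%s_c%03d", samples$sample_id[s], seq_len(n)),
      patient_id = samples$patient_id[s],
      sample_id = samples$sample_id[s],
      tissue_type = tt, hpv_status = samples$hpv_status[s],
      cell_type = types, cluster_label = types,
      stringsAsFactors = FALSE)
    cell_rows[[s]]$is_cis <- is_cis
    cell_rows[[s]]$is_malignant <- malignant
  }
  cells <- do.call(rbind, cell_rows)
  dimnames(counts) <- list(gid, cells$cell_id)
  dimnames(copy_state) <- list(gid, cells$cell_id)

  cell_meta <- cells[, c("cell_id", "patient_id", "sample_id", "tissue_type",
                         "hpv_status", "cell_type", "cluster_label")]
  cm <- cell_matrix(counts, cell_meta, world$gene_meta, scale = "counts")
  # construction order already matches (chrom, midpoint) sort order
  stopifnot(identical(cm$gene_meta$gene_id, gid))

  type_means <- sapply(CELL_TYPES, function(ct) {
    sel <- cells$cell_type == ct
    if (!any(sel)) return(rep(0, world$n_genes))
    rowMeans(counts[, sel, drop = FALSE])
  })
  rownames(type_means) <- gid

  stepwise <- NULL
  if (!is.null(world$lr)) {
    fib_step <- world$lr$ligand[world$lr$class %in%
                                  c("interdependent", "no_receptor",
                                    "autocrine")]
    stepwise <- rbind(
      data.frame(gene_id = fib_step, cell_type = "fibroblast",
                 direction = "up", stringsAsFactors = FALSE),
      data.frame(gene_id = gid[world$epi_step_idx], cell_type = "epithelial",
                 direction = "up", stringsAsFactors = FALSE))
    world$lr$interdependent <- world$lr$class == "interdependent"
  }

  truth <- list(cells = cells, copy_state = copy_state,
                segments = seg_rows, lr = world$lr, stepwise = stepwise,
                type_means = type_means,
                decoupled_genes = spec$decoupled_genes,
                coexp_genes = gid[world$coexp_idx],
                marker_genes = lapply(world$marker_idx,
                                      function(i) gid[i]),
                spec = spec)
  list(matrix = cm, truth = truth)
}

#' Draw malignant-dominant mixing proportions for bulk samples
#'
#' Dirichlet proportions whose means mirror bulk tumor composition
#' (malignant cells most abundant at roughly three quarters, fibroblasts
#' second at roughly a tenth).
#'
#' @param n_samples number of bulk samples.
#' @param alpha named Dirichlet concentration vector (names become cluster
#'   names).
#' @param rng_seed optional seed.
#' @return matrix n_samples x clusters, rows summing to 1.
#' @export
generate_proportions <- function(n_samples,
                                 alpha = c(epithelial = 16, fibroblast = 2,
                                           `NK/T` = 1.4, `B/plasma` = 0.8,
                                           macrophage = 0.6,
                                           endothelial = 0.4),
                                 rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  g <- matrix(rgamma(n_samples * length(alpha),
                     shape = rep(alpha, each = n_samples)),
              n_samples, length(alpha))
  p <- g / rowSums(g)
  colnames(p) <- names(alpha)
  rownames(p) <- sprintf("B%03d", seq_len(n_samples))
  p
}

#' Generate bulk expression from cluster profiles and known proportions
#'
#' Each bulk profile is the proportion-weighted sum of the cluster mean
#' profiles, perturbed by Gaussian noise on the log2 scale and floored at
#' zero.
#'
#' @param proportions n_samples x clusters matrix, rows summing to 1.
#' @param cluster_means genes x clusters matrix of linear-scale means.
#' @param noise_sd sd of the log2-scale Gaussian noise (0 for none).
#' @param rng_seed optional seed.
#' @return list with `bulk` (genes x samples) and `proportions` (the truth).
#' @export
generate_bulk <- function(proportions, cluster_means, noise_sd = 0.2,
                          rng_seed = NULL) {
  proportions <- as.matrix(proportions)
  if (any(proportions < 0)) {
    stop("spec error: proportions must be non-negative", call. = FALSE)
  }
  if (any(abs(rowSums(proportions) - 1) > 1e-6)) {
    stop("spec error: proportions must sum to 1 per sample", call. = FALSE)
  }
  stopifnot(ncol(proportions) == ncol(cluster_means))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  clean <- cluster_means %*% t(proportions)
  if (noise_sd > 0) {
    eps <- matrix(rnorm(length(clean), 0, noise_sd), nrow(clean))
    bulk <- pmax(2^(log2(clean + 1) + eps) - 1, 0)
  } else {
    bulk <- clean
  }
  rownames(bulk) <- rownames(cluster_means)
  colnames(bulk) <- rownames(proportions)
  list(bulk = bulk, proportions = proportions)
}

#' Generate proportion-linked survival records
#'
#' Exponential event times whose rate is the baseline multiplied by a
#' relative hazard determined by the focal cluster's proportion; by default
#' samples above the chosen percentile carry relative hazard
#' `hazard_ratio`. Censoring is independent exponential.
#'
#' @param proportions named numeric vector: the focal cluster's proportion
#'   per sample.
#' @param hazard_ratio relative hazard of the high group (1 = null).
#' @param percentile percentile (0-100) defining the high group.
#' @param baseline_rate baseline exponential event rate (> 0).
#' @param censor_rate exponential censoring rate (0 for no censoring).
#' @param hazard_link optional function mapping a proportion vector to
#'   relative hazards, overriding the percentile rule.
#' @param rng_seed optional seed.
#' @return data.frame of survival records (sample_id, time, event,
#'   endpoint, unit) plus the generating `group`.
#' @export
generate_survival <- function(proportions, hazard_ratio = 2,
                              percentile = 70, baseline_rate = 0.02,
                              censor_rate = 0.01, hazard_link = NULL,
                              rng_seed = NULL) {
  if (baseline_rate <= 0 || hazard_ratio <= 0) {
    stop("spec error: rates and hazard ratio must be positive",
         call. = FALSE)
  }
  if (censor_rate < 0) stop("spec error: censor_rate must be >= 0",
                            call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- length(proportions)
  if (is.null(hazard_link)) {
    cut <- quantile(proportions, percentile / 100, type = 7, names = FALSE)
    rel <- ifelse(proportions > cut, hazard_ratio, 1)
  } else {
    rel <- hazard_link(proportions)
  }
  t_event <- rexp(n, rate = baseline_rate * rel)
  t_cens <- if (censor_rate > 0) rexp(n, rate = censor_rate) else
    rep(Inf, n)
  ids <- names(proportions)
  if (is.null(ids)) ids <- sprintf("B%03d", seq_len(n))
  data.frame(sample_id = ids,
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             endpoint = "OS", unit = "months",
             group = ifelse(rel > 1, "high", "low"),
             stringsAsFactors = FALSE)
}
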