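#' @useDynLib hnsccStepwise, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as is
#' @importFrom stats cor cor.test phyper quantile rbinom rexp rgamma rlnorm
#'   rmultinom rnbinom rnorm runif sd setNames wilcox.test pt p.adjust
#'   na.omit pnorm pchisq var
#' @importFrom utils combn read.delim write.table head
"_PACKAGE"

TISSUE_TYPES <- c("NL", "LP", "CA", "LN")
HPV_LEVELS <- c("pos", "neg")
IMMUNE_CELL_TYPES <- c("NK/T", "B/plasma", "macrophage", "dendritic", "mast")

#' Order chromosomes canonically
#'
#' Maps chromosome names (with or without a "chr" prefix) to an integer rank:
#' autosomes 1-22 in numeric order, then X and Y. Mitochondrial and unplaced
#' contigs map to `NA` and are dropped when a [cell_matrix()] is built.
#'
#' @param chrom character vector of chromosome names.
#' @return integer rank vector, `NA` for contigs outside 1-22/X/Y.
#' @export
chrom_rank <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  r <- suppressWarnings(as.integer(x))
  r[x == "X"] <- 23L
  r[x == "Y"] <- 24L
  r[!(r %in% 1:24)] <- NA_integer_
  r
}

#' Single-cell expression container
#'
#' The universal carrier for every single-cell stage: a genes-by-cells
#' expression matrix together with per-cell and per-gene annotation. Genes are
#' stored sorted by (chromosome, midpoint) so that chromosomal smoothing and
#' segmentation operate on a single unambiguous ordering. Coordinates are
#' 1-based inclusive; the ordering position of a gene is its midpoint.
#' Mitochondrial and unplaced contigs are dropped at construction (with a
#' message) because the copy-number track is defined on ordered nuclear
#' chromosomes.
#'
#' @param values numeric matrix or sparse `Matrix` (genes x cells) of
#'   non-negative expression. Row and column names, when present, must agree
#'   with `gene_meta$gene_id` and `cell_meta$cell_id`.
#' @param cell_meta data.frame with columns `cell_id`, `patient_id`,
#'   `tissue_type` (one of NL/LP/CA/LN), `hpv_status` (pos/neg/NA),
#'   `cell_type`, and optionally `cluster_label`.
#' @param gene_meta data.frame with columns `gene_id`, `chrom`, `start_bp`,
#'   `end_bp`, `biotype`, and optionally `go_terms` (a list column of
#'   character term ids, or a `;`-separated string column).
#' @param scale `"counts"` for raw counts or `"lognorm"` for log-normalized
#'   values (see [normalize_cells()]).
#' @return an object of class `cell_matrix`: a list with elements `values`
#'   (dgCMatrix), `cell_meta`, `gene_meta`, `scale`.
#' @export
cell_matrix <- function(values, cell_meta, gene_meta,
                        scale = c("counts", "lognorm")) {
  scale <- match.arg(scale)
  values <- methods::as(methods::as(methods::as(
    Matrix::Matrix(values, sparse = TRUE), "dMatrix"), "generalMatrix"),
    "CsparseMatrix")

  req_cell <- c("cell_id", "patient_id", "tissue_type", "hpv_status",
                "cell_type")
  missing_c <- setdiff(req_cell, names(cell_meta))
  if (length(missing_c) > 0) {
    stop("cell_meta is missing required column(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  req_gene <- c("gene_id", "chrom", "start_bp", "end_bp", "biotype")
  missing_g <- setdiff(req_gene, names(gene_meta))
  if (length(missing_g) > 0) {
    stop("gene_meta is missing required column(s): ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  }
  if (nrow(cell_meta) != ncol(values)) {
    stop("shape error: ", ncol(values), " cells in matrix but ",
         nrow(cell_meta), " rows of cell_meta", call. = FALSE)
  }
  if (nrow(gene_meta) != nrow(values)) {
    stop("shape error: ", nrow(values), " genes in matrix but ",
         nrow(gene_meta), " rows of gene_meta", call. = FALSE)
  }
  bad_tissue <- setdiff(unique(as.character(cell_meta$tissue_type)),
                        TISSUE_TYPES)
  if (length(bad_tissue) > 0 || anyNA(cell_meta$tissue_type)) {
    stop("schema error: unknown tissue_type value(s): ",
         paste(c(bad_tissue, if (anyNA(cell_meta$tissue_type)) "NA"),
               collapse = ", "), call. = FALSE)
  }
  bad_hpv <- setdiff(unique(as.character(cell_meta$hpv_status)),
                     c(HPV_LEVELS, NA))
  if (length(stats::na.omit(bad_hpv)) > 0) {
    stop("schema error: unknown hpv_status value(s): ",
         paste(bad_hpv, collapse = ", "), call. = FALSE)
  }
  if (min(values@x, 0) < 0) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  if (any(gene_meta$start_bp > gene_meta$end_bp)) {
    stop("gene coordinates must satisfy start_bp <= end_bp", call. = FALSE)
  }
  if (!is.null(rownames(values)) &&
      !identical(rownames(values), as.character(gene_meta$gene_id))) {
    stop("rownames(values) disagree with gene_meta$gene_id", call. = FALSE)
  }
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), as.character(cell_meta$cell_id))) {
    stop("colnames(values) disagree with cell_meta$cell_id", call. = FALSE)
  }

  if (!"cluster_label" %in% names(cell_meta)) cell_meta$cluster_label <- NA
  if (!"go_terms" %in% names(gene_meta)) {
    gene_meta$go_terms <- replicate(nrow(gene_meta), character(0),
                                    simplify = FALSE)
  } else if (is.character(gene_meta$go_terms)) {
    gene_meta$go_terms <- lapply(strsplit(gene_meta$go_terms, ";",
                                          fixed = TRUE),
                                 function(x) x[nzchar(x)])
  }

  rank <- chrom_rank(gene_meta$chrom)
  n_drop <- sum(is.na(rank))
  if (n_drop > 0) {
    message("dropping ", n_drop,
            " gene(s) on mitochondrial/unplaced contigs")
    keep <- !is.na(rank)
    gene_meta <- gene_meta[keep, , drop = FALSE]
    values <- values[keep, , drop = FALSE]
    rank <- rank[keep]
  }
  if (nrow(gene_meta) == 0) stop("no genes left after contig filtering",
                                 call. = FALSE)
  mid <- (gene_meta$start_bp + gene_meta$end_bp) / 2
  ord <- order(rank, mid, gene_meta$gene_id)
  gene_meta <- gene_meta[ord, , drop = FALSE]
  values <- values[ord, , drop = FALSE]
  rownames(gene_meta) <- NULL
  rownames(cell_meta) <- NULL
  dimnames(values) <- list(as.character(gene_meta$gene_id),
                           as.character(cell_meta$cell_id))

  structure(list(values = values, cell_meta = cell_meta,
                 gene_meta = gene_meta, scale = scale),
            class = "cell_matrix")
}

#' @export
#' @method print cell_matrix
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d genes x %d cells (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  tt <- table(x$cell_meta$tissue_type)
  cat("tissues:", paste(sprintf("%s=%d", names(tt), tt), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$values)

#' Subset a cell_matrix by genes and/or cells
#'
#' @param x a [cell_matrix()].
#' @param genes,cells logical/integer/character index vectors.
#' @return a `cell_matrix` (gene sort order is preserved by construction).
#' @export
subset_cells <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "cell_matrix"))
  gi <- if (is.null(genes)) seq_len(nrow(x$values)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(x$values)) else cells
  if (is.character(gi)) gi <- match(gi, x$gene_meta$gene_id)
  if (is.character(ci)) ci <- match(ci, x$cell_meta$cell_id)
  out <- x
  out$values <- x$values[gi, ci, drop = FALSE]
  out$gene_meta <- x$gene_meta[gi, , drop = FALSE]
  out$cell_meta <- x$cell_meta[ci, , drop = FALSE]
  rownames(out$gene_meta) <- NULL
  rownames(out$cell_meta) <- NULL
  out
}

#' Log-normalize a count matrix
#'
#' Per-cell scaling to a fixed total (default 10,000) followed by
#' `log2(x + 1)`. This is the stated normalization convention for all
#' expression-ratio work in the package.
#'
#' @param x a counts-scale [cell_matrix()].
#' @param target_sum per-cell total after scaling.
#' @return a `cell_matrix` with `scale = "lognorm"`.
#' @export
normalize_cells <- function(x, target_sum = 1e4) {
  stopifnot(inherits(x, "cell_matrix"))
  if (x$scale == "lognorm") return(x)
  totals <- Matrix::colSums(x$values)
  totals[totals == 0] <- 1
  v <- x$values %*% Matrix::Diagonal(x = target_sum / totals)
  v@x <- log2(v@x + 1)
  dimnames(v) <- dimnames(x$values)
  x$values <- methods::as(v, "CsparseMatrix")
  x$scale <- "lognorm"
  x
}

#' Cells matching metadata criteria
#'
#' Convenience selector returning cell ids by tissue and/or cell type.
#'
#' @param x a [cell_matrix()].
#' @param tissue,cell_type,patient optional filters (vectors allowed).
#' @return character vector of cell ids.
#' @export
cells_where <- function(x, tissue = NULL, cell_type = NULL, patient = NULL) {
  m <- x$cell_meta
  keep <- rep(TRUE, nrow(m))
  if (!is.null(tissue)) keep <- keep & m$tissue_type %in% tissue
  if (!is.null(cell_type)) keep <- keep & m$cell_type %in% cell_type
  if (!is.null(patient)) keep <- keep & m$patient_id %in% patient
  as.character(m$cell_id[keep])
}

#' Malignant cells of a cohort
#'
#' Epithelial cells in primary carcinoma (CA) and nodal metastasis (LN)
#' tissue are taken as malignant.
#'
#' @param x a [cell_matrix()].
#' @return character vector of cell ids.
#' @export
malignant_cells <- function(x) {
  cells_where(x, tissue = c("CA", "LN"), cell_type = "epithelial")
}
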