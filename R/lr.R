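#' Fraction of cells expressing a gene
#'
#' Detection fraction: the share of the given cells with expression above
#' zero (count scale; log-normalization preserves positivity, so either
#' scale gives the same answer).
#'
#' @param cm a [cell_matrix()].
#' @param gene gene id.
#' @param cells non-empty cell id vector.
#' @return fraction in \[0, 1\].
#' @export
expressed_fraction <- function(cm, gene, cells) {
  stopifnot(length(cells) > 0)
  gi <- match(gene, rownames(cm$values))
  if (is.na(gi)) stop("gene '", gene, "' not in matrix", call. = FALSE)
  mean(cm$values[gi, cells] > 0)
}

#' Interdependent ligand-receptor pairs between two populations
#'
#' A pair is interdependent when (1) the ligand's detection fraction in the
#' source population (fibroblasts) increases monotonically across the
#' available tissue order with an overall increase of at least
#' `lr_min_increase` and a final fraction of at least `expr_min`; (2) the
#' receptor's detection fraction in the target population (malignant cells)
#' is at least `expr_min`; and (3) the ligand's detection fraction in the
#' target is at most `absent_max` — the target expresses the receptor but
#' depends on the source for the ligand (obligate paracrine signaling).
#'
#' @param cm a [cell_matrix()].
#' @param lr_list data.frame with `ligand_gene`, `receptor_gene` columns.
#' @param source_cells named list of source-population cell ids per tissue,
#'   in progression order (at least two of NL, LP, CA).
#' @param target_cells target-population cell ids.
#' @param config a [pipeline_config()] supplying `expr_min`, `absent_max`,
#'   `lr_min_increase`.
#' @return data.frame, one row per scored pair, sorted by the final source
#'   ligand fraction (descending): ligand, receptor, `frac_src_<tissue>`
#'   columns, frac_ligand_target, frac_receptor_target, stepwise_ligand,
#'   interdependent. Pairs with genes absent from the matrix are skipped
#'   with one summary warning.
#' @export
find_interdependent_pairs <- function(cm, lr_list, source_cells,
                                      target_cells,
                                      config = pipeline_config()) {
  stopifnot(length(source_cells) >= 2, !is.null(names(source_cells)))
  tissues <- names(source_cells)
  genes <- rownames(cm$values)
  present <- lr_list$ligand_gene %in% genes &
    lr_list$receptor_gene %in% genes
  if (any(!present)) {
    warning(sum(!present), " ligand-receptor pair(s) skipped: gene(s) ",
            "absent from the matrix")
  }
  lr <- lr_list[present, , drop = FALSE]
  if (nrow(lr) == 0) return(data.frame())

  vals <- cm$values
  det_frac <- function(gene_v, cells) {
    gi <- match(gene_v, genes)
    Matrix::rowMeans(vals[gi, cells, drop = FALSE] > 0)
  }
  src <- sapply(tissues, function(tt) det_frac(lr$ligand_gene,
                                               source_cells[[tt]]))
  if (nrow(lr) == 1) src <- matrix(src, nrow = 1,
                                   dimnames = list(NULL, tissues))
  lig_target <- det_frac(lr$ligand_gene, target_cells)
  rec_target <- det_frac(lr$receptor_gene, target_cells)

  monotone <- apply(src, 1, function(f) all(diff(f) >= 0))
  increase <- src[, length(tissues)] - src[, 1] >= config$lr_min_increase
  stepwise <- monotone & increase
  interdependent <- stepwise &
    src[, length(tissues)] >= config$expr_min &
    rec_target >= config$expr_min &
    lig_target <= config$absent_max

  out <- data.frame(ligand = lr$ligand_gene, receptor = lr$receptor_gene,
                    stringsAsFactors = FALSE)
  for (tt in tissues) out[[paste0("frac_src_", tt)]] <- src[, tt]
  out$frac_ligand_target <- as.numeric(lig_target)
  out$frac_receptor_target <- as.numeric(rec_target)
  out$stepwise_ligand <- as.logical(stepwise)
  out$interdependent <- as.logical(interdependent)
  out <- out[order(-out[[paste0("frac_src_", tissues[length(tissues)])]]), ]
  rownames(out) <- NULL
  out
}

#' Per-patient ligand-receptor coupling
#'
#' For each patient with cells in both populations, the mean log-normalized
#' ligand expression in the source population and mean receptor expression
#' in the target population; Pearson correlation across patients with a
#' two-sided t-based p-value. A negative control is also computed — the
#' coupling of the ligand with the receptor both measured within the source
#' population — to show that the association is not autocrine.
#'
#' @param cm a [cell_matrix()].
#' @param ligand,receptor gene ids.
#' @param source_cells,target_cells cell id vectors of the two populations.
#' @param min_patients minimum qualifying patients (default 5).
#' @return list with `r`, `p`, `n_patients`, `table` (per-patient means),
#'   `control_r`, `control_p`, and `reason` (`NA` unless the correlation is
#'   undefined).
#' @export
patient_coupling <- function(cm, ligand, receptor, source_cells,
                             target_cells, min_patients = 5) {
  X <- as.matrix(normalize_cells(cm)$values[c(ligand, receptor), ,
                                            drop = FALSE])
  meta <- cm$cell_meta
  pat_of <- setNames(as.character(meta$patient_id),
                     as.character(meta$cell_id))
  src_pat <- pat_of[source_cells]
  tgt_pat <- pat_of[target_cells]
  patients <- intersect(unique(src_pat), unique(tgt_pat))
  if (length(patients) < min_patients) {
    stop("need >= ", min_patients, " patients with both populations; got ",
         length(patients), call. = FALSE)
  }
  tab <- data.frame(
    patient_id = patients,
    ligand_source = vapply(patients, function(p) {
      mean(X[ligand, source_cells[src_pat == p]])
    }, 0),
    receptor_target = vapply(patients, function(p) {
      mean(X[receptor, target_cells[tgt_pat == p]])
    }, 0),
    receptor_source = vapply(patients, function(p) {
      mean(X[receptor, source_cells[src_pat == p]])
    }, 0),
    stringsAsFactors = FALSE, row.names = NULL)

  couple <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) {
      return(list(r = NA_real_, p = NA_real_,
                  reason = "zero variance across patients"))
    }
    ct <- cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, reason = NA_character_)
  }
  main <- couple(tab$ligand_source, tab$receptor_target)
  ctrl <- couple(tab$ligand_source, tab$receptor_source)
  list(r = main$r, p = main$p, n_patients = length(patients), table = tab,
       control_r = ctrl$r, control_p = ctrl$p, reason = main$reason)
}
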