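# build a cell_matrix with exact detection patterns: `frac` gives, per gene
# and cell group, the fraction of cells with a positive count
lr_world <- function(groups, frac_table) {
  n_cells <- sum(lengths(groups))
  n_genes <- nrow(frac_table)
  vals <- matrix(0, n_genes, n_cells)
  col0 <- 0
  for (g in seq_along(groups)) {
    n <- lengths(groups)[g]
    for (r in seq_len(n_genes)) {
      k <- round(frac_table[r, g] * n)
      if (k > 0) vals[r, col0 + seq_len(k)] <- 5
    }
    col0 <- col0 + n
  }
  tissues <- rep(names(groups), lengths(groups))
  tissues[tissues == "MAL"] <- "CA"
  cm <- tiny_matrix(vals, tissue = tissues)
  cm
}

test_that("expressed_fraction counts positive cells", {
  cm <- tiny_matrix(matrix(c(0, 0, 5, 0, 2, 7), 3, 2))
  cells <- colnames(cm$values)
  expect_equal(expressed_fraction(cm, "g01", cells), 0)
  expect_equal(expressed_fraction(cm, "g03", cells), 1)
  big <- tiny_matrix(matrix(c(rep(1, 3), rep(0, 7)), 1, 10),
                     tissue = rep("CA", 10))
  expect_equal(expressed_fraction(big, "g01", colnames(big$values)), 0.3)
  expect_error(expressed_fraction(cm, "nope", cells), "not in matrix")
})

test_that("find_interdependent_pairs applies all three conditions", {
  # genes: L1 planted interdependent ligand, L2 autocrine ligand,
  # L3 declining ligand, R1/R2/R3 receptors
  frac <- rbind(
    L1 = c(NL = 0.10, LP = 0.40, CA = 0.70, MAL = 0.01),
    L2 = c(0.50, 0.70, 0.90, 0.90),
    L3 = c(0.60, 0.50, 0.40, 0.01),
    R1 = c(0.10, 0.10, 0.10, 0.60),
    R2 = c(0.10, 0.10, 0.10, 0.60),
    R3 = c(0.10, 0.10, 0.10, 0.60))
  groups <- list(NL = 1:100, LP = 1:100, CA = 1:100, MAL = 1:100)
  cm <- lr_world(groups, frac)
  cells <- colnames(cm$values)
  src <- list(NL = cells[1:100], LP = cells[101:200], CA = cells[201:300])
  target <- cells[301:400]
  cm$gene_meta$gene_id <- rownames(cm$values) <-
    c("L1", "L2", "L3", "R1", "R2", "R3")
  dimnames(cm$values) <- list(cm$gene_meta$gene_id, cm$cell_meta$cell_id)

  lr_list <- data.frame(ligand_gene = c("L1", "L2", "L3", "MISSING"),
                        receptor_gene = c("R1", "R2", "R3", "R1"),
                        stringsAsFactors = FALSE)
  expect_warning(res <- find_interdependent_pairs(cm, lr_list, src, target),
                 "skipped")
  expect_equal(nrow(res), 3)
  expect_true(res$interdependent[res$ligand == "L1"])
  expect_false(res$interdependent[res$ligand == "L2"])  # expressed in target
  expect_false(res$interdependent[res$ligand == "L3"])  # not stepwise
  expect_true(res$stepwise_ligand[res$ligand == "L1"])
  expect_false(res$stepwise_ligand[res$ligand == "L3"])
  # sorted by final source fraction, descending
  expect_equal(res$ligand, c("L2", "L1", "L3"))
})

test_that("interdependence thresholds are monotone in the stated directions", {
  sim <- small_sim()
  cm <- sim$matrix
  src <- lapply(c("NL", "LP", "CA"), function(tt) {
    cells_where(cm, tissue = tt, cell_type = "fibroblast")
  })
  names(src) <- c("NL", "LP", "CA")
  target <- malignant_cells(cm)
  lr_list <- data.frame(ligand_gene = sim$truth$lr$ligand,
                        receptor_gene = sim$truth$lr$receptor)
  n_dep <- function(expr_min, absent_max) {
    cfg <- synthetic_config(expr_min = expr_min, absent_max = absent_max)
    sum(find_interdependent_pairs(cm, lr_list, src, target, cfg)$interdependent)
  }
  # raising absent_max never shrinks the set
  counts <- vapply(c(0.01, 0.05, 0.2, 0.9), function(a) n_dep(0.25, a), 0)
  expect_true(all(diff(counts) >= 0))
  # raising expr_min never grows it
  counts2 <- vapply(c(0.1, 0.25, 0.6, 0.95), function(e) n_dep(e, 0.05), 0)
  expect_true(all(diff(counts2) <= 0))
})

test_that("the verdict ignores per-cell scaling of counts", {
  sim <- small_sim()
  cm <- sim$matrix
  src <- lapply(c("NL", "LP", "CA"), function(tt) {
    cells_where(cm, tissue = tt, cell_type = "fibroblast")
  })
  names(src) <- c("NL", "LP", "CA")
  target <- malignant_cells(cm)
  lr_list <- data.frame(ligand_gene = sim$truth$lr$ligand[1:10],
                        receptor_gene = sim$truth$lr$receptor[1:10])
  r1 <- find_interdependent_pairs(cm, lr_list, src, target,
                                  synthetic_config())
  cm2 <- cm
  scale <- Matrix::Diagonal(x = runif(ncol(cm2$values), 0.5, 3))
  cm2$values <- methods::as(cm2$values %*% scale, "CsparseMatrix")
  dimnames(cm2$values) <- dimnames(cm$values)
  r2 <- find_interdependent_pairs(cm2, lr_list, src, target,
                                  synthetic_config())
  expect_equal(r1$interdependent, r2$interdependent)
  expect_equal(r1$ligand, r2$ligand)
})

test_that("patient_coupling correlates per-patient means with controls", {
  sim <- small_sim()
  cm <- sim$matrix
  fib <- cells_where(cm, tissue = c("CA", "LN"), cell_type = "fibroblast")
  mal <- malignant_cells(cm)
  pair <- sim$truth$lr[sim$truth$lr$interdependent, ][1, ]
  res <- patient_coupling(cm, pair$ligand, pair$receptor, fib, mal)
  expect_true(res$n_patients >= 5)
  expect_true(is.finite(res$r))
  expect_equal(nrow(res$table), res$n_patients)

  # too few patients
  one_pat <- cm$cell_meta$patient_id == cm$cell_meta$patient_id[
    match(mal[1], cm$cell_meta$cell_id)]
  expect_error(patient_coupling(cm, pair$ligand, pair$receptor,
                                intersect(fib, cm$cell_meta$cell_id[one_pat]),
                                intersect(mal, cm$cell_meta$cell_id[one_pat])),
               "patients")
})

test_that("patient_coupling reports NA with a reason on zero variance", {
  vals <- matrix(5, 2, 40)
  cm <- tiny_matrix(vals, tissue = rep("CA", 40))
  cm$cell_meta$patient_id <- rep(sprintf("p%d", 1:8), 5)
  cells <- colnames(cm$values)
  res <- patient_coupling(cm, "g01", "g02", cells[1:20], cells[21:40])
  expect_true(is.na(res$r))
  expect_match(res$reason, "zero variance")
})

test_that("a planted linear coupling is recovered", {
  # per-patient ligand mean rises linearly; receptor follows exactly
  set.seed(41)
  n_pat <- 12
  cells_per <- 20
  lig <- rep(seq(1, 12), each = cells_per)
  vals <- rbind(lig + rnorm(n_pat * cells_per, 0, 1e-8),
                lig + rnorm(n_pat * cells_per, 0, 1e-8))
  vals <- pmax(vals, 0)
  cm <- tiny_matrix(vals, tissue = rep("CA", n_pat * cells_per))
  cm$cell_meta$patient_id <- rep(sprintf("p%02d", 1:n_pat),
                                 each = cells_per)
  cm$scale <- "lognorm"
  cells <- colnames(cm$values)
  res <- patient_coupling(cm, "g01", "g02", cells, cells)
  expect_gt(res$r, 0.999)
  expect_lt(res$p, 1e-10)
})
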