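test_that("cell_matrix round-trips through dense TSV and MTX", {
  cm <- tiny_matrix(matrix(c(1, 0, 3, 2, 5, 0), 3, 2))
  dir <- withr::local_tempdir()

  # dense TSV
  tab <- data.frame(gene_id = rownames(cm$values),
                    as.matrix(cm$values), check.names = FALSE)
  write.table(tab, file.path(dir, "m.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_table(cm$cell_meta, file.path(dir, "cells.tsv"))
  write_table(cm$gene_meta, file.path(dir, "genes.tsv"))
  back <- read_cell_matrix(file.path(dir, "m.tsv"),
                           file.path(dir, "cells.tsv"),
                           file.path(dir, "genes.tsv"))
  expect_equal(as.matrix(back$values), as.matrix(cm$values))
  expect_equal(back$cell_meta$tissue_type, cm$cell_meta$tissue_type)

  # MTX (with an explicit stored zero) equals the dense equivalent
  m <- cm$values
  mtx <- methods::as(m, "TsparseMatrix")
  Matrix::writeMM(mtx, file.path(dir, "m.mtx"))
  back_mtx <- read_cell_matrix(file.path(dir, "m.mtx"),
                               file.path(dir, "cells.tsv"),
                               file.path(dir, "genes.tsv"))
  expect_equal(as.matrix(back_mtx$values), as.matrix(back$values))
})

test_that("cell_matrix validates schema and shapes", {
  vals <- matrix(1:6, 3, 2)
  cm <- tiny_matrix(vals)
  bad_meta <- cm$cell_meta
  bad_meta$tissue_type[1] <- "XX"
  expect_error(cell_matrix(unname(as.matrix(cm$values)), bad_meta,
                           cm$gene_meta),
               "tissue_type")
  expect_error(cell_matrix(unname(as.matrix(cm$values)),
                           cm$cell_meta[, -1], cm$gene_meta),
               "missing required column")
  expect_error(cell_matrix(matrix(1:9, 3, 3), cm$cell_meta, cm$gene_meta),
               "shape error")
  gm <- cm$gene_meta
  gm$start_bp[1] <- gm$end_bp[1] + 10
  expect_error(cell_matrix(unname(as.matrix(cm$values)), cm$cell_meta, gm),
               "start_bp <= end_bp")
})

test_that("genes are sorted by chromosome then midpoint; MT dropped", {
  gene_meta <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    chrom = c("chr2", "chr1", "chrM", "chr1", "chrX"),
    start_bp = c(100, 500, 1, 100, 50),
    end_bp = c(200, 600, 10, 200, 80),
    biotype = "protein_coding", stringsAsFactors = FALSE)
  cell_meta <- data.frame(cell_id = "c1", patient_id = "p1",
                          tissue_type = "NL", hpv_status = "neg",
                          cell_type = "epithelial")
  vals <- matrix(1:5, 5, 1, dimnames = list(gene_meta$gene_id, "c1"))
  expect_message(cm <- cell_matrix(vals, cell_meta, gene_meta),
                 "mitochondrial/unplaced")
  expect_equal(cm$gene_meta$gene_id, c("d", "b", "a", "e"))
  # deterministic pure function of gene_meta: same input, same order
  cm2 <- suppressMessages(cell_matrix(vals, cell_meta, gene_meta))
  expect_identical(cm$gene_meta, cm2$gene_meta)
})

test_that("write_table round-trips values to better than 5e-7", {
  dir <- withr::local_tempdir()
  set.seed(1)
  tab <- data.frame(sample_id = sprintf("s%d", 1:20),
                    p1 = runif(20), p2 = runif(20))
  tab$p2 <- 1 - tab$p1  # rows sum to 1 like a proportion table
  path <- file.path(dir, "props.tsv")
  write_table(tab, path)
  back <- read_table(path)
  expect_true(all(abs(back$p1 - tab$p1) < 5e-7))
  expect_true(all(abs(back$p1 + back$p2 - 1) < 5e-7))

  # empty table -> header-only file
  write_table(tab[0, ], file.path(dir, "empty.tsv"))
  expect_equal(nrow(read_table(file.path(dir, "empty.tsv"))), 0)
  expect_equal(names(read_table(file.path(dir, "empty.tsv"))), names(tab))

  expect_error(write_table(tab, file.path(dir, "no/such/dir/x.tsv")),
               "I/O error")
})

test_that("normalize_cells applies the stated convention", {
  cm <- tiny_matrix(matrix(c(10, 30, 60, 5, 5, 0), 3, 2))
  nm <- normalize_cells(cm, target_sum = 100)
  expect_equal(nm$scale, "lognorm")
  expect_equal(as.numeric(nm$values[, 1]),
               log2(c(10, 30, 60) + 1))
  # idempotent
  expect_identical(normalize_cells(nm)$values, nm$values)
})

test_that("pipeline_config validates and reads from JSON", {
  cfg <- pipeline_config()
  expect_equal(cfg$cna_fold_cutoff, 0.1)
  expect_equal(cfg$recurrence_freq, 0.05)
  expect_equal(cfg$burden_undetermined, 200)
  expect_error(pipeline_config(high_group_percentile = 100), "percentile")
  expect_error(pipeline_config(n_permutations = 50), "100")
  expect_error(pipeline_config(marker_fold = -1), "positive")

  dir <- withr::local_tempdir()
  jsonlite::write_json(list(cna_fold_cutoff = 0.2, rng_seed = 42),
                       file.path(dir, "cfg.json"), auto_unbox = TRUE)
  cfg2 <- read_config(file.path(dir, "cfg.json"))
  expect_equal(cfg2$cna_fold_cutoff, 0.2)
  expect_equal(cfg2$rng_seed, 42L)
})

test_that("survival and ligand-receptor readers validate input", {
  dir <- withr::local_tempdir()
  write_table(data.frame(sample_id = c("a", "b"), time = c(10, 20),
                         event = c(1, 0)),
              file.path(dir, "surv.tsv"))
  s <- read_survival(file.path(dir, "surv.tsv"))
  expect_equal(s$event, c(1, 0))
  write_table(data.frame(sample_id = "a", time = -1, event = 1),
              file.path(dir, "bad.tsv"))
  expect_error(read_survival(file.path(dir, "bad.tsv")), ">= 0")

  lr <- read_lr_list(system.file("extdata", "lr_pairs.tsv",
                                 package = "hnsccStepwise"))
  expect_true(all(c("ligand_gene", "receptor_gene") %in% names(lr)))
  expect_true(all(c("COL1A1", "THBS1", "TNC", "LAMA4") %in% lr$ligand_gene))
})
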