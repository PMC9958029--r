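
test_that("permuted_t_test enumerates exactly for small groups", {
  res <- permuted_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$method, "exact")
  expect_equal(res$n_permutations, 20L)
  # only the two extreme partitions reach |mean difference| = 3
  expect_equal(res$perm_p, 2 / 20)

  same <- permuted_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$perm_p, 1)

  degenerate <- permuted_t_test(c(2, 2), c(2, 2))
  expect_equal(degenerate$t_stat, 0)
  expect_equal(degenerate$perm_p, 1)

  expect_error(permuted_t_test(1, c(1, 2)), "at least 2")
})

test_that("permutation p is invariant under group-label swap", {
  set.seed(5)
  for (i in 1:5) {
    a <- rnorm(8)
    b <- rnorm(6, 0.5)
    pab <- permuted_t_test(a, b, 500, rng_seed = 10 + i)
    pba <- permuted_t_test(b, a, 500, rng_seed = 10 + i)
    expect_equal(pab$perm_p, pba$perm_p)
    expect_equal(pab$t_stat, -pba$t_stat)
  }
})

test_that("sampled p approaches the exact enumeration p", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(5)
    y <- rnorm(5)
    exact <- permuted_t_test(x, y, n_permutations = 1000)$perm_p
    sampled <- permuted_t_test(x, y, n_permutations = 200,
                               rng_seed = 100 + i)$perm_p
    se <- sqrt(exact * (1 - exact) / 200)
    expect_lt(abs(sampled - exact), 4 * se + 1 / 201)
  }
})

test_that("wilcoxon markers match the exact rank-sum oracle at small n", {
  set.seed(11)
  for (i in 1:8) {
    x <- sample(seq(0.1, 50, by = 0.7), 7)
    y <- sample(seq(0.05, 30, by = 0.45), 9)
    ours <- suppressWarnings(wilcox.test(x, y))$p.value
    expect_equal(ours, oracle_ranksum_p(x, y), tolerance = 1e-9)
  }
})

test_that("wilcoxon_markers recovers planted markers with no false calls", {
  set.seed(21)
  n_genes <- 200
  n_per <- 100
  base <- rlnorm(n_genes, log(2), 0.4)
  mu <- cbind(matrix(base, n_genes, n_per),
              matrix(base, n_genes, n_per))
  mu[1:50, (n_per + 1):(2 * n_per)] <- mu[1:50, (n_per + 1):(2 * n_per)] * 4
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 2), n_genes)
  cm <- tiny_matrix(counts, tissue = rep("CA", 2 * n_per))
  labels <- rep(c("rest", "planted"), each = n_per)
  markers <- wilcoxon_markers(cm, labels)
  planted_found <- markers$gene_id[markers$cluster == "planted"]
  expect_gte(sum(planted_found %in% sprintf("g%02d", 1:50)), 45)
  expect_length(setdiff(planted_found, rownames(cm$values)[1:50]), 0)

  # a constant gene is never a marker
  counts2 <- counts
  counts2[60, ] <- 5
  cm2 <- tiny_matrix(counts2, tissue = rep("CA", 2 * n_per))
  markers2 <- wilcoxon_markers(cm2, labels)
  expect_false(rownames(cm2$values)[60] %in% markers2$gene_id)

  expect_error(wilcoxon_markers(cm, rep("one", 2 * n_per)), ">= 2")
})

test_that("marker calls are invariant to cell and gene order", {
  set.seed(31)
  n <- 60
  counts <- matrix(rnbinom(50 * n, mu = 3, size = 2), 50, n)
  counts[1:5, 1:30] <- counts[1:5, 1:30] + 20
  cm <- tiny_matrix(counts, tissue = rep("CA", n))
  labels <- rep(c("A", "B"), each = 30)
  m1 <- wilcoxon_markers(cm, labels)

  perm <- sample(n)
  cm2 <- subset_cells(cm, cells = perm)
  m2 <- wilcoxon_markers(cm2, labels[perm])
  expect_equal(m1[order(m1$cluster, m1$gene_id), c("cluster", "gene_id", "p")],
               m2[order(m2$cluster, m2$gene_id), c("cluster", "gene_id", "p")],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cna_dependent_genes reports only concordant coupled genes", {
  # cohort with a strong amplification; a handful of genes inside it are
  # dosage-decoupled and must not be reported
  spec <- cohort_spec(
    n_patients = c(NL = 3, LP = 2, CA = 4, LN = 2),
    cells_per_sample = 150,
    cna_segments = data.frame(chrom = "chr1", start = 46, end = 95,
                              direction = "gain", copy_ratio = 2.5,
                              carrier = "clone", carrier_fraction = 1,
                              stringsAsFactors = FALSE),
    cis_fraction = 0.2, rng_seed = 17L)
  sim <- generate_cohort(spec)
  cm <- sim$matrix
  cfg <- synthetic_config(n_permutations = 2000, perm_p = 0.001)
  cis_cells <- sim$truth$cells$cell_id[sim$truth$cells$is_cis]
  nl_epi <- cells_where(cm, tissue = "NL", cell_type = "epithelial")
  res <- infer_cna(cm, cfg, cells = c(cis_cells, nl_epi))
  dep <- cna_dependent_genes(res, cm, cis_cells, nl_epi, cfg)

  seg_genes <- sprintf("G%04d", 46:95)
  coupled <- setdiff(seg_genes, sim$truth$decoupled_genes)
  expect_gt(sum(dep$gene_id %in% coupled), 25)
  expect_false(any(dep$gene_id %in% sim$truth$decoupled_genes))
  expect_true(all(dep$concordant))
  # nothing reported off the amplicon
  expect_lt(mean(!dep$gene_id %in% seg_genes), 0.35)

  expect_error(cna_dependent_genes(res, cm, cis_cells,
                                   c(nl_epi, cis_cells[1]), cfg),
               "overlap")

  # two groups from the same population -> nothing reported
  half <- length(nl_epi) %/% 2
  dep0 <- cna_dependent_genes(res, cm, nl_epi[seq_len(half)],
                              nl_epi[(half + 1):length(nl_epi)], cfg)
  expect_equal(nrow(dep0), 0)
})

test_that("stepwise_genes finds planted monotone programs", {
  spec <- cohort_spec(
    n_patients = c(NL = 3, LP = 3, CA = 4, LN = 1),
    cells_per_sample = 150,
    mixtures = rbind(NL = c(0.4, 0.4, 0.1, 0.05, 0.03, 0.02),
                     LP = c(0.4, 0.4, 0.1, 0.05, 0.03, 0.02),
                     CA = c(0.4, 0.4, 0.1, 0.05, 0.03, 0.02),
                     LN = c(0.4, 0.4, 0.1, 0.05, 0.03, 0.02)),
    cna_segments = data.frame(),
    epi_step_mult = c(1, 3, 9, 9),
    cis_fraction = 0, rng_seed = 23L)
  sim <- generate_cohort(spec)
  cfg <- synthetic_config(n_permutations = 2000)
  sw <- stepwise_genes(sim$matrix, "fibroblast", config = cfg)
  truth_up <- sim$truth$stepwise$gene_id[
    sim$truth$stepwise$cell_type == "fibroblast"]
  found <- sw$gene_id[sw$direction == "up"]
  expect_gt(mean(truth_up %in% found), 0.8)
  # declining distractor ligands are never called stepwise-up
  declining <- sim$truth$lr$ligand[sim$truth$lr$class == "declining"]
  expect_false(any(declining %in% found))

  sw_epi <- stepwise_genes(sim$matrix, "epithelial", config = cfg)
  truth_epi <- sim$truth$stepwise$gene_id[
    sim$truth$stepwise$cell_type == "epithelial"]
  expect_gt(mean(truth_epi %in%
                   sw_epi$gene_id[sw_epi$direction == "up"]), 0.7)

  expect_error(stepwise_genes(sim$matrix, "no_such_type", config = cfg),
               "missing in tissue")
})
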