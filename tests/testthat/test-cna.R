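
test_that("filter_gene_set applies the three exclusion rules", {
  # all genes on chrY -> nothing retained
  gm_y <- data.frame(gene_id = paste0("y", 1:5), chrom = "chrY",
                     start_bp = 1:5 * 1000, end_bp = 1:5 * 1000 + 10,
                     biotype = "protein_coding", stringsAsFactors = FALSE)
  expect_error(filter_gene_set(gm_y), "degenerate")

  # hypergeometric oracle: 4 genes within 0.8 Mb all annotated to term T,
  # background 1000 genes of which 10 carry T:
  # P = C(10,4) C(990,0) / C(1000,4) ~ 5.1e-10 < 0.05 -> all 4 excluded
  p_exact <- choose(10, 4) / choose(1000, 4)
  expect_equal(p_exact,
               phyper(3, 10, 990, 4, lower.tail = FALSE))
  gm <- data.frame(gene_id = paste0("g", 1:8), chrom = "chr1",
                   start_bp = c(1, 2, 3, 4, 30, 40, 50, 60) * 1e5,
                   end_bp = c(1, 2, 3, 4, 30, 40, 50, 60) * 1e5 + 10,
                   biotype = "protein_coding", stringsAsFactors = FALSE)
  gm$go_terms <- c(rep(list("T"), 4), replicate(4, character(0),
                                                simplify = FALSE))
  # background map spanning a 1000-gene universe: 10 genes carry T
  bg_map <- list(T = c(paste0("g", 1:4), paste0("bg", 1:6)),
                 OTHER = c(paste0("g", 5:8), paste0("u", 1:986)))
  ret <- filter_gene_set(gm, go_background = bg_map)
  expect_false(any(paste0("g", 1:4) %in% gm$gene_id[ret]))
  expect_true(all(paste0("g", 5:8) %in% gm$gene_id[ret]))

  # no shared term in any window -> everything retained
  gm2 <- gm
  gm2$go_terms <- replicate(8, character(0), simplify = FALSE)
  ret2 <- filter_gene_set(gm2)
  expect_equal(length(ret2), 8)

  # immune biotypes removed
  gm3 <- gm2
  gm3$biotype[1:2] <- c("IG_C_gene", "TR_V_gene")
  ret3 <- filter_gene_set(gm3)
  expect_false(any(c("g1", "g2") %in% gm3$gene_id[ret3]))
})

test_that("relative_track subtracts, clips, and smooths as stated", {
  set.seed(1)
  n_ref <- 25
  vals <- matrix(rpois(5 * (n_ref + 2), 20), 5, n_ref + 2)
  cm <- tiny_matrix(vals, tissue = rep("NL", n_ref + 2))
  cmn <- normalize_cells(cm)
  ref <- colnames(cmn$values)[1:n_ref]
  ref_mean <- rowMeans(as.matrix(cmn$values[, ref]))

  # a synthetic cell equal to the reference mean -> all-zero track
  cm2 <- cmn
  cm2$values[, n_ref + 1] <- ref_mean
  tr <- relative_track(cm2, ref, colnames(cm2$values)[n_ref + 1],
                       window = 3)
  expect_equal(as.numeric(tr), rep(0, 5))

  # constant offset +0.2 survives the moving average untouched
  cm3 <- cmn
  cm3$values[, n_ref + 2] <- ref_mean + 0.2
  tr3 <- relative_track(cm3, ref, colnames(cm3$values)[n_ref + 2],
                        window = 3)
  expect_equal(as.numeric(tr3), rep(0.2, 5), tolerance = 1e-12)

  expect_error(relative_track(cmn, ref[1:10], NULL), "insufficient")
  expect_error(relative_track(cm, ref, NULL), "log-normalized")
})

test_that("the truncated moving average matches the hand-computed case", {
  # w = 3 on raw ratios [0,0,3,0,0] -> [0,1,1,1,0]
  n_ref <- 20
  vals <- matrix(1, 5, n_ref + 1)
  cm <- tiny_matrix(vals, tissue = rep("NL", n_ref + 1))
  cm$scale <- "lognorm"
  ref <- colnames(cm$values)[1:n_ref]
  cm$values[, n_ref + 1] <- c(1, 1, 4, 1, 1)  # ratios 0,0,3,0,0
  tr <- relative_track(cm, ref, colnames(cm$values)[n_ref + 1], window = 3)
  expect_equal(as.numeric(tr), c(0, 1, 1, 1, 0))
})

test_that("segment_track finds exact breakpoints and matches the oracle", {
  set.seed(42)
  # constant track -> single segment
  s <- segment_track(rep(0.3, 60))
  expect_equal(nrow(s), 1)
  expect_equal(s$start, 1)
  expect_equal(s$end, 60)

  # noiseless 50/50 step -> exactly one breakpoint between 50 and 51
  s2 <- segment_track(c(rep(0, 50), rep(1, 50)))
  expect_equal(nrow(s2), 2)
  expect_equal(s2$end[1], 50)
  expect_equal(s2$mean, c(0, 1))

  # short track -> one segment with a warning
  expect_warning(s3 <- segment_track(rnorm(6), min_width = 5), "min_width")
  expect_equal(nrow(s3), 1)

  # oracle equivalence on <= 20-gene tracks with <= 1 planted breakpoint
  for (rep_i in 1:10) {
    n <- sample(12:20, 1)
    x <- rnorm(n, 0, 0.2)
    if (rep_i %% 2 == 0) {
      b <- sample(6:(n - 6), 1)
      x[(b + 1):n] <- x[(b + 1):n] + 2
    }
    set.seed(100 + rep_i)
    ours <- segment_track(x, n_perm = 2000)
    set.seed(200 + rep_i)
    orc <- oracle_two_segment(x)
    expect_equal(ours$mean, orc$mean, tolerance = 1e-12,
                 info = paste("instance", rep_i))
    expect_equal(ours$end, orc$end, info = paste("instance", rep_i))
  }
})

test_that("call_cna uses strict inequalities at the fold cutoff", {
  seg <- data.frame(start = c(1, 11, 21, 31), end = c(10, 20, 30, 40),
                    mean = c(0.15, 0.1, -0.1, 0))
  called <- call_cna(seg, cutoff = 0.1)
  expect_equal(called$call, c("gain", "neutral", "neutral", "neutral"))
  expect_equal(call_cna(data.frame(start = 1, end = 5, mean = -0.11),
                        0.1)$call, "loss")
})

test_that("cna_burden is additive over aberrant segments", {
  seg <- call_cna(data.frame(start = c(1, 251, 301), end = c(250, 300, 320),
                             mean = c(0.4, 0, -0.2)), 0.1)
  expect_equal(cna_burden(seg), 250 + 20)
  expect_true(250 > 200)  # such an immune cell would be flagged
  seg2 <- call_cna(data.frame(start = c(1, 31), end = c(30, 50),
                              mean = c(0.2, -0.3)), 0.1)
  expect_equal(cna_burden(seg2), 50)
  all_neutral <- call_cna(data.frame(start = 1, end = 100, mean = 0), 0.1)
  expect_equal(cna_burden(all_neutral), 0)
})

test_that("raising the fold cutoff never increases burden", {
  set.seed(9)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    bounds <- sort(sample(1:99, k - 1))
    seg <- data.frame(start = c(1, bounds + 1), end = c(bounds, 100),
                      mean = rnorm(k, 0, 0.2))
    burdens <- vapply(c(0.05, 0.1, 0.2, 0.4), function(cut) {
      cna_burden(call_cna(seg, cut))
    }, 0)
    expect_true(all(diff(burdens) <= 0))
  }
})

test_that("burden_contrast handles identical and degenerate groups", {
  b <- c(a1 = 10, a2 = 20, a3 = 30)
  res <- burden_contrast(b, b, n_permutations = 200, rng_seed = 1)
  expect_equal(res$diff, 0)
  expect_equal(res$perm_p, 1)

  # a single-cell group still runs and yields a wide null
  res2 <- burden_contrast(c(x = 100), c(y1 = 10, y2 = 12, y3 = 9),
                          n_permutations = 200, rng_seed = 1)
  expect_true(res2$perm_p > 0.2)
  expect_equal(res2$mean_a, 100)
})

test_that("recurrent_cna applies the frequency-in-samples rule", {
  # build a minimal cna_result by hand: 10 genes, 3 samples x 10 cells
  n_genes <- 10
  cells <- sprintf("s%d_c%d", rep(1:3, each = 10), rep(1:10, 3))
  tracks <- matrix(0, n_genes, 30, dimnames = list(
    sprintf("g%02d", 1:n_genes), cells))
  segs <- do.call(rbind, lapply(seq_along(cells), function(i) {
    data.frame(cell_id = cells[i], chrom = "chr1", start = 1, end = 10,
               start_bp = 1, end_bp = 10, mean = 0, call = "neutral",
               stringsAsFactors = FALSE)
  }))
  # gene run 3..5 gained: 6% of cells in sample 1 and 7% in sample 2 is not
  # reachable with 10 cells; use 1 cell (10%) in samples 1 and 2
  segs$call[segs$cell_id == "s1_c1"] <- "gain"
  segs$start[segs$cell_id == "s1_c1"] <- 3
  segs$end[segs$cell_id == "s1_c1"] <- 5
  segs$call[segs$cell_id == "s2_c1"] <- "gain"
  segs$start[segs$cell_id == "s2_c1"] <- 3
  segs$end[segs$cell_id == "s2_c1"] <- 5
  gm <- data.frame(gene_id = rownames(tracks), chrom = "chr1",
                   start_bp = 1:10 * 1000, end_bp = 1:10 * 1000 + 10,
                   biotype = "protein_coding", stringsAsFactors = FALSE)
  res <- structure(list(tracks = tracks, segments = segs,
                        burden = setNames(rep(0, 30), cells),
                        gene_meta = gm, retained = 1:10),
                   class = "cna_result")
  meta <- data.frame(cell_id = cells,
                     sample_id = sub("_.*", "", cells),
                     tissue_type = "CA", cell_type = "epithelial",
                     stringsAsFactors = FALSE)
  reg <- recurrent_cna(res, meta, "CA", pipeline_config())
  expect_equal(nrow(reg), 1)
  expect_equal(reg$direction, "gain")
  expect_equal(reg$start_idx, 3)
  expect_equal(reg$end_idx, 5)
  expect_equal(reg$n_samples_passing, 2)

  # frequencies {0.2, 0} in two samples: only one sample passes -> nothing
  segs2 <- segs
  segs2$call[segs2$cell_id == "s2_c1"] <- "neutral"
  segs2$call[segs2$cell_id == "s1_c2"] <- "gain"
  segs2$start[segs2$cell_id == "s1_c2"] <- 3
  segs2$end[segs2$cell_id == "s1_c2"] <- 5
  res2 <- res
  res2$segments <- segs2
  expect_equal(nrow(recurrent_cna(res2, meta, "CA", pipeline_config())), 0)

  # single-sample tissue type -> error naming the precondition
  meta3 <- meta
  meta3$sample_id <- "s1"
  expect_error(recurrent_cna(res, meta3, "CA", pipeline_config()),
               ">= 2 samples")
})

test_that("raising recurrence_freq never increases region count", {
  res <- default_cna_epi()
  sim <- default_sim()
  counts <- vapply(c(0.05, 0.2, 0.5, 0.9), function(f) {
    reg <- recurrent_cna(res, sim$matrix$cell_meta, "CA",
                         synthetic_config(recurrence_freq = f))
    if (nrow(reg) == 0) 0L else sum(reg$n_genes)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})
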