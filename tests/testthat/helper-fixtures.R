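# Shared fixtures, built once per test run and cached. The default cohort
# and its copy-number inference are expensive (minutes), so every test that
# needs them goes through these accessors.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# The stated synthetic world: pipeline thresholds are the published
# defaults; the smoothing window and segmentation permutation count are
# scaled to the synthetic genome (140-gene chromosomes vs ~1000+ real
# genes per chromosome under the 101-gene default window).
synthetic_config <- function(...) {
  pipeline_config(smoothing_window = 11, cbs_n_perm = 200, ...)
}

default_sim <- function() {
  fixture("default_sim", function() generate_cohort(cohort_spec()))
}

# one shared inference over all epithelial cells of the default cohort
default_cna_epi <- function() {
  fixture("default_cna_epi", function() {
    sim <- default_sim()
    cells <- cells_where(sim$matrix, tissue = c("LP", "CA", "LN"),
                         cell_type = "epithelial")
    infer_cna(sim$matrix, synthetic_config(), cells = cells)
  })
}

# a small cohort for I/O, marker and LR plumbing tests
small_sim <- function() {
  fixture("small_sim", function() {
    generate_cohort(cohort_spec(
      n_patients = c(NL = 3, LP = 2, CA = 6, LN = 2),
      cells_per_sample = 120, rng_seed = 7L))
  })
}

# a minimal hand-built cell_matrix with controllable values
tiny_matrix <- function(values = NULL, n_genes = 3, n_cells = 2,
                        tissue = rep("CA", n_cells)) {
  if (is.null(values)) {
    values <- matrix(seq_len(n_genes * n_cells), n_genes, n_cells)
  }
  n_genes <- nrow(values)
  n_cells <- ncol(values)
  cell_meta <- data.frame(
    cell_id = sprintf("c%02d", seq_len(n_cells)),
    patient_id = sprintf("p%02d", seq_len(n_cells)),
    tissue_type = tissue, hpv_status = "neg",
    cell_type = "epithelial", stringsAsFactors = FALSE)
  gene_meta <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n_genes)),
    chrom = "chr1",
    start_bp = seq_len(n_genes) * 1000,
    end_bp = seq_len(n_genes) * 1000 + 500,
    biotype = "protein_coding", stringsAsFactors = FALSE)
  dimnames(values) <- list(gene_meta$gene_id, cell_meta$cell_id)
  cell_matrix(values, cell_meta, gene_meta)
}
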