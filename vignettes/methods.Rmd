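---
title: "Methods: expression-based copy-number inference and stepwise-progression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-based copy-number inference and stepwise-progression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`hnsccStepwise` re-implements, as a tested and reusable pipeline, the
bespoke computational procedures used to study the stepwise progression of
head and neck squamous cell carcinoma (HNSCC) across four tissue states:
normal mucosa (NL), premalignant leukoplakia (LP), primary carcinoma (CA)
and nodal metastasis (LN). Five analytical stages are covered:

1. **Copy-number inference from expression** (`infer_cna`,
   `recurrent_cna`): per-cell relative expression tracks against an immune
   reference, circular binary segmentation (CBS), gain/loss calls, and
   recurrence calling per tissue type.
2. **Carcinoma-in-situ (CIS) detection** (`classify_cis`): premalignant LP
   epithelial cells carrying malignant-like aberration profiles.
3. **Permutation differential expression** (`permuted_t_test`,
   `wilcoxon_markers`, `cna_dependent_genes`, `stepwise_genes`).
4. **Interdependent ligand-receptor analysis**
   (`find_interdependent_pairs`, `patient_coupling`): paracrine pairs whose
   ligand is confined to fibroblasts with stepwise-rising expression while
   the receptor is expressed by malignant cells.
5. **Bulk deconvolution and prognosis** (`build_signature`,
   `estimate_proportions`, `ntp_assign`, `stratify`, `logrank_survival`).

Clustering, embeddings and pseudotime are out of scope: cluster and tissue
labels are taken as inputs. Everything is exercised against a synthetic
cohort generator (`generate_cohort`) that plants known ground truth.

# The copy-number model

A cell's DNA copy state is inferred from expression under a proportional
dosage model: a single-copy gain multiplies a gene's expected expression by
1.5, a single-copy loss by 0.5 (diploid arithmetic). The inference chain is:

1. **Gene filters** (`filter_gene_set`). Genes on sex chromosomes and genes
   with immune-related biotypes (`IG_*`, `TR_*`) are removed, as are
   chromosomal gene clusters that are functionally co-expressed: for every
   1 Mb window (anchored at each gene midpoint) a one-sided hypergeometric
   test checks each gene-ontology term with at least three annotated window
   genes; at `P < 0.05` the annotated window genes are excluded. These
   filters remove the main sources of coordinated, non-dosage expression.
   In addition, genes with mean counts below 0.1 — in all cells or in the
   diploid reference cells — are dropped: a gene silent in the reference
   carries no dosage signal, its log ratio is pinned near zero whatever the
   copy state.
2. **Relative track** (`relative_track`). Using the immune cells of NL
   tissue as the diploid reference, each gene's log-normalized expression
   (per-cell scaling to 10,000, `log2(x + 1)`; the source protocol does not
   print its normalization, so this fixed convention is documented here) is
   reduced by the reference mean, clipped to [-3, 3], and smoothed with a
   centered moving average (window `smoothing_window` genes, truncated at
   chromosome ends).
3. **Segmentation** (`segment_track`). Recursive CBS: the arc `(i, j]`
   maximizing `|mean_in - mean_out| / sqrt(1/k + 1/(n-k))` is accepted as a
   split when its permutation P (value permutations) is below
   `cbs_alpha = 0.01`; segments shorter than `cbs_min_width = 5` genes are
   merged into the nearest neighbor by mean similarity. The permutation
   loop is curtailed sequentially: it stops as soon as the accept/reject
   decision at level alpha is settled, which changes no decision.
4. **Split undoing** (`cbs_undo_sd = 4`). A value-permutation null is
   exchangeable, but a smoothed track is autocorrelated over one window, so
   CBS systematically over-splits smoothed noise. We therefore undo splits
   the way DNAcopy's `undo.splits = "sdundo"` does: adjacent segments whose
   means differ by less than `undo_sd` per-point standard deviations are
   merged. The noise scale is estimated from first differences of the
   *unsmoothed* ratios (breakpoints touch too few raw differences to
   disturb a MAD estimate, whereas ramps contaminate a large share of
   smoothed-track differences). The default 4 is deliberately more
   aggressive than DNAcopy's usual 2-3 because single-cell tracks are far
   noisier than array data.
5. **Boundary refinement.** Smoothing localizes a breakpoint only to about
   half a window; each boundary is therefore moved (within one window) to
   the position minimizing the squared error of the unsmoothed ratios
   against the two adjacent segment levels.
6. **Neutral-state calibration.** Library renormalization shifts every
   gene's log ratio when part of the genome is amplified or lost (a
   compositional effect), so each cell's neutral level is re-estimated as
   the densest gene-weighted cluster of its segment means and subtracted.
   This plays the role of inferCNV's median re-centering but remains
   calibrated when a third of the measured genome is aberrant, where a
   plain median is dragged toward the gains.
7. **Calls** (`call_cna`). A segment is a gain when its mean exceeds the
   fold cutoff 0.1 (strict, "more than"), a loss below -0.1. The cutoff is
   interpreted on the smoothed log2-ratio scale; whether the source applied
   it to per-gene values or segment means is not stated, and segment means
   are used here (per-gene values would make single noisy genes callable).
   Calls use a boundary-trimmed interior mean — the moving average
   contaminates up to half a window on each side of a breakpoint with the
   neighboring segment's level — while the reported segment mean is the
   plain mean, which conserves the chromosome track mean exactly.

**Burden and recurrence.** A cell's burden is the number of genes in
non-neutral segments; immune cells with burden strictly above 200 genes are
reassigned as undetermined. A gene is recurrently gained (lost) in a tissue
type when the fraction of a sample's epithelial-lineage cells calling it
reaches 0.05 in at least two samples; maximal runs of consecutive recurrent
genes form the reported regions. Note that with few cells per sample this
frequency rule is fragile (two noisy cells out of forty already exceed
0.05); it behaves as intended only with on the order of a hundred cells per
sample, which the synthetic cohort provides.

# CIS detection

Malignant cells are the epithelial cells of CA/LN tissue. An LP epithelial
cell is called CIS when its smoothed track correlates with the mean
malignant track at Pearson `r >= 0.3` *and* its burden is at least 50
genes. The source describes CIS cells only as "harboring CNAs similar to
malignant cells"; this two-axis rule (pattern plus load) is our
operationalization — correlation alone is degenerate for near-neutral
tracks, burden alone ignores the pattern. Both thresholds are configurable;
raising either is monotone (never creates calls).

# Permutation tests

`permuted_t_test` uses the Welch t statistic under a label-permutation
null; when `choose(n, n_a)` does not exceed the permutation budget the null
is enumerated exactly (the p-value is then the fraction of all assignments,
including the observed one, at least as extreme), otherwise sampled with
`p = (1 + exceedances) / (1 + B)`. Cluster markers use the Wilcoxon
rank-sum test (exact for small untied samples, normal approximation with
tie and continuity correction otherwise) at `P < 0.001` and log2 fold
difference above 1. "Fold difference > 1" is read on the log2-normalized
scale (i.e. more than two-fold); the source does not define the scale and a
config toggle documents the choice. CNA-dependent genes must pass the
permutation test on *both* the smoothed track and expression between the
contrasted groups, with concordant signs. Stepwise genes must increase (or
decrease) at every adjacent step of NL → LP → CA with per-step permutation
`P < 0.001` and per-step log2 fold above `step_fold = 0.25`; the fold floor
prevents noise-monotone calls and is our choice (no per-step effect size is
printed in the source).

# Ligand-receptor interdependence

"Expressed" is detection: a count above zero. A pair is interdependent when
(1) the ligand's detection fraction in fibroblasts rises monotonically over
the available NL → LP → CA order, by at least `lr_min_increase = 0.1`
overall, ending at `expr_min = 0.25` or higher; (2) the receptor's fraction
in malignant cells is at least `expr_min`; and (3) the ligand's fraction in
malignant cells is at most `absent_max = 0.05`. The thresholds mirror how
the source presents expressed-cell proportions without printing cutoffs;
they are configurable and logged. `patient_coupling` reports the Pearson
correlation of per-patient fibroblast-ligand and malignant-receptor means,
plus a within-fibroblast negative control to demonstrate non-autocrine
specificity.

# Deconvolution, subtype templates and survival

The signature matrix holds per-cluster mean linear expression over the
union of per-cluster top-50 Wilcoxon markers. Proportions are estimated by
non-negative least squares (Lawson-Hanson, implemented in `nnls_fit`) with
coefficients normalized to sum to one; estimates are invariant to scaling a
bulk profile. NNLS is a deliberate minimal surrogate — the source's exact
deconvolution algorithm is not printed — and is isolated behind
`estimate_proportions` so an alternative can be slotted in. Nearest
template prediction assigns a profile to the template with smallest cosine
distance over that template's markers; significance comes from gene-label
permutations of the profile, with Benjamini-Hochberg control across
profiles and `FDR <= 0.05` required for an assignment. Survival
stratification takes the samples strictly above the 70th percentile
(linear-interpolation type-7; boundary ties go low) of the focal cluster's
proportion as the high group, skipping the split when the percentile value
is zero; the log-rank test and Kaplan-Meier curves come from the `survival`
package, and the hazard ratio is the observed/expected ratio
`(O_high/E_high)/(O_low/E_low)` rather than a fitted regression
(multivariate models are out of scope).

# The synthetic cohort: what it emulates, and what it does not

`cohort_spec()` describes a 23-patient cohort (NL 9, LP 4, CA 20, LN 4
samples; LN samples pair with the first CA patients), six cell types whose
mixtures shift across progression, and these planted truths:

* four 50-gene copy-number segments on 140-gene chromosomes — a clonal
  gain (chr1) and loss (chr5) carried by every malignant and CIS cell, and
  an extra gain (chr3) and loss (chr6) private to HPV-negative malignant
  cells, yielding the roughly two-fold burden difference between
  HPV-negative and HPV-positive tumors;
* a 10% CIS subclone among LP epithelial cells carrying the clonal
  segments;
* five dosage-decoupled genes inside the chr1 gain (copy state changes,
  expression does not) for the CNA-dependent-gene contrast;
* 50 ligand-receptor pairs: 5 interdependent (stepwise fibroblast ligand,
  ligand absent from malignant cells, receptor expressed broadly), 15 with
  mildly declining ligand detection (ligands tied to normal stroma diluted
  in tumor), 15 autocrine (ligand expressed by malignant cells too), and 15
  with a silent receptor;
* stepwise epithelial and fibroblast-ligand programs with per-tissue mean
  multipliers;
* a 7-gene co-expressed functional cluster within 1 Mb on chr4 (shared GO
  term, 3x epithelial boost) that mimics a gain and must be removed by the
  GO-window filter;
* near-exclusive cell-type markers (12 per type, 6-fold up in their own
  type and near-silent elsewhere, like canonical markers) confined to
  chromosome X and the immunoglobulin-biotype genes, plus a weak
  genome-wide per-(gene, type) log-normal identity factor (sdlog 0.02).

Counts are negative binomial (size 90) around per-(gene, type, tissue)
means with log-normal base means (median 90 counts) and a log-normal
library-size factor. **These are not 10x-like sparse counts, by design**:
with ~900 genes standing in for ~15,000, each smoothing window holds ~10x
fewer genes than the real pipeline's 101-gene window, so per-gene noise
must be correspondingly smaller for the *window-averaged* noise-to-signal
ratio — the quantity the method actually operates on — to match the real
regime. The same scaling argument fixes the test-suite smoothing window at
11 genes. Placing the strong identity markers on chrX/IG genes is the
second deliberate idealization: it makes the standard filters (which the
real pipeline applies for exactly this reason) sufficient to keep the
autosomal dosage channel identifiable. Gains and losses are balanced in
total transcript mass within each clone so that the planted aberrations do
not themselves shift the compositional baseline; real tumors are not
balanced, which is precisely why the neutral-state calibration step exists
(and the calibration is exercised by the imbalance between the clone and
the HPV-negative private segments at the cell level).

A green test therefore establishes that the implementation recovers planted
dosage signals, subclones, interdependent pairs, proportions and hazard
structure under a faithful but idealized noise model. It does not establish
robustness to doublets, ambient RNA, patient batch effects, unbalanced
genome-wide aneuploidy, or real 10x sparsity.

# Numerical choices and degenerate inputs

* CBS arc ties break toward the smallest start then smallest end;
  permutations use R's RNG, so `pipeline_config(rng_seed=)` makes the whole
  inference deterministic.
* Tracks shorter than `2 * cbs_min_width` genes return a single segment
  with a warning.
* Correlation against a zero-variance track is defined as 0 (CIS) or
  reported `NA` with a reason (couplings).
* Exact Welch-t enumeration counts the observed assignment, so `p >=
  1/choose(n, n_a)`; sampled p-values are bounded below by `1/(B + 1)`.
* `estimate_proportions` errors below 50 shared genes; an all-zero NNLS
  fit yields `NA` proportions with a warning.
* Stratification at a zero percentile value is skipped with a warning
  rather than producing a meaningless "high" group.

# Known limitations

* The per-cell CBS is O(n^2) per chromosome scan; tracks of many thousands
  of genes per chromosome would need the O(n) scan-statistic approximations
  used by DNAcopy.
* Recurrence calling inherits the fragility of the 5%-in-2-samples rule at
  low cell counts (see above).
* The CIS rule is a documented surrogate; the source does not describe its
  exact criterion.
* The LR scoring is detection-fraction-based; a mean-expression variant is
  not implemented.
* NNLS deconvolution assumes linear mixing of cluster means over marker
  genes; no batch/platform correction is attempted.
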