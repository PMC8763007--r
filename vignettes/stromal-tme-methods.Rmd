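---
title: "Methods: stromal-cell heterogeneity analysis for pan-cancer scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stromal-cell heterogeneity analysis for pan-cancer scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmestroma)
```

# Overview

`tmestroma` implements a single analysis pipeline for examining stromal
cells — endothelial cells (ECs) and fibroblasts/myofibroblasts — in the
tumor microenvironment (TME) across many cancer scRNA-seq datasets. The
stages are:

1. **QC and normalization**, with separate conventions for UMI-based
   (droplet) and full-length (Smart-seq-style) platforms;
2. **major-cell-type identification**: highly variable gene (HVG)
   selection, covariate regression, PCA, graph clustering, marker-based
   annotation;
3. **subtype transfer classification**: ECs into five vascular subtypes
   (tip `C1_ESM1`, venous `C2_ACKR1`, capillary `C3_CA4`, arterial
   `C4_FBLN5`, lymphatic `C5_PROX1`) and fibroblasts/myofibroblasts into
   common subtypes (`C7_MYH11` myofibroblasts, `C8_RGS5` pericytes,
   `C9_CFD` adipogenic, `C10_COMP`, `C11_SERPINE1`) using
   subtype-specific gene models from a reference study, with optional
   rejection of cells not significantly similar to any model;
4. **composition analysis** by cancer type, tumor vs adjacent normal
   tissue, and patient age (young < 60 vs old ≥ 60 years);
5. **per-cell pathway activity** via single-sample gene set enrichment
   (ssGSEA), typically for the hallmark EMT and TGF-β signaling sets.

Because the real pan-cancer datasets are external downloads, the package
ships a synthetic-data generator that plants the structure each stage is
supposed to recover, so the whole pipeline is testable end to end.

# QC and normalization

Cells are kept when they satisfy **strict** bounds: more than 200 and
fewer than 6,000 detected genes, mitochondrial read fraction below 25%,
and (UMI platforms only) more than 400 UMIs. Boundary cells (exactly 200
genes, exactly 25% mito, exactly 400 UMIs) are removed. Degenerate
all-zero cells get `mito_fraction = 0` by convention and fail the gene
filter.

UMI counts are library-size normalized as
$x_{gc} = \ln\!\left(1 + \frac{n_{gc}}{N_c}\cdot 10^4\right)$.
The natural-log convention is the single-cell standard; the inverse
identity $\sum_g (e^{x_{gc}} - 1) = 10^4$ holds exactly per cell and is
asserted in the tests. Full-length data (FPKM or TPM) are rescaled per
cell to TPM (columns sum to $10^6$) and transformed to
$\log_2(\mathrm{TPM}/10 + 1)$, so TPM = 10 maps exactly to 1.

**Cell-cycle scores** follow the program-minus-control design: the score
is the mean expression of the program genes minus the mean of control
genes drawn from matching average-expression bins (25 equal-size bins,
100 controls per program gene, sampled with replacement under a fixed
seed). The S and G2M gene lists are user input; the synthetic generator
plants its own. Both scores enter the regression below.

**HVG selection (VST)** fits a loess trend (span 0.3, degree 2) of
log10 variance on log10 mean over genes with nonzero variance,
standardizes each gene's counts by the trend-predicted standard
deviation, clips standardized values at ±√n_cells, and ranks genes by the
variance of the clipped values; the top 2,000 are kept. We clip
symmetrically (some implementations clip only the upper tail); the
difference only matters for genes with extreme low outliers, which are
rare in counts. Ties in the ranking are broken by gene name so the
selection is deterministic.

**Regression and scaling**: per HVG, ordinary-least-squares residuals
against mito fraction, total UMIs (UMI platforms), sample identity
(categorical indicators), and both cell-cycle scores, then centered,
scaled to unit variance, and clipped at ±10. Rank-deficient designs are
handled by the pivoted-QR projection (residuals are unique even when
coefficients are not). Genes whose residual variation is numerically
zero (constant genes, or genes exactly equal to a covariate) become
all-zero rows rather than amplified noise. Only the HVGs are scaled —
they are all that clustering consumes.

# Clustering and annotation

PCA is centered (not variance-scaled — rows are already unit variance),
computed by SVD, with a deterministic sign convention (largest-magnitude
loading positive). The number of dimensions is chosen by an elbow rule:
the first component index at which the decrease between consecutive
explained-variance ratios falls below 0.001, clamped to [10, 50]. On a
spectrum that never flattens the rule returns the upper clamp; on a flat
spectrum it returns the lower clamp.

Clustering builds an exact k-nearest-neighbor graph (Euclidean, k = 20)
and partitions it with multilevel modularity (Louvain, resolution 0.8),
seeded for determinism. These algorithm choices are the de-facto
single-cell standard; k and resolution are exposed because the
modularity resolution limit can split large homogeneous populations into
several clusters — harmless here, because annotation operates per
cluster and maps several clusters to one type.

Annotation scores each cluster against each marker gene set by the mean
expression of the set's genes over the cluster's cells, z-scored across
clusters per set so high-expression sets cannot dominate, and assigns the
argmax set. Exact ties go to the lexicographically first type name with a
warning.

# Subtype transfer classification

The subtype "model" is a centroid profile over the union of all
signature genes. Two constructions are supported:

* **reference centroids** — per-gene means over a labeled reference
  dataset's cells (log-normalized, or log2(TPM/10+1) for full-length
  references);
* **indicator centroids** — 1 on the subtype's own signature genes, 0
  elsewhere, for when only the gene lists are available.

Similarity is the Pearson correlation over the union (Spearman is
offered); Pearson is scale-free, hence invariant to per-cell affine
transforms — asserted exactly in the tests. Each cell takes the argmax
label. Significance per model comes from a gene-label permutation null:
the cell's values over the union are permuted (n_perm = 1000) and the
correlation recomputed; $p = (1 + \#\{null \ge obs\})/(n_{perm}+1)$.
With rejection enabled, a cell whose p-values all exceed α = 0.05 is
labeled `unknown`. Following the asymmetry of the source analysis,
rejection defaults off for ECs (every EC is forced into one of the five
subtypes) and should be enabled for fibroblasts/myofibroblasts, where
tissue-specific subtypes outside the model set are expected.

Two calibration caveats are worth knowing. First, the permutation test
is exact for the null "this cell's values are exchangeable across the
union genes"; a cell with no subtype signal still has gene-to-gene
baseline differences, so its p-values are conservative (super-uniform),
never anti-conservative. Second, with a union of only ~200 genes (40 per
subtype × 5), the chance correlation between the dataset's per-gene
baseline profile and any one centroid is of the same order as the
permutation-null standard deviation, so rejection rates on null data
shift coherently between runs; this is inherent to the small signature
size, not to the estimator.

Fraction denominators follow the source conventions: EC subtype
fractions are over all classified ECs; fibroblast "common-5" fractions
are computed among cells assigned to the five common subtypes only,
excluding `unknown` and any tissue-specific calls
(`composition_table(..., types = common5)`).

# Composition tables and the transcribed reference tables

`composition_table()` counts cells per group × type and normalizes
within group; `compare_groups()` gives descriptive fraction differences
(no inferential statistics — none are defined for these comparisons);
`stratify_age()` applies the 60-year cutoff (59 is young, 60 is old,
missing ages are `unknown` and excluded from age comparisons).

The package ships transcribed copies of the published pan-cancer survey
summary tables (`pancancer_tables()`): the per-dataset cohort summary
and the per-cell-type count tables for tumor and normal tissues.
`consistency_check()` sums each count column and compares it with the
declared total. Eleven of the twelve tumor columns agree exactly; the
gastric row of the summary table duplicates the CRC totals
(44,684/30,626/14,058) and does not match the gastric count columns
(27,321 tumor, 18,308 normal). The transcription is kept verbatim and
the mismatch is reported, not corrected.

# ssGSEA

For one cell, genes are ranked by expression descending (ties broken by
gene name). Walking down the ranked list, the score integrates the
difference between the weighted in-set empirical CDF and the unweighted
out-of-set CDF:

$$ES = \sum_{i=1}^{N}\left[\frac{\sum_{j \le i,\, j \in S} r_j^{\alpha}}
{\sum_{j \in S} r_j^{\alpha}} - \frac{\#\{j \le i,\, j \notin S\}}{N - |S|}\right]$$

where $r_j = N - \mathrm{pos}_j + 1$ is the rank score (largest at the
top) and α = 0.25. Using rank positions rather than raw expression as
weights makes the score exactly invariant under strictly monotone
transforms of the expression vector and robust to the many zeros of
sparse cells; raw-value weighting is the main alternative convention and
differs only in the weight term. Per-set scores are range-normalized
across the cells of a run (divide by max − min); a zero range falls back
to raw scores with a warning. The implementation is checked against an
independently written loop-based evaluation of the same formula on
1,000 random instances (max |Δ| < 1e-9).

`group_activity_summary()` reports median and quartiles per cell group
(EC subtypes, fibroblast subtypes, tumor cells), and
`gene_activity_matrix()` lets individual genes (e.g. *TGFB1*, *TGFBR2*,
*ACVR1*) be summarized the same way. "Tumor cells" for these comparisons
are cells annotated Epithelial in tumor-tissue samples; no copy-number
inference is performed to separate malignant from normal epithelium —
a documented limitation of marker-based annotation.

# The synthetic-data generator

`simulate_tme_counts()` draws negative-binomial (gamma-Poisson) counts
with mean

$$\mu_{gc} = b_g \cdot d_c \cdot s_{g,\mathrm{sample}(c)} \cdot
2^{\mathrm{lfc} \cdot \mathbb{1}[g \in \mathrm{program}(c)]}$$

and shared dispersion (variance $\mu + \phi\mu^2$). The pieces:

* $b_g$: per-gene baseline, log-normal (meanlog 0, sdlog 1);
* $d_c$: per-cell depth factor, log-normal with mean 1.5 and sd 0.3 —
  with 3,000 genes this gives ~4,000–8,000 UMIs and ~1,300–1,800
  detected genes per cell, comfortably inside the QC window;
* $s_{g,\mathrm{sample}}$: multiplicative per-(sample, gene) batch
  effect, log-normal with sdlog 0.15 — what sample-identity regression
  has to remove;
* planted programs: 25 marker genes per major type and 40 signature
  genes per stromal subtype, both at log2 fold change 2 (the
  signature-set size matches the reference study's design of 40
  subtype-specific genes per EC subtype); an optional cell-cycle program
  (20 S + 20 G2M genes, log2FC 1.5) in a 15% cycling fraction, typical
  of tumor tissue.

Defaults are 2,000 cells × 3,000 genes, six major types at fractions
(T 0.30, Epithelial 0.25, Myeloid 0.13, B 0.12, EC 0.10,
Fibroblast 0.10) loosely following the tumor-tissue compositions of the
transcribed tables, five equal EC and five equal fibroblast subtypes,
and six patient samples (half tumor, half normal; one age per sample,
uniform on 30–85). 1% of genes are flagged mitochondrial (`MT-` prefix).
`simulate_full_length()` reuses the same model and rescales each cell to
TPM. Identical configs and seeds give bit-identical output.

What the generator does **not** emulate: transcriptome-wide gene-gene
correlation, doublets, ambient RNA, zero inflation beyond the NB, and
platform-specific gene-length bias. Passing tests therefore demonstrate
that the pipeline recovers the structure it assumes — planted
multiplicative programs on an NB background — not that it is robust to
every artifact of real data.

# Problem sizes and numerical choices

The test and acceptance runs use sizes chosen to exercise every stage at
full signature scale while staying desk-sized: classifier recovery on
2,000 EC cells × 1,000 genes (5 subtypes × 40 signature genes, matching
the reference signature design), the end-to-end run on the
2,000 × 3,000 default,
p-value calibration on 500 null cells × 1,000 permutations, and ssGSEA
oracle comparisons on universes of ≤ 30 genes where the quadratic
brute-force evaluation is exact and fast.

Other numerical conventions: exact (not approximate) kNN; loess span
0.3; clip values √n_cells (VST) and 10 (scaling); permutation p-values
use the add-one form so p ∈ (0, 1]; all stochastic steps (simulation,
control-gene draws, permutations, Louvain) take explicit seeds and are
reproducible bit-for-bit.

# A worked example

```{r example, eval = FALSE}
sim <- simulate_tme_counts(sim_config(seed = 42))
qc <- compute_cell_qc(sim$counts, sim$genes$gene_id[sim$genes$mito])
keep <- filter_cells(qc, qc_thresholds(), "umi")
ln <- lognormalize(subset_matrix(sim$counts, cells = qc$cell_id[keep]))

ec <- subset_matrix(ln, cells = sim$cells$cell_id[sim$cells$major_type == "EC"])
models <- build_indicator_models(sim$signatures[1:5])
head(classify_cells(ec, models, n_perm = 1000, seed = 1))
```

The vignette states no result that the test suite and
`scripts/acceptance.R` do not themselves compute; run those to reproduce
every number quoted in the README.
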