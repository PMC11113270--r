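---
title: "Aging clocks from genome-wide DNA damage maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aging clocks from genome-wide DNA damage maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakclock)
```

## The problem

Single-strand DNA breaks (SSBs) and abasic (AP) sites are the most common
DNA lesions, and assays now map them genome-wide at single-nucleotide
resolution. breakclock implements the downstream analysis that turns such
maps into age (or tissue) predictors: per-gene lesion densities, univariate
gene ranking, and a repeated random-split evaluation of ten standard model
families, together with a synthetic data generator that makes the whole
pipeline testable without any sequencing data.

The intended design is a mouse panel of five age groups (3, 12, 19, 22 and
24 months) by six tissues with two to three animals per cell — 83 samples
after one brain sample is lost to quality control. The analysis treats age
groups as classes (an "aging clock" that predicts the age class), not as a
continuous regression target.

## The LPKM metric

For gene $i$ and sample $j$,

$$\mathrm{LPKM}_{ij} = \frac{R_{ij} \cdot s}{L_i \cdot N_j},$$

where $R_{ij}$ is the number of **distinct** lesion positions (position and
strand identify a lesion; duplicated records are counted once because the
assay reports positions, not reads) falling in gene $i$'s territory, $L_i$
is the territory length in bp, $N_j$ is the sample's total number of
distinct lesion positions genome-wide, and $s$ is a fixed scale constant.

Choices that matter:

* **Territory.** Either the exon union (`region_mode = "exon"`, with
  $L_i$ the exon-union length) or the whole gene span including introns
  (`"whole_gene"`, with $L_i$ the span length). Exon unions are merged
  across transcripts; no isoform handling.
* **Strands.** Lesions on both strands are pooled by default;
  `strand_mode` can restrict counting to the template or non-template
  strand relative to the gene's orientation.
* **Scale.** The default $s = 10^9$ gives exact "per kb of territory per
  million total positions" semantics ($10^3 \times 10^6$). Any fixed
  positive $s$ is rank-preserving, so gene selection and every model
  downstream are unaffected by this constant; it is exposed as an argument
  for compatibility with other conventions.
* **Overlapping genes.** A lesion inside two genes' territories counts for
  both by default (`overlap = "all_genes"`); `"unique_gene"` discards
  ambiguous lesions.
* **Denominator.** $N_j$ is the genome-wide total per sample, not the
  gene-mapped total; with disjoint genes the genic counts then sum to at
  most $N_j$.

TPM is computed from gene-level read counts with exon-union effective
lengths (`count / length`, rescaled so each sample sums to $10^6$). There
is no isoform EM and no fragment-length correction; this is the naive
gene-level TPM, which is what per-gene damage densities should be compared
against.

Gene filters follow the study: genes with a nonzero value in at least 40%
of samples (TPM) or 20% of samples (LPKM), pooled across all samples.

## Gene selection

`anova_f_scores()` ranks genes by the one-way ANOVA F-score
$F = \mathrm{MSB}/\mathrm{MSE}$ across the label's groups (age groups or
tissues), rank 1 being the largest F. Two degenerate cases need a total
order: genes that separate groups perfectly ($\mathrm{MSE} = 0$,
$\mathrm{MSB} > 0$) get $F = \infty$ and sort above all finite scores;
fully constant genes get $F = 0$. All ties break by ascending `gene_id`, so
rankings are reproducible across machines. Nested top-$k$ sets use the
schedule 15, 25, 50, 75, 100, 150, 200, 300, 400, 500 by default (the study
names 15, 25, 50, 200 and 500 explicitly; the intermediate sizes are a
configurable choice), with an 11th "all genes" set appended by the caller.

`spearman_age_screen()` is the linear companion: mid-rank Spearman
correlation against numeric age in months, two-sided p from the
t-approximation, a `positive`/`negative` sign call at `alpha = 0.05`, and
no multiple-testing correction (the screen reports raw fractions, as the
analysis it supports does). Constant genes get `rho = 0`, `p = 1`,
`sign = "none"`. `per_tissue_correlation_range()` computes the same
correlation within each tissue and reports max minus min per gene; genes
constant within a tissue contribute rho = 0 rather than dropping out, so
ranges stay comparable across metrics. Range distributions are compared
with one-way ANOVA plus Tukey's HSD; gene-set overlaps are tested with the
upper-tail hypergeometric distribution (the study reports significance
without naming a test; the hypergeometric upper tail is the standard
choice for set overlap).

## The evaluation protocol

`run_evaluation()` repeats, `n_iterations` times (default 100): draw a
random 80/20 train/test split, fit one model family on the training
samples restricted to a gene set, score the held-out samples, and compute
four metrics. Everything derives from one master seed, so results are
reproducible bit-for-bit.

* **Splits** default to stratified by class so every class appears in both
  halves; `split_mode = "plain"` gives the literal simple random split,
  with degenerate draws (a class missing from either half) re-drawn at
  most 100 times.
* **Selection mode.** `"full_data"` mirrors the emulated study's order of
  operations: the ANOVA ranking is computed on all samples before
  splitting. `"within_train"` recomputes the ranking inside every training
  split and is the statistically clean alternative. Both are first-class
  because their difference — selection leakage — is itself a property the
  package tests: on pure-noise data, full-data selection of 500 genes from
  2,000 yields apparent AUC near 1 while within-train selection stays near
  0.5. With 13,000+ genes, two signal-bearing metrics and a real biological
  effect the inflation on real data would be far smaller, but the ordering
  (full-data ≥ within-train) always holds, and readers of accuracy figures
  produced under full-data selection should know which protocol they are
  looking at.
* **Metrics.** One-vs-rest macro-averaged multiclass AUC from the class
  score matrix (rank-based with mid-rank ties, so uninformative scores give
  0.5); macro F1 on argmax predictions; MAE and Spearman correlation
  between encoded predictions and truth. Labels encode as the 0-based class
  index by default — on a five-class clock an MAE of 0.04 is interpretable
  only on the index scale — with months encoding available.
* **Regressors.** LASSO, Elastic Net and the regression tree predict a
  continuous value; `regression_adapter()` converts it to class scores via
  $-|prediction - v_k|$ with a row softmax, predicting the nearest class
  value and resolving exact ties to the lower class. Whether the emulated
  analysis used the same adapter is not stated; this is a comparability
  caveat, not a tuned choice.

### The ten model families

R equivalents of the usual Python stack, library defaults unless noted:

| id | model | implementation |
|----|-------|----------------|
| `logreg` | multinomial logistic regression | glmnet, ridge penalty `lambda = 1/n` (the common default of an L2-regularized logistic solver) |
| `rf` | random forest classifier | randomForest, 500 trees |
| `gnb` | Gaussian naive Bayes | in-package, log-space, variance floor `1e-9` |
| `hist_gbm` | histogram gradient boosting | xgboost, `tree_method = "hist"`, eta 0.1, 100 rounds |
| `reg_gbm` | regularized gradient boosting | xgboost, exact splits, eta 0.3, 100 rounds |
| `adaboost` | multiclass AdaBoost (SAMME) | in-package, 50 weighted-Gini decision stumps |
| `lasso` | L1 linear regression | glmnet, `alpha = 1`, `lambda = 1` |
| `enet` | elastic-net linear regression | glmnet, `alpha = 0.5`, `lambda = 1` |
| `dtree_reg` | decision tree regressor | rpart, fully grown (`cp = 0`, `minsplit = 2`) |
| `dtree_clf` | decision tree classifier | rpart, fully grown |

Gaussian naive Bayes is implemented in the package because products of
hundreds of per-feature densities underflow unless accumulated in log
space. AdaBoost is implemented in the package as discrete SAMME over
decision stumps; stump split ties are broken in random (seeded) order per
boosting round — with many equally good marker features a deterministic
tie-break can lock boosting into a short cycle of identical stumps that
never resolves the multiclass vote. There is no hyperparameter search
anywhere: the emulated protocol reports none.

`evaluate_grid()` runs the full factorial (metrics x gene sets x methods)
and summarizes each method by the maximum of its mean AUC over the gene-set
schedule — the per-method figure-of-merit — plus a tier flag: Tier I
methods peak at the largest ranked set, Tier II methods peak at an interior
size (the boosting families typically do, because their performance decays
once noise genes dominate the input).

## The synthetic generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with a ground-truth manifest for every gene:

* **Design:** 5 ages x 6 tissues x 3 replicates, 2 in the oldest group,
  one young-brain replicate dropped — 83 samples in 30 strata.
* **Lesions:** per gene and sample, $R \sim
  \mathrm{Poisson}\!\left(N \cdot u_{gs} / \sum_g u_{gs}\right)$ with
  $\log u_{gs} = \log(L_g w_g) + s_g \beta a + \gamma 1[\text{marker of }
  t]$, where $a$ is age min-max scaled to $[0,1]$ (so $\beta$ has a
  depth-free log-rate meaning), $s_g \in \{+1, -1, 0\}$ the planted sign
  and $w_g$ a lognormal gene factor. Rates are renormalized per sample to
  the configured depth, like sequencing depth: realized totals concentrate
  on `lesion_depth` and planted effects are compositional, as in real
  libraries. Counts are realized as uniform positions in the gene's exon
  union with random strand, sampled with replacement and deduplicated
  (duplication rate is reported).
* **Expression:** negative binomial with the same planted effects
  (variance $\mu + 0.1\mu^2$ by default).
* **Defaults** (chosen once as realistic study conditions): 2,000 genes of
  1-10 kb with 1-5 exons; 100 planted age genes — 65 positive, 35 negative,
  matching the observation that a sizable minority (~43% for SSB) of
  damage-age correlations are negative; $\beta = 1$ (an $e$-fold rate
  change over the age range); 120 tissue markers (20 per tissue) at
  $\gamma = 3$, the order-of-magnitude specificity typical of strong
  markers; $2 \times 10^5$ lesion positions and $2 \times 10^6$ reads per
  sample.

What the generator does **not** emulate: sequence context, damage hotspots,
chromatin or GC/mappability structure, intronic/intergenic lesions
(positions are placed in exon unions only), correlated genes, batch
effects, or isoform structure. Tests passing on this generator therefore
demonstrate the pipeline's statistical correctness — calibration under the
null, recovery of planted signal, leakage ordering, determinism — not that
real tissue panels will reach any particular accuracy.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere internally; GTF converts at
  the boundary, and chromosome names match by exact string equality.
* A sample with zero total lesion positions is an error when LPKM is
  computed (the density is undefined), as is an all-zero expression column
  for TPM.
* Two constant AUC vectors compare with p = 1 when their means are equal
  (and p = 0 otherwise); a degenerate ANOVA (no variance anywhere) returns
  p = 1.
* `compare_ranges` and the screen treat within-group constancy as rho = 0
  rather than missing, keeping vector lengths aligned across metrics.
* All stochastic steps consume an iteration-specific seed derived from the
  master seed, so any single iteration can be reproduced in isolation.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the full 83-sample design
with the generator defaults. Where an iteration count is part of the
protocol (null-calibration clock) they use 100 iterations; the
leakage-ordering check uses 50 iterations per selection mode over five
seeds, and the ten-method tissue grid uses gene-set sizes
{15, 50, 200, 500} with 30 (tests) or 20 (acceptance script) iterations —
representative subsets of the full schedule chosen so a complete run stays
in the minutes range on one CPU. Mean AUC estimates at these sizes carry a
standard error of roughly 0.01 or less on the strong-signal tasks.

## Known limitations

* Gene-level only: no isoforms, no sub-gene resolution, no non-genic bins.
* The naive TPM is not RSEM; on real RNA-seq the two differ for genes with
  strong isoform switching.
* The regression families predict an arbitrary class index for unordered
  targets (tissue); their AUC through the adapter is structurally
  disadvantaged and peaks at small gene sets.
* `full_data` selection reproduces the emulated protocol and its optimism;
  use `within_train` for honest error estimates on your own data.
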