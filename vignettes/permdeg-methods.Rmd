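---
title: "permdeg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{permdeg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bulk RNA-seq of airway brush samples from COPD cases and healthy controls
poses two statistical problems that standard parametric DE tools handle
poorly. First, brush material is a cell mixture whose composition varies
between patients, so expression distributions are heavy-tailed and
outlier-prone. Second, a biologically real effect may live in only part of
the distribution: if a gene is up-regulated in a cell type present in a
subset of patients, the group *median* barely moves while the *upper
quartile* does. permdeg implements a distribution-shape-aware alternative:
an exact permutation test on quantile differences of TMM-normalized
counts-per-million, plus the downstream machinery (three-criterion DEG
calling, sub-phenotype unique-DEG logic, a mitochondrial signature score
with clustering) needed to run a CT-phenotyped case/control analysis end
to end.

## The statistic and its null

For a gene, let $x_1,\dots,x_{n_1}$ and $y_1,\dots,y_{n_2}$ be the cpm
values of the two groups and $q_\ell(\cdot)$ the level-$\ell$ quantile,
$\ell \in \{0.25, 0.5, 0.75\}$. The test statistic is

$$Y_\ell = \left| q_\ell(x) - q_\ell(y) \right|.$$

Under the null that both groups share one expression distribution, group
labels are exchangeable; the null distribution of $Y_\ell$ is obtained by
re-assigning $n_1$ labels among the $n_1+n_2$ pooled values. The p-value
is the proportion of assignments with $Y_\ell \ge y_{\mathrm{obs}}$. Since
the observed assignment is in the enumerated set, $p \ge 1/\binom{n}{n_1}
> 0$. On binary data with the median statistic this reduces to a
hypergeometric tail — the sense in which the procedure is a
quantile-generalization of Fisher's exact test — and the test suite
asserts this equivalence exhaustively for $n \le 12$.

**Engines.** Full enumeration is used when $\binom{n}{n_1} \le$ `budget`
(default $2\times10^5$ assignments). Beyond that — study-sized groups like
145 vs 50 make enumeration impossible — a seeded Monte-Carlo engine draws
`n_perm` (default $10^5$) assignments and uses the add-one estimator
$p = (1 + \#\{Y \ge y_{\mathrm{obs}}\})/(B+1)$, which is never zero and is
(mildly conservatively) valid. Every result records which engine ran and
with how many assignments.

**Determinism.** The Monte-Carlo engine uses a package-internal
xoshiro256\*\* generator (not R's RNG, whose global state is left
untouched), seeded by a (seed, counter) pair where the counter is the gene
row index. Identical seed and inputs give bit-identical p-values on any
platform, and the per-gene streams are independent of gene iteration
order.

**Ties and degenerate genes.** Permutations are over label assignments to
the pooled *multiset*; ties need no breaking and simply reduce the number
of distinct $Y$ values. A zero-variance gene yields $y_{\mathrm{obs}} = 0$
and $p = 1$; it is retained in the FDR universe (conservative, keeps the
gene count stable across comparisons). Floating-point comparison of
$Y \ge y_{\mathrm{obs}}$ uses a relative guard of $10^{-9}$ so that
permutations reproducing the observed split are never lost to rounding.

**Quantile convention.** The quartile convention is not canonical across
software; permdeg pins linear interpolation between order statistics
($h = \ell(m-1)$, R's type 7 and NumPy's default), so the median of an
even-sized group is the mean of the two middle values. All frozen test
values use this convention.

## Normalization

TMM scaling factors are implemented from the published definition rather
than wrapped: pairwise log2 ratios $M$ and mean log2 abundances $A$
against a reference sample (the one whose upper-quartile count fraction is
closest to the cohort mean), genes with a zero count in either pair
member excluded, the extreme 30% of $M$ and 5% of $A$ trimmed on each
side, and the factor taken as the inverse-variance-weighted mean of the
surviving $M$ values, with the factor vector rescaled to geometric mean 1.
The test suite verifies agreement with edgeR's `calcNormFactors` to
$10^{-8}$ on random fixtures. cpm is
$\mathrm{count}/(\mathrm{libsize}\times\mathrm{factor})\times10^6$ with
library size the raw column sum; zeros stay exactly zero.

One caveat worth stating: because the precision weights depend on
*absolute* counts, multiplying one sample's counts by a constant changes
its weights slightly, so TMM factors are scale-equivariant only
approximately (within ~1% on realistic fixtures; canonical weighted TMM
behaves identically). With fixed factors, cpm equivariance is exact.

Normalization is computed once on the full cohort by default; because
`cpm_normalize` accepts any count matrix, per-comparison renormalization
is a one-line opt-in (pass the subset), which we do not default to since
the factor estimates are better with all samples.

## DEG calling

A gene is called differentially expressed when **one quantile level
simultaneously** satisfies all three criteria: FDR-adjusted permutation
p < 0.05 (strict), absolute quantile difference ≥ 10 cpm, and fold change
≥ 1.5 between the two group quantiles. Evaluating the criteria jointly
per level matters: a gene whose FDR passes at the median but whose 10-cpm
difference is achieved only at q3 is not called.

* **FDR**: Benjamini–Hochberg step-up, applied per quantile level across
  genes (default) with a `joint` option across genes × levels. The
  procedure behind the reported "FDR" is not documented in the source
  analysis; BH is the field default for that column name.
* **Reporting level**: the qualifying level with the smallest FDR, ties
  broken median > upper quartile > lower quartile — an explicit,
  reproducible rule for which cpm pair a table prints.
* **Ratios** are always ≥ 1 with an up/down direction flag; a zero group
  summary reports an infinite ratio rather than failing.
* **Unique sub-phenotype DEGs**: a gene unique to emphysema-dominant
  disease is significant in control-vs-E or control-vs-Eex but in neither
  control-vs-A nor control-vs-Aex, and vice versa; the E and A outputs are
  provably disjoint and each record carries its provenance. Discovery
  combines the three quantile levels as a union.
* **Confirmation concordance** is deliberately descriptive (sign
  agreement of the recomputed group summaries against the same controls),
  not inferential — the confirmation cohort has no matched control group
  of its own.

No minimal-expression pre-filter is applied before testing; the ≥ 10 cpm
difference criterion already removes the low-expression regime, and an
undocumented pre-filter would silently change the FDR universe.

## The mitochondrial signature

The signature score of a sample is the plain sum of cpm over the eight
mitochondria-encoded OXPHOS genes (MT-ND1/2/3/5, MT-CO1/2/3, MT-ATP6).
Group comparisons use a Wilcoxon rank-sum test: exact by enumeration of
rank-sum assignments for combined n ≤ 20 (valid under ties), otherwise the
tie-corrected, continuity-corrected normal approximation.

Clustering of the signature genes uses per-gene z-scoring across the
clustered samples (the row scaling of standard expression heatmaps),
Euclidean distance between samples, complete linkage, and a cut at k = 2;
the cluster with the higher mean score is labelled "high". Metric,
linkage and k are pinned because "unsupervised hierarchical clustering"
alone does not determine a result; they are arguments of record, not
hidden constants. Zero-variance gene rows are dropped with a warning
(z-score undefined); if nothing informative remains, the input is
declared degenerate rather than clustered arbitrarily. Cluster/phenotype
enrichment uses an in-package two-sided Fisher exact test (hypergeometric
tables at most as probable as the observed one). For cohorts without
imaging labels, `extreme_score_samples` selects the top/bottom k samples
by score (default k = 5) for surrogate-marker comparisons such as
TLCO/Va.

Associations: Spearman rho on mid-ranks with an exact enumeration p for
n ≤ 9 (the enumeration doubles as the test oracle) and the t
approximation beyond; covariate links by OLS with BH across the
covariates tested.

qPCR copy-number arithmetic follows the assay definition exactly:
$\mathrm{fold} = 2^{|\mathrm{Ct}_{\mathrm{gene}} -
\mathrm{Ct}_{\mathrm{ref}}|}$, with no amplification-efficiency
correction (none is defined for the assay being modelled), and group
comparisons as plain fold ratios.

## The synthetic cohort: what it is and is not

`simulate_cohort` generates the world the pipeline assumes so every stage
is testable without controlled-access patient data:

* **Counts**: negative binomial with log-normal baseline abundances
  (meanlog log 30 cpm, sdlog 1.5) and per-gene gamma dispersions (shape
  2, mean 0.2 — a standard bulk RNA-seq scale; brush-specific dispersions
  are not published, so this is a stated assumption, not a fit). Library
  sizes are uniform over a configurable range, and sequencing renormalizes
  the perturbed composition to depth, so spike-ins create the
  composition bias TMM exists to fix. Baselines are in cpm units: the
  null-gene baselines are rescaled so the library totals $10^6$, making
  the MT-block and spike-in baselines land on the true cpm scale — the
  null genes stand in for the unmodelled remainder of the transcriptome.
* **Design**: default group sizes mirror the modelled study — males 145
  controls, 50 E-dominant (22 extreme), 32 A-dominant (16 extreme), with
  mixed/normal-CT cases completing 173 male cases; females 73 controls
  and 86 cases at roughly half the male numbers; 53 confirmation cases
  (36 male, 17 female) without imaging labels.
* **Effects**: whole-distribution spike-ins (default 20 genes, fold 4,
  all cases) and upper-tail spike-ins (default 10 genes, fold 4 applied
  to a random 30% of E/Eex males — group median ~unchanged, q3 moved);
  spiked genes get ~100 cpm baselines so the 10-cpm criterion is live.
  The MT block sits at ~10^4 cpm baseline, fold 2 in E/Eex males and in
  40% of confirmation cases.
* **Covariates**: TLCO/Va decreases and TLC increases linearly in the
  z-scored realized signature score (slopes 0.9 and 0.5, noise SD 0.5 and
  0.4); case FEV1/FVC has a mild negative link; control FEV1/FVC is
  uniform above the 0.75 eligibility cut-off.

What the generator does **not** emulate: batch and center effects, RNA
degradation, sex-chromosome expression structure, cell-type deconvolution
(effects are per-gene, not per-cell-type), gene–gene correlation beyond
the MT block, and count sparsity of single-cell data. A green
parameter-recovery test therefore establishes that the pipeline recovers
the effects *this* generative model encodes at study-like sample sizes —
it does not certify performance under confounding the model omits.

## Numerical and scaling choices in the test suite

Enumeration budget 2×10^5 assignments; Monte-Carlo default 10^5
permutations, scaled down to 2×10^4 in the large parameter-recovery
acceptance run (p-value resolution 5×10^-5, far below any BH threshold a
called gene needs there) and to a few thousand in CLI/unit smoke tests.
The null type-I acceptance run uses 200 genes × 30 vs 30 at the full 10^5
permutations. Seeds are fixed a priori in every stochastic test; binomial
99% confidence bands are used where a rate is checked against its nominal
value.

## Known limitations

* Exact enumeration cost grows as $\binom{n}{n_1}$; the engine refuses
  rather than silently degrading, and the Monte-Carlo p has resolution
  $1/(B+1)$.
* Permutation tests assume exchangeability under the null: no covariate
  adjustment, paired designs, or continuous-trait DE within the test
  module (linear associations live in the signature module).
* TMM scale equivariance is approximate under precision weighting (see
  above).
* The clustering contract is deterministic but convention-dependent;
  alternative metrics/linkages are arguments, and results should be read
  as conditional on them.
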