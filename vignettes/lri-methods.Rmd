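---
title: "Ligand-receptor interaction analysis with lriscape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-receptor interaction analysis with lriscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lriscape)
```

# The scientific problem

Cells in a tumor communicate through ligand-receptor interactions (LRIs): a
sender cell secretes or displays a ligand, a receiver cell expresses the
matching receptor. lriscape treats the LR pair — not the gene — as the unit
of analysis and follows it across three levels:

1. **single cells**: how strongly does cell type A talk to cell type B, and
   is that strength more than chance?
2. **bulk cohorts**: do patients cluster into LRI subtypes, do pair scores
   track immune infiltration, and do they predict overall survival?
3. **pseudo-space**: which cells sit at the communication center of the
   tissue, and what distinguishes the cells that have disengaged from it?

All stages run on synthetic data with planted ground truth, so every claim
the package makes is checkable.

# Interaction strength and its permutation null

For an annotated expression matrix (log-normalized,
$x = \ln(1 + c_{g}/c_{\cdot} \cdot 10^4)$) the strength of pair $p =
(L, R)$ from source type $a$ to target type $b$ is

$$ S_{p,a\to b} \;=\; \overline{x_L}^{(a)} \cdot \overline{x_R}^{(b)}, $$

the mean ligand expression in $a$ times the mean receptor expression in
$b$, autocrine entries included. Significance comes from a global label
permutation: cell-type labels are shuffled across all cells (type sizes
preserved) `nPerm` times, the whole tensor is recomputed under each
shuffle, and

$$ p_{p,a\to b} = \frac{1 + \#\{S^{perm} \ge S^{obs}\}}{1 + nPerm}. $$

Choices worth knowing:

* **One shared shuffle set across pairs.** This is both much faster than
  independent shuffles per pair and statistically preferable: the joint
  null retains the cross-pair dependence of the data, so family-wise
  statements over the tensor are honestly calibrated.
* **One-sided, add-one.** Only enrichment is of interest, and the add-one
  convention bounds p away from zero at $1/(nPerm+1)$ — with the default
  `nPerm = 1000`, the smallest reportable p is $1/1001$.
* **Scale.** Single-cell strengths are computed on log-normalized values.
  Library-size log-normalization stands in for variance-stabilizing
  regression deliberately: the strength statistic only needs a monotone,
  cross-cell-comparable scale, and the simpler transform keeps the
  permutation null exact. This is the package's one intentional
  methodological substitution in preprocessing.
* Bulk pair scores are the per-sample product
  $y_{s,p} = x_{L,s} \, x_{R,s}$. Whether $x$ is linear or log scale is an
  explicit `assay` argument, because public bulk cohorts arrive on both
  scales; the package convention downstream is natural-log scale
  (`"logexprs"`), so a pair score is a product of log expressions.

QC filtering keeps cells with $> 1000$ total UMIs, $> 200$ and $< 6000$
detected genes, and $< 5\%$ mitochondrial counts — strict inequalities on
all four rules, mitochondrial fraction computed on raw totals (computing it
after gene filtering would change results only marginally but is a
different contract; the pre-filter total is the documented one).

# The affinity embedding

The spatial module is a deliberately simplified stand-in for full
tissue-reconstruction tools. Affinity between cells $i, j$ is

$$ A_{ij} = \sum_p \big( x_{L_p}(i)\,x_{R_p}(j) + x_{R_p}(i)\,x_{L_p}(j) \big), $$

symmetric with zero diagonal. The row-normalized, symmetrized affinity
becomes a target distribution $P$, and 3-d coordinates minimize
$KL(P \| Q)$ where $Q$ is the Student-t (1 d.f.) kernel on embedded
distances — the t-SNE objective with the affinity supplying the
neighbourhood structure. Gradient descent runs from a seeded random start
with a fixed base learning rate (default 50) that is **halved whenever a
step would increase the objective**; pure fixed-step descent on this
objective can oscillate, and the halving rule makes the recorded objective
trace provably non-increasing while keeping the optimization fully
deterministic per seed. Coordinates are re-centred every iteration, so
"distance from the origin" always means distance from the embedding
centroid.

The far-cell rule defaults to the 95th percentile of distances rather than
an absolute cut: an absolute threshold (the conventional "40 units" on the
original tool's scale) is retained for parity experiments, but embedding
scale is implementation-specific and a percentile rule transfers across
scales. Near/far differential expression within a focus cell type uses a
two-sided rank-sum test with BH adjustment; log2 fold changes are computed
on mean `expm1`-backtransformed expression with pseudocount 1, and
significance requires adjusted $p < 0.05$ **and** $|\log_2 FC| > 0.5$.

What this module does *not* claim: competition for physical space, capacity
constraints, or absolute tissue geometry. Its claims are limited to
*relative* proximity — high-affinity cell pairs end up closer than
low-affinity ones.

# Consensus subtyping

Bulk samples are clustered on z-standardized pair scores (constant pairs
dropped; standardization is on by default and switchable, since product
scores span orders of magnitude across pairs). Each of `nIter = 1000`
iterations subsamples 80% of samples and runs k-means (Euclidean, 10
seeded restarts, best inertia kept) for every candidate k; the consensus
matrix entry is the fraction of co-samplings in which two samples
co-clustered. Final labels are the average-linkage hierarchical cut of
$1 - \text{consensus}$, the conventional finishing step.

Model selection operationalizes the visual CDF criterion as **PAC
minimization**: PAC(k) is the fraction of off-diagonal consensus values
strictly between 0.1 and 0.9, ties broken toward smaller k. The CDF table
is still emitted so the visual criterion can be reproduced by eye. When
even the best PAC exceeds 0.2 the data have no clean block structure and
the selection is flagged low-confidence rather than silently returned.

Marker pairs per subtype come from a one-vs-rest rank-sum test with BH
adjustment within subtype, keeping up-regulated pairs only (adjusted
$p < 0.05$, $\log_2 FC > 0$), ranked by fold change, top 50 kept. A
rank-sum test replaces count-model differential testing here because pair
scores are products of normalized expression, not counts — a
negative-binomial model would be mis-specified for them.

New cohorts are assigned by nearest marker centroid under Spearman
correlation (within-cohort z-standardization first, because Spearman ranks
across pairs and the pairs must be on comparable scales; cohorts with
fewer than three samples use raw scores since standardization is
undefined). Exact ties and undefined correlations yield "unassigned".
Cross-cohort concordance replaces enrichment-based subclass mapping with a
transparent permutation statistic — the mean marker-score difference
between a candidate subtype and the rest of its cohort, nulled by label
permutation, Bonferroni-corrected over all (subtype, subtype) cells with
the conventional 0.05 decision rule.

# The prognostic risk model

The survival chain is univariate screen → LASSO → multivariate Cox →
median split, with every data-derived quantity learned on training data
only:

* **Univariate screen**: per-pair Cox fit on standardized scores (hazard
  ratios per SD), Breslow tie handling (ties are rare in continuous
  follow-up and Breslow keeps the partial likelihood simple), candidates at
  $p < 0.05$.
* **LASSO**: `glmnet` Cox path, 10-fold cross-validation with a seeded
  fold assignment, penalty at the **one-standard-error rule** — the sparser
  of the two conventional choices, preferring a smaller signature at
  equivalent cross-validated fit.
* **Risk score**: unpenalized multivariate Cox on the selected pairs;
  $\text{risk}_s = \sum_p \beta_p z_{s,p}$. The training median is the
  high/low cutoff; validation cohorts are split at the *training* median
  and standardized with the *training* means and SDs, never their own.
* **Evaluation**: Kaplan-Meier curves with the two-group log-rank test;
  IPCW time-dependent AUC at 36 and 60 months (cumulative cases, dynamic
  controls, censoring weights from the Kaplan-Meier estimate of the
  censoring distribution — written in-package since no installed library
  provides it); calibration via the Breslow baseline cumulative hazard,
  $\hat S(t \mid x) = \exp(-\hat H_0(t) e^{\text{risk}})$, against
  within-bin Kaplan-Meier estimates over risk-score quantile bins (empty
  bins merge with a neighbour and are logged).

# What the synthetic generator emulates — and what it does not

The generator exists so that every downstream stage has a known answer.

* **Single cell**: negative-binomial UMI counts, mean `baseMean = 0.5` per
  gene per cell and dispersion 0.5 (variance $\mu + 0.5\mu^2$) — a
  shallow-depth droplet-like regime where most entries are zero. A planted
  interaction $(p, a, b, f)$ sets the ligand's mean to $f \cdot$
  `baseMean` in source-type cells and the receptor's in target-type cells.
  A configurable number of `"MT-"`-prefixed genes exercises the QC rules.
* **Bulk**: log-normal expression, natural-log values
  $\mathcal{N}(2, 0.3^2)$; a subtype shifts *both* genes of each of its
  marker pairs by `markerLogFC` so the product score separates subtypes
  multiplicatively (subtyping operates on pair scores, not genes, so
  planting must act on the pair level). The standard planted cohort used
  throughout testing is n = 150, k = 3, 50 markers per subtype, log-fc
  1.5, noise sd 0.3.
* **Survival**: exponential event times with log-hazard
  $\sum \beta_p z_p$ over the causal pairs and baseline rate 0.02/month
  (median survival near three years, typical of intermediate-stage CRC
  cohorts); censoring is an independent exponential whose rate is
  calibrated numerically so the expected censored fraction matches the
  requested rate.
* **Abundance**: immune cell-type columns are linear in standardized
  driver pair scores plus Gaussian noise with the residual variance set so
  the marginal correlation equals the requested $\rho$, offset and
  truncated at zero.

Not emulated: doublets, ambient RNA, batch effects, realistic gene-gene
correlation, non-proportional hazards, informative censoring. Passing
tests therefore demonstrate that the *methods are implemented correctly
and recover planted structure under their own assumptions* — not that real
cohorts satisfy those assumptions.

# Numerical and design details

* Every stochastic function takes a `seed` and is bit-reproducible per
  seed; the pipeline manifest records each stage's derived seed.
* Permutation p-values can never be zero (add-one convention).
* k-means uses `iter.max = 25` and 10 restarts; consensus entries of
  never-co-sampled sample pairs (possible only at very low `nIter`) are
  defined as 0.
* Tie rules: risk scores equal to the cutoff are low-risk; `selectK` ties
  go to the smaller k; exact assignment-correlation ties are unassigned.
* Degenerate inputs error early with named offenders: zero-total cells in
  normalization, constant pairs in Cox screens (dropped with a warning),
  single-cluster silhouette requests, all-zero affinities.
* Problem sizes in the shipped tests and acceptance script (e.g. 70 cells
  per type for calibration, 150-sample cohorts, `nIter = 200` consensus
  iterations, 20 replicates per Monte-Carlo property) were chosen as the
  smallest sizes at which the targeted properties are stable, keeping the
  whole suite comfortably fast on one CPU.

# Known limitations

* The affinity embedding is a relative-geometry tool only; distances carry
  no physical units.
* Multi-subunit receptor complexes and percent-expressing-cell filters are
  out of scope; an LR reference row is one ligand gene and one receptor
  gene.
* The concordance test assumes the two cohorts' scores are comparable
  after within-cohort standardization; strong batch effects between
  cohorts would need explicit correction upstream.
* Gene matching is exact and case-sensitive; no alias resolution is
  attempted.
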