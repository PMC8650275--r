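# lriscape

Ligand-receptor interaction (LRI) analysis for tumor transcriptomics:
interaction-strength scoring with a permutation null on annotated
single-cell data, LR-pair feature matrices for bulk cohorts, consensus
subtyping with marker-pair signatures and cross-cohort concordance
testing, LR–immune-infiltration association screening, an LRI-affinity 3-d
embedding with far-cell analysis, and a LASSO–Cox prognostic risk score —
plus a synthetic-data generator with planted ground truth that makes every
stage testable end to end.

## Who it is for

Computational biologists who want to go beyond per-gene analysis and treat
the **ligand-receptor pair** as the feature: which cell types talk to each
other, whether patients stratify into communication subtypes, whether
specific pairs track immune infiltration, and whether a compact pair
signature predicts overall survival.

## The core quantities

For cell types $a, b$ and pair $p = (L, R)$ on log-normalized single-cell
expression $x$:

$$ S_{p,a\to b} = \overline{x_L}^{(a)} \cdot \overline{x_R}^{(b)}, \qquad
   p\text{-value} = \frac{1 + \#\{S^{perm} \ge S^{obs}\}}{1 + n_{perm}} $$

with cell-type labels globally shuffled $n_{perm}$ times (default 1000,
one shared shuffle set across pairs). For bulk sample $s$ the pair score
is the within-sample product $y_{s,p} = x_{L,s} x_{R,s}$; subtyping runs
consensus k-means (1000 × 80% subsampling, PAC model selection) on
standardized pair scores, and prognosis fits
$\text{risk}_s = \sum_p \beta_p z_{s,p}$ by univariate screen → LASSO
(one-SE rule) → multivariate Cox, with median-split Kaplan-Meier, IPCW
time-dependent AUC and Breslow-baseline calibration. The methods vignette
(`vignettes/lri-methods.Rmd`) derives and justifies each step.

## Worked example

```r
library(lriscape)

# a synthetic LR reference and an annotated single-cell cohort with one
# planted Tcell -> Epithelial interaction at fold 8
lr  <- generateLRReference(nGenes = 60, nPairs = 25, seed = 1,
                           distinctGenes = TRUE)
planted <- data.frame(pair_id = lr$pair_id[1], source = "Tcell",
                      target = "Epithelial", fold = 8)
sim <- simulateSCCounts(c(Tcell = 150, Myeloid = 150, Epithelial = 150),
                        lr, planted, seed = 2)
sce    <- logNormalize(sim$sce)
tensor <- permutationSignificance(sce, lr, nPerm = 1000, seed = 3)
tensor
#> InteractionTensor: 25 pairs x 3 source types x 3 target types
#>   expression scale: logcounts
#>   permutation p-values from 1000 shuffles (min possible 0.000999 )

strengths(tensor)["G00057:G00058", "Tcell", "Epithelial"]  # planted pair
#> [1] 39.245
pvalues(tensor)["G00057:G00058", "Tcell", "Epithelial"]
#> [1] 0.000999
```

The planted channel carries an interaction strength of 39.2 (the
fold-8 ligand and receptor means multiply) against a null-pair median
near 5, and its permutation p-value sits at the add-one floor
1/1001 — the label shuffle never reproduces it.

```r
# a bulk cohort with 3 planted subtypes and 2 survival-driving pairs
bulk <- simulateBulkCohort(150, lr, kSubtypes = 3, markersPerSubtype = 8,
          markerLogFC = 1.5, noiseSd = 0.3,
          survivalSpec = list(baselineRate = 0.02,
                              causal = data.frame(
                                pair_id = lr$pair_id[c(24, 25)],
                                coef = c(0.8, -0.8)),
                              censorRate = 0.3), seed = 4)
scores <- bulkScores(bulk$se, lr, assay = "logexprs")

cons <- consensusCluster(scores, kRange = 2:5, nIter = 200, seed = 5)
selectK(cons)                     # PAC: k2=0.671 k3=0 k4=0.013 k5=0.122
#> [1] 3
```

PAC (proportion of ambiguous consensus values) collapses to 0 exactly at
the planted k = 3: every pair of samples either always or never
co-clusters.

```r
uni   <- univariateScreen(scores, bulk$survival)
sel   <- lassoSelect(scores, bulk$survival, uni$pair_id[uni$candidate],
                     seed = 6)
model <- fitRiskModel(scores, bulk$survival, sel$selected)
model
#> RiskModel: 4 pairs; cutoff -0.2348
#>            pair coefficient
#> 1 G00015:G00028 -0.07352586
#> 2 G00048:G00019  0.59297487
#> 3 G00038:G00013  0.37050244
#> 4 G00056:G00016 -0.77255271

grp <- stratifyMedian(riskScore(model, scores), riskCutoff(model))
km  <- kmLogrank(bulk$survival, grp)
c(chisq = km$chisq, p = km$p)     # 53.7, 2.3e-13
timeDependentAUC(riskScore(model, scores)[bulk$survival$sample],
                 bulk$survival, 36)
#> [1] 0.86
```

Both planted causal pairs (`G00048:G00019`, `G00056:G00016`) are selected
with the correct signs and dominant magnitudes; the median split separates
survival decisively and the 36-month IPCW AUC is 0.86. The two small
extra coefficients are the usual post-LASSO hitchhikers from the
subtype structure, which confounds the marginal screen exactly as it
would in a real cohort.

An end-to-end run that writes every artifact plus a seed-stamped manifest:

```r
runPipeline(outdir = "lri_out", seed = 1)          # or stages = c(...)
```

or from a shell, `Rscript inst/scripts/lri-pipeline.R --outdir lri_out
--seed 1` (optionally `--config config.yaml`, `--stages simulate,subtype`).

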