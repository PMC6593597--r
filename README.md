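# twiner

Twin-network correlation-based regularization for sparse logistic
regression in R.

## What problem this solves

Given transcriptomic cohorts from **two diseases** (each with tumor and
normal samples), the package identifies a **shared gene signature**:
genes that both discriminate tumor from normal tissue and behave
similarly — in the co-expression sense — in the two diseases. Typical
users are computational biologists comparing related cancers (the
motivating case is two hormone-dependent cancers) who want candidate
common biomarkers rather than two disjoint per-disease signatures.

## The method

Let Σ_A and Σ_B be the gene–gene Pearson correlation matrices of the two
diseases, with σ_j the j-th column (gene j's correlation vector). Each
gene gets an **angular distance**

    d_j = arccos( ⟨σ_j^A, σ_j^B⟩ / (‖σ_j^A‖·‖σ_j^B‖) )

and a penalty factor w_j = d_j / max_k d_k ∈ [0, 1]. Genes whose
correlation patterns nearly coincide across the diseases ("twin" genes)
receive small weights. These factors enter a weighted elastic-net
logistic regression over the pooled cohorts (tumor of either disease =
1, normal = 0):

    minimize  −(1/n)·ℓ(β₀, β) + λ[ α‖w∘β‖₁ + (1−α)‖w∘β‖₂² ]

so twin genes are shrunk less and selected preferentially. With w ≡ 1
this is the ordinary elastic net (EN), which serves as the comparison
arm. Around the estimator the package implements the full protocol:
a 75° angular pre-filter, repeated stratified 75/25 train/test splits
with 10-fold cross-validated λ, consensus signatures (genes selected in
>75% of runs), signed correlation-network export for selected genes,
and survival validation of a signature (Cox fit, median-risk split,
Kaplan–Meier, log-rank). A synthetic two-cohort generator with a planted
twin block provides a fully controlled test bed.

## Worked example

```r
library(twiner)

## two synthetic cohorts: 60 genes (10 "twin", 2x10 disease-specific,
## 30 noise), 3 outcome-driving genes planted in the twin block
sc  <- twinScenario(nA = 60, nB = 60, p = 60, twinSize = 10,
                    specificSize = 10, nSignal = 3)
sim <- generateTwinData(sc, seed = 1)
sim$a
#> ExpressionDataset (cohort A): 60 genes x 60 samples; 38 tumor / 22 normal

res <- twinerAnalysis(sim$a, sim$b, nRuns = 10, cvFolds = 5, baseSeed = 1)
res$weights
#> TwinerWeights: 60 genes; distance 42.4-100.1 deg
length(res$filtered$dropped)
#> [1] 47          # genes at >= 75 degrees removed before modeling
res$stability
#> StabilityResult: 10 runs, alpha=0.9
#>   consensus (freq > 0.75): en=8, twiner=7 genes (7 shared)
res$stability@medians[, c("method", "test_mse", "test_auc_pr", "test_miscl")]
#>   method   test_mse test_auc_pr test_miscl
#> 1     en 0.08985952   0.9772127        3.0
#> 2 twiner 0.08778759   0.9811558        2.5
```

The angular distances separate sharply: the ten twin genes sit near 42°,
disease-specific and noise genes near 90–100°, so the 75° filter keeps
essentially the twin block. Across the ten resampling runs the twiner
arm attains a slightly lower median Brier score (test_mse) and higher
precision–recall AUC with a smaller consensus signature, and the three
planted signal genes are selected in 100% of runs:

```r
f <- selectionFrequency(res$stability)
f[f$gene_id %in% c("g001", "g002", "g003"), ]
#>   gene_id en twiner
#> 1    g001  1      1
#> 2    g002  1      1
#> 3    g003  1      1
```

Downstream, `stratifyAndTest()` validates any signature against
survival data, and `exportSelectedGeneNetwork()` writes the signed
weighted correlation edges among selected genes. A thin command-line
wrapper for shell use lives at `inst/scripts/twiner.R`
(`twiner.R run ...`, `twiner.R simulate ...`).

## Package layout

| Area | Entry points |
| --- | --- |
| Data containers & I/O | `ExpressionDataset()`, `readExpression()`, `preprocessExpression()`, `subsetGenes()`, `mergeCohorts()`, `SurvivalTable()` |
| Twin weights | `correlationProfile()`, `angularDistance()`, `twinerWeights()`, `prefilterByAngle()` |
| Weighted elastic net | `PenaltySpec()`, `fitWeightedEnet()`, `cvLambda()`, `predictProb()`, `kktResiduals()`, `negPenalizedLogLik()` |
| Protocol | `splitTrainTest()`, `runStability()`, `mseClassification()`, `aucPrecisionRecall()`, `misclassificationCount()`, `exportSelectedGeneNetwork()` |
| Survival validation | `stratifyAndTest()`, `riskTable()`, `kmCurves()`, `logrankTest()` |
| Simulation | `twinScenario()`, `generateTwinData()`, `generateSurvival()` |
| One-call pipeline | `twinerAnalysis()` |

The methods vignette (`vignettes/twiner-methods.Rmd`) documents the
model, every tunable default, the numerical choices of the solver, and
what the synthetic test bed does and does not emulate.
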