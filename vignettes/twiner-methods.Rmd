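---
title: "Twin-network regularization: model, protocol and design notes"
author: "twiner package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin-network regularization: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twiner)
```

## The problem

Two diseases that share biology — for instance two hormone-dependent
cancers — are usually analysed separately, each yielding its own gene
signature for discriminating tumor from normal tissue. Genes that behave
*similarly in both* diseases are of particular interest: they point at
shared mechanisms and shared therapeutic targets. The question this
package addresses is how to bias sparse classification toward such
genes without giving up predictive accuracy.

The idea is to compare each gene's *co-expression context* across the
two diseases. Let $\Sigma_A$ and $\Sigma_B$ be the $p \times p$ Pearson
correlation matrices of the two cohorts, and let $\sigma_j^A$,
$\sigma_j^B$ denote gene $j$'s column in each. The dissimilarity of gene
$j$ between the diseases is the angle between those two vectors,

$$d_j = \arccos \frac{\langle \sigma_j^A, \sigma_j^B\rangle}
{\lVert\sigma_j^A\rVert \, \lVert\sigma_j^B\rVert},$$

which depends only on the direction (the *pattern* of correlations), not
on vector magnitude. Genes whose correlation patterns nearly coincide —
"twin" genes — get small angles. Normalizing by the largest distance
gives per-gene penalty factors $w_j = d_j / \max_k d_k \in [0, 1]$.

These factors enter a weighted elastic-net logistic regression for
classifying all samples of both cohorts (tumors of either disease coded
1, normals 0). The solver minimizes

$$-\tfrac1n \, \ell(\beta_0, \beta) + \lambda\left[\alpha \lVert w \circ
\beta\rVert_1 + (1-\alpha)\lVert w \circ \beta\rVert_2^2\right],$$

with $\ell$ the Bernoulli log-likelihood and $\circ$ the elementwise
product. Twin genes (small $w_j$) are shrunk less and therefore
preferentially selected; a gene with $w_j = 0$ is not penalized at all.
With $w \equiv 1$ the model is exactly the standard elastic net, which
serves as the comparison arm everywhere.

Two conventions deserve explicit mention:

* **The weight enters the ridge term squared.** Because $w$ sits inside
  the squared $\ell_2$ norm, the ridge part of the penalty carries
  $w_j^2$. This makes the reparameterization $x_j \mapsto x_j / w_j$,
  $\beta_j \mapsto w_j \beta_j$ exact, which the package exploits as an
  internal cross-check (`method = "rescale"` in `fitWeightedEnet()`).
  Solvers that take "penalty factors" usually multiply *both* terms
  linearly by $w_j$ and halve the ridge term; for the unit-weight case
  the correspondence is exact under the remapping
  $\lambda' = \lambda(2-\alpha)$, $\alpha' = \alpha/(2-\alpha)$, which
  the test suite uses to compare against an independent solver.
* **Penalty factors are used exactly as defined**, without rescaling
  them to sum to $p$ (a convention some solvers apply internally). Such
  a rescaling only shifts the effective $\lambda$ scale, and $\lambda$
  is always chosen by cross-validation here, so gene selection is
  unaffected; keeping the factors untouched makes $w_j$ interpretable
  as a fraction of the maximal angular dissimilarity.

## The estimation machinery

`fitWeightedEnet()` minimizes the objective by cyclic coordinate descent
on the iteratively-reweighted-least-squares quadratic (proximal Newton),
restricted to an ever-active gene set that is grown by full
Karush–Kuhn–Tucker (KKT) sweeps, warm-started along a descending
$\lambda$ path. Numerical choices:

* Convergence requires both a maximal coefficient change below `tol`
  (default `1e-7`) and an exact KKT residual below `10 * tol`; the
  residuals are exposed via `kktResiduals()` so optimality is checkable
  from the outside.
* The IRLS variance weights are floored at `1e-5` and the logistic
  probabilities are evaluated overflow-safely; under complete separation
  the penalized optimum is finite for any $\lambda > 0$ and the solver
  converges to it rather than erroring.
* $\lambda_{\max}$ — the smallest $\lambda$ at which every penalized
  coefficient is zero — is computed from the weighted KKT threshold
  $\max_j |g_j| / (\alpha w_j)$ at the null model; the path is 100
  log-spaced values down to $10^{-3}\lambda_{\max}$ (both configurable).
  The intercept is never penalized.
* `cvLambda()` chooses $\lambda$ by stratified $k$-fold cross-validation
  (default $k = 10$) minimizing the Brier score (`"mse"`) or deviance;
  on ties the largest (sparsest) $\lambda$ wins. Fold labels cycle
  across classes so no fold is empty even when a class is smaller than
  $k$.

## The experimental protocol

`runStability()` mirrors the published protocol: repeated random
stratified 75/25 train/test splits (default 100 runs; both methods share
each run's split, so the comparison is paired), per-run
cross-validated $\lambda$, and per-run metrics — Brier MSE,
precision–recall AUC (preferred over ROC because tumors heavily
outnumber normals), and misclassification counts at cutoff 0.5 with
"$\geq$ is positive". Genes selected in strictly more than 75% of runs
form each method's *consensus signature*; the package also reports the
Venn decomposition (EN-only / twiner-only / shared) and per-gene
selection frequencies. Run $r$ uses seed `baseSeed + r`, so any single
run is re-derivable in isolation.

Protocol choices that the underlying description leaves open, fixed here
as package defaults:

* Splits are stratified by class (unstratified splits can strand the
  small normal class entirely in the training set); a flag disables it.
* "MSE of classification" is read as the Brier score on predicted
  probabilities, the scale on which cross-validation MSE is computed; a
  hard-threshold variant sits behind `hard = TRUE`.
* Correlation matrices are computed on tumor samples only by default
  (`sampleFilter`), since the penalty targets the *disease* correlation
  structure; `"all"` and `"normal_only"` are available.
* The self-correlation entry (identically 1 in both diseases) is
  excluded from each correlation column before the angle is taken
  (`includeSelf = FALSE`), because including it uniformly deflates all
  angles; the literal reading with the full column is available via the
  flag.
* Genes at angular distance $\geq$ 75° are discarded before model
  fitting (strictly-less-than survival rule, threshold configurable);
  weights are *not* renormalized after filtering, since the
  normalization by the maximum distance is defined on the full gene set.
* If every distance is zero the weights all become zero — every gene
  unpenalized — with a loud warning; this is the only limit consistent
  with "smaller distance, smaller penalty".

## Survival validation

`stratifyAndTest()` checks a signature against follow-up data: a Cox
proportional-hazards fit on the signature genes over tumor samples
(Breslow tie handling), dichotomization at the median fitted relative
risk $\exp(X\hat\beta)$ (the exact-median sample goes to the low-risk
group), Kaplan–Meier curves per group, and the two-group log-rank test
against $\chi^2_1$. Signatures of dozens of genes against a few hundred
samples can be ill-conditioned, so a small ridge penalty (default
$10^{-4}$, set 0 to force the unpenalized fit) stabilizes the Cox fit;
the choice of a joint (rather than gene-by-gene) fit is deliberate, as
the signature is meant to act as one risk score.

## The synthetic test bed

`generateTwinData()` draws two cohorts at the *post-preprocessing* scale
(multivariate normal with standard margins), which is faithful because
the modeling pipeline consumes log-transformed, per-gene z-scored
values anyway; a lognormal `mode = "fpkm"` pre-image exists to exercise
`preprocessExpression()` (natural log, pseudo-count 1, sample standard
deviation with $n-1$ — all configurable, none of them canonical).

The default scenario has 300 genes: a twin block of 30 genes,
equicorrelated at $\rho = 0.7$ with the *same* structure in both
cohorts; two disease-specific blocks of 30 genes each, built from signed
one-factor loadings whose signs are flipped for half the genes and whose
within-block order is permuted in cohort B, so their correlation vectors
differ strongly between cohorts by construction; and 210 independent
noise genes. Five twin genes drive the outcome with log-odds 1 per unit
expression around a logistic intercept targeting 70% tumor prevalence.
Cohorts have 150 samples each. The correlation 0.7 is typical of a
tight co-expression module; 0.7 prevalence keeps the class imbalance
qualitatively realistic (tumors dominate) while leaving enough normals
for stratified splits and 10-fold cross-validation at this sample size.
Survival times, when requested, are exponential with rate
$0.1\,e^{x^\top\gamma}$ and exponential censoring at rate 0.05, i.e.
roughly two-thirds of subjects reach the event.

What the generator does *not* emulate: count noise and library-size
effects, heavy-tailed expression, batch structure, and correlation
between blocks. Passing tests therefore demonstrate correctness of the
machinery and recoverability of a planted twin structure under clean
conditions — not performance on real RNA-Seq data.

One property of the default scenario is worth knowing when reading test
output: the planted effects are strong, so on this scenario *both*
methods select the five planted genes in essentially every resampling
run. Selection frequencies then saturate at 1 for both arms and the
methods tie on that statistic; the discriminating observations are the
angular-distance separation (twin genes near 40°, others near 90°), the
pre-filter's behavior, and the planted genes ranking above the 90th
percentile of twiner's selection frequencies.

## Problem sizes used in checks

The shipped tests and the acceptance script run the protocol at reduced
size — typically 20–30 resampling runs on the default scenario and a
60-gene miniature for unit-level checks — so the whole suite completes
in minutes on a single core while exercising every code path at the
spec's stated cohort size (150 samples per cohort, 300 genes).

## Known limitations

* Pearson correlation is the only similarity measure (by design);
  rank-based or partial correlations are out of scope.
* The angular distance treats positive and negative deviations
  symmetrically; two genes whose correlation vectors are exactly
  opposite get the maximal distance of 180°, not a special status.
* `cvLambda()` requires some lasso component ($\alpha > 0$) to define a
  finite $\lambda_{\max}$.
* The Cox validation assumes proportional hazards and independent
  censoring; it is a sanity check of a signature, not a prognostic
  model-building tool.
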