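---
title: "Methods: network module-based prognostic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network module-based prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modsig)
```

## The model

`modsig` searches for prognostic signatures in three stages, only the last
of which is supervised by survival.

**Edge weighting.** A functional interaction (FI) network is a static,
tissue-agnostic graph over gene symbols. Given a genes × samples
expression matrix, every edge whose two genes are measured receives weight
$|r_{gh}|$, the absolute Pearson correlation of the two genes' profiles;
the signed correlation is kept as provenance. Edges with an unmeasured or
constant-expression endpoint are dropped rather than zero-weighted, so the
clustered graph reflects actual coverage. Weights are not thresholded:
filtering happens after clustering, on whole modules.

**Markov clustering.** MCL alternates *expansion* (squaring the
column-stochastic transition matrix, i.e. two-step random-walk mixing) and
*inflation* (elementwise power followed by column renormalization), until
the matrix stops changing. Random walks stay trapped in regions that are
both topologically dense and, through the weights, strongly co-expressed;
inflation sharpens those regions into disjoint clusters. Modules are then
filtered by size ($\ge n$, default 8) and mean intra-module edge weight
($\ge p$, default 0.25, both inclusive), and each surviving module is
summarized per sample by the mean expression of its member genes.

**Supervised principal components.** Each module row of the module ×
sample matrix gets a univariate Cox score $U(0)/\sqrt{I(0)}$ (Breslow
partial likelihood; positive when high module expression accompanies early
events). Modules with $|score| \ge \theta$ are retained, the retained
submatrix is column-centered, and its top right-singular vectors define
component loadings. Training component scores enter per-component Cox
models (coefficient, HR, Wald 95% CI and P). New cohorts are scored by
rebuilding the module matrix from the *training* gene lists, subtracting
the training means, and projecting through the training loadings —
continuous scores for Cox validation, or a two-group split at the stored
training-median cutpoint for Kaplan–Meier analysis (scores exactly at the
cutpoint go to "low"; the high-expression group is read as the risk
group).

Assumptions worth keeping in mind: proportional hazards for every Cox fit;
independent, non-informative censoring; expression already normalized
(typically per-gene z-scores) so that gene rows are comparable within a
cohort; and case-sensitive gene symbols shared between the network and the
expression files.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `inflation` | 5.0 | MCL cluster granularity; larger → smaller, tighter modules (unitless exponent) |
| `min_size` / `min_avg_weight` | 8 / 0.25 | module filters, both inclusive |
| `folds` | 10 | CV folds for the score threshold, stratified by event status |
| `n_thresholds` | 20 | grid resolution over the \|score\| range |
| `n_components` | 3 | principal components fitted and reported |
| `select_components` | 1 | how many leading components the CV selection statistic uses |
| `beta`, `baseline_hazard`, `censor_horizon` | 1, 0.1, 20 | synthetic hazard: rate $= h_0 e^{\beta f}$, uniform censoring (time units) |

## Design choices

Several points were genuinely open; the choices below are the package's
own, and each is switchable.

**MCL self-loops are unit weight.** Before normalization every node gets a
self-loop of weight 1 (`self_loop = "unit"`). The alternative of tying the
loop to the node's largest incident weight (`"max_incident"`) makes weakly
attached nodes sticky: a gene whose only edge is a faint background
correlation gets an equally faint self-loop, so half its transition mass
flows into the neighboring module at every step and the periphery gets
absorbed. Unit loops keep such nodes self-dominant, and planted-module
recovery in the test suite is exact under them. A rescaling consequence:
clique tests use intra-edge weights comparable to 1, since the loop sets
the scale against which edges compete.

**CV selects on the first-component curve over a linear score grid.** The
threshold grid is `n_thresholds` equally spaced *values* between the
smallest and largest absolute score (a quantile grid cannot place a
candidate between the strongest noise feature and a far-stronger signal
feature, so it can never isolate the latter). Each fold is scored by the
held-out partial-likelihood-ratio statistic of Cox fits on the first 1,
2, ..., `n_components` projected components — one CV curve per component
count, and the selection reads the curve for `select_components`
components (default 1). A joint statistic over all components is reported
in the CV table but deliberately not used for selection: every retained
noise feature donates an extra ~1 expected chi-square unit to a joint LR,
biasing it toward noisier thresholds. Ties prefer the smaller threshold
(more features). Inside CV the likelihood-ratio statistic is used because
it is stable in small held-out folds; all *reported* P-values are Wald
tests, and non-converged (monotone-likelihood) fold fits still contribute
their LR value.

**PCA is centered, not variance-scaled.** For module mean-expression rows
over z-scored genes, a tightly co-expressed module has systematically
larger score variance than a loose one — member noise averages out only in
proportion to 1/size — and that variance is informative, so the default
keeps it (`scale_features = FALSE`). For feature matrices on genuinely
different scales, set `scale_features = TRUE` or z-score the module matrix
upstream, which is the appropriate treatment when reusing the machinery on
heterogeneous feature sets.

**Permutation unit.** "Swapping expression values for all genes" is
implemented as permuting gene-row labels over the same matrix rows: each
row keeps its values (and hence its relationship with survival), while the
gene ↔ network correspondence is destroyed — exactly the null needed to
ask whether *module discovery* beats chance. Per permutation the whole
chain (weighting, MCL, filters, per-module Cox) is rerun and the smallest
module P recorded; the observed module's empirical P is the add-one rank
$(r+1)/(n+1)$. A `within_row` mode that also destroys the
expression–survival link is available. On synthetic data the permuted
cohorts usually yield no module passing the correlation filter at all, so
the null concentrates near 1 — informative about discovery specificity,
degenerate as a distribution.

**Cross-platform rescaling** is affine mean/sd matching of module scores
to a reference cohort (a quantile-mapping mode exists for sensitivity
analysis). Cohorts whose endpoint is disease-free rather than overall
survival carry an endpoint tag and are excluded from pooling unless
explicitly admitted.

**Greedy baseline.** The supervised comparator grows a module from every
seed gene, adding the neighbor (within search depth 1 of the module, and
max depth 2 of the seed) that most increases $-\log_{10}$ of the module
mean-expression Cox P, stopping at zero improvement. Module activity is
the plain member mean, consistent with the main pipeline, rather than a
normalized-sum activity score. Its characteristic failure mode — small,
over-fitted high-scoring modules — is visible in the test suite and is
part of why the main pipeline keeps module construction unsupervised.

## Numerical choices

* Cox Newton–Raphson: convergence at max |Δβ| < 1e-8, cap 50 iterations,
  step-halving to keep the likelihood monotone; Breslow tie handling
  throughout (under it, the two-group score test equals the log-rank
  chi-square exactly when event times are untied, which the tests
  exploit); monotone likelihood is flagged, not fatal. Rank-deficient
  designs and <2 events are errors.
* MCL: convergence at max elementwise change < 1e-6, cap 200 iterations;
  entries < 1e-5 pruned after inflation with renormalization; attractor
  assignment by largest column mass, ties to the lexicographically
  smallest attractor gene; module numbering by decreasing size, ties by
  smallest member. Everything is deterministic.
* Degenerate inputs: constant expression rows are excluded from z-scoring
  (logged), drop their edges at weighting, and are unscorable in superpc;
  modules with no internal FI edge have undefined average weight and fail
  the filter; an all-identical score vector cannot be median-split.
* The empirical P estimator never returns 0; the P-value score
  $-\log_{10}$ geometric mean requires P ∈ (0, 1].

## The synthetic generator

`simulate_cohort()` emulates the study conditions every test runs under:
an FI network of planted dense modules (intra-edge probability 0.8) over
an Erdős–Rényi background (0.01); per-module latent factors
$f_m \sim N(0,1)$ with member expression
$\ell f_m + \sqrt{1-\ell^2}\,\varepsilon$ (loading $\ell = 0.8$, so two
members correlate at $\ell^2 = 0.64$ in expectation); survival exponential
with rate $h_0 e^{\beta f}$ for the prognostic module's factor, uniformly
censored. Defaults: 500 genes, 200 samples, five modules of sizes
30/25/20/15/12 with the first prognostic — a signature scale comparable to
the ~30-gene modules this class of method aims at. Because the hazard is
genuinely log-linear in the factor, parameter recovery is well posed.

What the generator does *not* emulate: platform/probe effects, missing
values, correlated background structure, non-proportional hazards, and
covariate confounding. Passing tests therefore demonstrate correctness of
the machinery and recoverability of a planted signal under the stated
model — not clinical performance on real cohorts.

## Problem sizes in the test suite

The suite keeps everything desk-scale: end-to-end recovery uses the
default 500-gene/200-sample cohorts over 20 seeds; supervised-PC recovery
uses 21 planted modules (one prognostic) at 300 genes × 200 samples over
20 seeds plus independent replicates; permutation checks use 99
re-clustering permutations at 100 genes and a 200-cohort null calibration
at 60 genes. The acceptance script reruns the same computations from a
single command-line seed.

## Known limitations

Disjoint (hard) module membership only; no Efron tie handling in the
shipped Cox fit (Breslow everywhere); no time-varying covariates,
stratification, or competing risks; Bonferroni is the only multiplicity
utility; cross-platform harmonization is score-level, not probe-level
(no batch correction). The FI network itself is an input — nothing here
builds one.
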