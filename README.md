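# modsig

Network module-based discovery of prognostic gene signatures from cancer
expression data.

## The problem

Prognostic gene signatures trained by purely supervised search (pick genes
or subnetworks that best separate survivors from non-survivors in one
cohort) are notoriously fragile: they overfit the training series and fail
to replicate on independent patients. `modsig` implements a semi-supervised
alternative built around a static protein **functional interaction (FI)
network**:

1. **Disease-specific weighting.** For every FI edge (g, h) whose genes are
   measured, compute the Pearson correlation r(g, h) of their expression
   profiles and weight the edge by |r|. The generic network becomes a
   disease-specific weighted graph — without ever looking at the outcome.
2. **Module extraction.** Cluster the weighted graph with Markov clustering
   (MCL; expansion = squaring of the column-stochastic transition matrix,
   inflation = elementwise power with renormalization, inflation
   coefficient 5.0). Keep modules with size ≥ 8 and average intra-module
   |r| ≥ 0.25. Each surviving module is summarized per sample by the mean
   expression of its member genes, giving a small modules × samples matrix.
3. **Supervised principal components (superpc).** Score each module by its
   univariate Cox partial-likelihood score statistic U(0)/√I(0), select the
   score threshold by stratified 10-fold cross-validation, and take the
   leading principal components of the retained module rows. The component
   scores are the signature: continuous risk scores for Cox models, or a
   two-group split at the training median for Kaplan–Meier analysis.

Only step 3 sees survival at all, and only through a handful of module
scores — the module structure itself is unsupervised, which is what makes
the signatures replicate across cohorts and platforms.

Supporting machinery includes a from-scratch Cox proportional hazards fit
(Newton–Raphson on the Breslow partial likelihood; HR = exp(β), Wald tests,
95% CI via β ± 1.96·SE), Kaplan–Meier/log-rank, permutation nulls
(gene-label shuffles with full re-clustering, and random network gene
sets), hypergeometric signature-overlap tests, the cross-dataset
−log10-geometric-mean P-value score, affine cross-platform rescaling for
pooled survival analysis, a supervised greedy subnetwork search baseline,
and a synthetic cohort generator with planted prognostic modules.

## Worked example

Simulate a cohort whose FI network contains three dense co-expression
modules (sizes 20/15/12), the first of which drives an exponential hazard
through its latent factor, then run discovery and validate on an
independent replicate:

```r
library(modsig)
cfg <- synthetic_config(n_genes = 200, n_samples = 150,
                        module_sizes = c(20L, 15L, 12L))
sim <- simulate_cohort(cfg, seed = 42)
fit <- modsig(sim$network, sim$expression, seed = 42)
print(fit)
#> modsig fit: 3 filtered modules; threshold 1.630 retains 1 module(s)
#> Per-component Cox (training):
#>       component coef     se    hr ci_low ci_high         p
#> lower         1 1.48 0.1852 4.392  3.055   6.314 1.362e-15

val <- modsig_validate(fit,
  list(replicate = simulate_cohort(cfg, seed = 1042)$expression),
  discrete_component = 1)
print(val$replicate$component_cox)
#>       component      coef        se       hr  ci_low  ci_high            p
#> lower         1 0.9778845 0.1750796 2.658825 1.88651 3.747318 2.332034e-08
print(val$replicate$km)
#> Kaplan-Meier / log-rank: chi2 = 15.53 (df = 1), p = 8.124e-05
#>      observed expected
#> high       56    37.66
#> low        35    53.34
```

Reading the output: cross-validation picked the module-score threshold
1.63, retaining exactly the planted prognostic module; on the training
cohort one unit of the first component multiplies the hazard by 4.4. On a
fully independent replicate the same frozen model still gives HR 2.66 per
unit (Wald P = 2.3e-08), and splitting the replicate at the *training*
median separates survival curves at log-rank P = 8.1e-05 — high module
expression is the high-risk group (56 deaths observed vs 37.7 expected).

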