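# dartnet

Single-sample molecular pathway activity inference with prior-knowledge
denoising, for transcriptomics researchers who score curated pathway
signatures (e.g. perturbation signatures or pathway-database up/down gene
modules) against tumour expression cohorts.

## The problem and the method

A pathway signature is a list of genes annotated with the sign of their
expected regulation upon pathway activation: σᵢ = +1 (up) or −1 (down). The
naive estimator of per-sample activity is the signed average of z-scored
expression over all signature genes,

    s_AV(s) = (1/M) Σᵢ σᵢ z_is                         (unpruned: UPR-AV)

But prior information gathered in one biological context (a cell line, a
curated database) is partly irrelevant in another (a primary tumour cohort),
and irrelevant genes add pure noise to the average. `dartnet` filters the
prior against the data before scoring:

1. **Relevance network.** Compute Pearson correlations c_ij between all
   signature-gene pairs; transform with Fisher's z, y_ij = ½·log((1+c)/(1−c)),
   which is null-distributed as Normal(0, 1/√(n_S−3)); keep as edges the pairs
   with p ≤ 10⁻⁴ (a threshold at which Monte-Carlo permutation of each gene's
   profile yields well under one false-positive edge per run at genome scale;
   `fdr_calibrated_threshold()` applies the same rule to any pathway size).
2. **Consistency test.** Each edge's observed correlation sign is compared
   with the prior prediction σᵢσⱼ; the fraction of consistent edges is tested
   against a binomial randomization null with the positive-sign probability
   estimated from the data. Signatures that fail this test are flagged — their
   activity estimates are not trustworthy in this cohort.
3. **Pruning.** Inconsistent edges are removed and the largest connected
   component of the remaining network is extracted (pruned average over its
   genes: PR-AV).
4. **Hub-weighted activity.** The denoised estimate weights each component
   gene by its degree kᵢ — correlation hubs are the most reliable pathway
   markers:

       s_WAV(s) = (1/√(Σᵢ kᵢ²)) Σᵢ σᵢ kᵢ z_is          (DART)

   The normalisation makes the score unit-variance for independent
   unit-variance inputs.

The package also ships the synthetic benchmark generators (`simset1()`,
`simset2()`: 24 genes × 100 samples, 40 inactive samples, three activity
levels, faithful genes at σ = 0.25 vs noisy at σ = 3), a variational-Bayes
1-D Gaussian mixture (`vb_cluster_1d()`) for objective cluster-based
evaluation with ground-state accuracy, permutation/t-test phenotype
associations, and the cross-cohort V-score for validating inter-pathway
correlations.

## Worked example

Simulate the hard scenario (only 3 of 24 signature genes faithfully track the
pathway, 3 more carry the pattern buried in noise, 18 are pure noise), then
denoise and score:

```r
library(dartnet)

sim <- simset2(seed = 1)
fit <- run_dart(sim$expression, sim$signature,
                methods = c("DART", "PR-AV", "UPR-AV"), seed = 1)
fit
#> Denoised pathway activity fit
#> Relevance network: 24 nodes, 3 edge(s) at p <= 0.0001 (unpruned), n_S = 100
#> Consistency: 1.000 over 3 edge(s); randomization p = 0 (1000 draws, Pr[+] = 1.000)
#> Pruned component: 3 of 24 network gene(s), 3 consistent edge(s)
#> Activity: 100 sample(s) x 3 method(s)

hub_ranking(fit$component)
#> # A tibble: 3 × 3
#>   gene  degree prior_sign
#> 1 g01        2          1
#> 2 g02        2          1
#> 3 g03        2          1
```

The network step recovered exactly the three faithful genes (g01–g03), all
pairwise connected and consistent with the all-up prior. Clustering the
activity profiles and scoring against the simulation truth:

```r
dart_scores <- dplyr::filter(tidy(fit), method == "DART")
cl <- vb_cluster_1d(dart_scores, seed = 1)
cl
#> VB mixture: 2 effective component(s); ground state mean -1.468
ground_state_accuracy(cl, sim$truth)
#> [1] 0.99

upr <- dplyr::filter(tidy(fit), method == "UPR-AV")
ground_state_accuracy(vb_cluster_1d(upr, seed = 1), sim$truth)
#> [1] 0.43
```

Denoising lifts the accuracy of separating truly active from inactive samples
from 0.43 (naive average over all 24 genes) to 0.99. A full benchmark over
100 replicates, with paired Wilcoxon method comparisons, is
`benchmark_simulation("simset2", n_reps = 100, seed = 1)`; see the methods
vignette (`vignettes/pathway-denoising.Rmd`) for the model, parameter and
design discussion.

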