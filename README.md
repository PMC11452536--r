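# SpotShapley

Does the quality of slide preparation and imaging matter more than the
model when inferring spatial gene expression from tissue morphology —
and is the better protocol worth its price? `SpotShapley` is an R
package for answering that question with game-theoretic data valuation.
It targets analysts working with Visium-style spatial transcriptomics
who train image-based expression predictors and need to decide, slide
by slide, whether a higher-quality (automated-staining,
high-resolution) acquisition protocol pays for itself relative to a
traditional (manual-staining, low-resolution) one.

## What it computes

**Spot-level inference.** Each Visium spot (55 µm diameter, 100 µm
center-to-center pitch on a hexagonal-offset lattice) yields an image
patch centered on the spot and two prediction targets per gene: the
continuous target `log(count + 1)` and a binary low/high label from
per-gene median dichotomization. A pluggable predictor — here a
deterministic reference backend of per-channel patch statistics feeding
per-gene ridge (continuous) and ridge-logistic (binary) heads — maps
patches to expression, including superresolution inference on
overlapping windows at sub-pitch stride.

**Four-part evaluation.** Per-gene AUC (binary) and Spearman
correlation (continuous), macro-averaged with 95% confidence intervals
from a non-parametric spot bootstrap; cluster recovery, the fraction of
predicted spots whose k-NN-assigned cluster (from ground-truth
embeddings) matches their true cluster (k = 3 and 5); and a
differential-expression localization shift, the median percentage
change of tumor-interface Mann–Whitney U statistics between true and
predicted expression over the best-predicted genes.

**Data-Shapley valuation.** Each training slide *i* is valued by its
data Shapley value

φᵢ = (1/n!) Σ_π [ V(S_π^i ∪ {i}) − V(S_π^i) ],

the average marginal change in the value function V — the validation
slide's macro AUC of models trained on a slide subset — when slide *i*
joins a random coalition (V(∅) = 0.5, chance AUC). Both the exact
subset-weighted computation (memoized, for small cohorts) and Monte
Carlo permutation sampling with standard errors and optional truncation
are provided. φ is set against a per-slide assay cost model (base +
per-spot + labor + sequencing, protocol-specific) to give
Shapley-to-cost ratios, with Mann–Whitney / rank-biserial comparisons
between protocols.

**Synthetic cohorts.** Because matched clinical slide sets are rarely
shareable, a seeded generator reproduces the study conditions: latent
tissue regions (tumor / interface / distal), spatially autocorrelated
expression programs driving negative-binomial counts, paired serial
sections, two-patient capture areas, and two image-quality regimes that
differ in noise, stain variability, signal gain, artifact rate and
resolution.

## Worked example

```r
library(SpotShapley)

coh <- generateCohort(cohortConfig(seed = 42, genes = 20, captureMm = 1.6,
                                   nTrainingSlidesPerProtocol = 2))
train <- cohortSlides(coh, "train")
val   <- cohortSlides(coh, "validation")

fit    <- trainGeneModels(train[c("train_enh_01", "train_enh_02")], seed = 1)
report <- evaluateModels(fit, val$val_enhanced, nBoot = 200, topN = 20, seed = 1)
report
#> EvalReport: trained on [train_enh_01,train_enh_02], evaluated on 'val_enhanced'
#>   macro AUC      mean 0.946 [0.939, 0.953]  median 0.948
#>   macro Spearman mean 0.902 [0.891, 0.909]  median 0.903
#>   recovery: k3=0.786, k5=0.789
#>   DE localization shift: -0.52% [-3.60, 2.64]
```

Models trained on the two enhanced-protocol slides discriminate
low/high expression on the enhanced validation section at macro AUC
0.95 (bootstrap 95% CI in brackets), correlate with continuous
expression at Spearman 0.90, place 79% of predicted spots back in their
true expression cluster, and shift the tumor-interface localization
statistic by only −0.5% (CI spanning 0, i.e. no systematic loss of
regional contrast).

```r
v <- valuateCohort(coh, seed = 1)
aggregate(phi ~ protocol + validation, v@table, median)
#>      protocol  validation     phi
#> 1    enhanced    enhanced  0.2003
#> 2 traditional    enhanced  0.0069
#> 3    enhanced traditional -0.0259
#> 4 traditional traditional  0.0843
```

Validating on the enhanced serial section, the median enhanced training
slide contributes +0.200 AUC versus +0.007 for a traditional slide; on
the traditional serial section the direction reverses. The
`comparisons` slot reports Mann–Whitney U, rank-biserial r and exact
p-values for cost, φ and φ/cost contrasts (in `compareGroups()`'s
convention, r = 1 − 2U/(n₁n₂) with U counting first-group wins, so
positive r means the second-named group tends larger).

Slides round-trip through standard Visium-dialect files
(`writeVisiumBundle()` / `readVisiumBundle()`: Matrix Market counts,
features/barcodes TSV, `tissue_positions.csv`), and
`runExperiment()` drives the full 3 training regimes × 2 validation
sections design, writing TSV/JSON reports.

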