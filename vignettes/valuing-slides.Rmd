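---
title: "Valuing training slides for expression inference from morphology"
author: "SpotShapley"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing training slides for expression inference from morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpotShapley)
```

## The problem

Deep-learning models can infer spot-level spatial transcriptomics (ST)
from H&E morphology alone, which would let expression maps be read off
archival slides at a fraction of assay cost. How well this works
depends not only on the model but on how the training slides were
prepared and imaged: manual staining with low-resolution scanning
("traditional" protocol) versus automated staining with
clinical-grade 40x scanning ("enhanced" protocol). `SpotShapley`
quantifies that dependence with slide-level data-Shapley valuation and
sets the algorithmic value of each slide against its assay cost.

This vignette documents the models, their assumptions, and every
numerical choice a maintainer might want to revisit.

## Spot geometry

Visium spots sit on a hexagonal-offset lattice: odd array rows shifted
half a pitch, rows spaced `pitch * sqrt(3)/2` apart, so nearest
neighbors are one pitch (default 100 µm) apart in all directions. Spot
centers in the half-open square `[0, capture)` are kept; with a 6.5 mm
capture area this yields `r nSpots(buildSpotGrid(6.5))` spots,
consistent with the platform's "up to 5000". Conventions chosen for
exact round trips: 0-based, row-major, pixel-center coordinates;
half-open patch windows `[c - p/2, c + p/2)`; pixel positions are
micron positions divided by the resolution, so rescaling resolution
never changes the spot set. Fixed magnification mappings: 40x = 0.25
µm/px, 20x = 0.5 µm/px. Border spots are reflect-padded by default and
flagged per spot, because real pipelines must either pad or drop and
silent dropping hides errors; `pad = "none"` records a per-spot error
instead.

## The synthetic cohort generator

No public data accompany the study design this package operationalizes
(clinical ST cohorts are rarely shareable), so the generator is a
first-class, tested module that reproduces the *statistical structure*
the analysis assumes, not the appearance of H&E tissue.

**Tissue fields.** Tumor regions are connected blobs grown from random
foci (default 2, separated by at least 3 pitches); single-spot holes
are filled so the interface — the non-tumor spots adjacent to tumor —
always touches both tumor and non-tumor; the remainder is distal.
Latent expression programs (default P = 4) are neighbor-smoothed
Gaussian fields, standardized and offset by region (+1.2 on a cycling
program-region assignment), giving each program positive spatial
autocorrelation and each region a distinct signature.

**Counts.** A P x G weight matrix (each gene loading mainly on one
program, sign random, plus dense N(0, 0.1) background) maps programs to
genes; the log-mean of gene g at spot s is a per-slide offset plus
`(loadings %*% weights)[s, g]`, with the offset set so the average
spot's total equals `librarySizeMean` (default 10,000). Counts are
negative binomial with size (theta) `nbDispersion` (default 10;
variance `mu + mu^2/theta`, approaching Poisson as theta grows). The
log-mean is thus exactly linear in the latent loadings, which makes the
noise-free ceiling of a linear readout analytically attainable — the
property the predictor tests rely on. Within a cohort all slides share
one weight matrix (one organism-level gene-program map); each tissue
section gets its own field.

**Imaging.** A patch's noise-free per-channel mean is
`0.5 + 0.08 * signalGain * A %*% loadings`, clamped to [0.02, 0.98],
where `A` is a fixed orthonormal 6 x P channel-mixing basis derived
deterministically from the protocol name. Two deliberate choices here:

* *Protocol-specific bases.* The two protocols encode the same latent
  signal through different stain/color responses. A predictor
  calibrated to one basis transfers imperfectly to the other, which is
  what lets matched-protocol training data be worth more — the
  mechanism behind the directional findings below. With a shared basis,
  rank-based metrics would be blind to everything except noise levels.
* *Noise with a patch-level component.* Additive noise is i.i.d. per
  pixel (sd `pixelNoiseSd`) plus a patch-level DC term (sd
  `pixelNoiseSd / 2`). Pure pixel-level noise would average away over
  the ~10^2-10^3 pixels of a capture mask and make protocols nearly
  indistinguishable at the feature level; the DC term models
  low-frequency variation (focus, illumination, section thickness)
  that does not average out.

Per-slide stain shifts (channel offsets, sd `stainVariability`) and
per-spot occluding artifact blocks (probability `artifactRate`,
constant-value square of 40% patch side) complete the quality model.
Defaults encode the quality contrast — traditional: noise 0.15, stain
0.08, gain 0.55, artifacts 12%, 4 µm/px rendering; enhanced: noise
0.05, stain 0.02, gain 0.90, artifacts 2%, 2 µm/px — chosen once so
that the traditional regime is clearly degraded but far from
uninformative. Rendering resolutions are desk-scale stand-ins that
preserve the 2x resolution advantage while keeping patches small.

**What the generator does not emulate:** nuclei, texture, realistic
H&E color, fresh-frozen artifacts, sequencing reads, batch effects, or
biological morphology-expression coupling (the link here is linear by
construction). Passing tests therefore certify the *pipeline* —
geometry, metrics, valuation, and the qualitative effect of
protocol-quality differences under a known signal model — not
performance on real tissue.

**Cohort design.** `generateCohort()` mirrors the study template: 4
traditional training slides (one patient each), 4 enhanced training
slides (two patients each, capture area scaled by sqrt(2), split at the
vertical midline with independent fields), and one held-out serial
pair — two sections of one block sharing a tissue field, rendered under
the two protocols, the second section's loadings jittered by
`serialPairJitter`. The drift magnitude between serial sections is not
characterized anywhere we could anchor it; the default 0.05 (5% of the
loading scale) is a deliberately mild, exposed choice. Default
single-patient capture areas are 2.8 mm (~920 spots), scaled down from
6.5 mm so a full valuation stays desk-sized; all sub-seeds derive from
the master seed by fixed offsets.

## Predictors

The reference backend featurizes each spot patch as per-channel mean,
sd, and 25/50/75% quantiles inside the circular capture mask (the spot
diameter at the slide's resolution, capped at the patch size), then
fits per gene: a ridge head minimizing MSE on `log1p` counts, and a
ridge-logistic head on median-dichotomized labels (strictly greater
than the median; ties at the median are class 0, a convention the
data would otherwise leave ambiguous). The ridge penalty scales with n,
so duplicated training data leave fits unchanged — a property the
valuation sanity tests use. An internal validation split (10% of spots,
stratified by slide, seeded) picks the penalty from a small fixed grid
`10^(-4..-1)`; the final fit uses all spots. Genes whose labels are
single-class are flagged untrainable and excluded from macro binary
metrics. A deep featurizer can replace the reference one behind the
same interface (patch -> feature vector); nothing downstream changes.

Spatially variable genes are ranked by Moran's I of `log1p` counts
under row-standardized nearest-neighbor weights. On the hexagonal
lattice the six nearest neighbors are exactly the spots within one
pitch, so adjacency (cutoff 1.05 x pitch) realizes the k = 6
neighborhood without the distance ties that make a strict k-NN rule
ill-defined on a lattice; border spots simply have fewer neighbors.
Zero-variance genes take I = 0 and rank last; ties break by gene id.

## Evaluation

* **AUC** is rank-based (midranks for ties), identical to
  `U / (n1 * n0)`; **Spearman** is Pearson on midranks. Both are
  verified against brute-force pair-counting / rank-then-Pearson
  oracles.
* **Macro averages** are arithmetic means over genes; because summary
  tables in this literature often report medians, both are emitted.
  95% CIs come from a non-parametric bootstrap over spots (resampling
  spots, recomputing the macro; 2.5/97.5 percentiles). Genes that turn
  degenerate within a replicate are skipped in that replicate.
* **Cluster recovery.** Ground-truth clusters are k-means (k = 5
  default, seeded, 10 restarts) on 20 principal components of
  log-normalized expression — the simplest reproducible choice, since
  no clustering algorithm is canonical here. The joint embedding
  backend is a truth-fit PCA basis applied to both matrices
  (deterministic and alignment-free); an aligned-UMAP wrapper can be
  plugged in through the same interface. The k-NN vote is
  inverse-distance weighted so that a predicted spot coinciding with
  its truth spot recovers that label exactly — the identity
  `recovery(truth, truth) = 1` would not hold under plain majority
  voting at cluster boundaries.
* **Mann-Whitney U** uses the exact null distribution for tie-free
  groups with min(n) <= 8 and the tie-corrected normal approximation
  (with continuity correction) otherwise.
* **DE localization shift** contrasts interface spots against all
  others per gene (continuous expression), on truth and predictions,
  over the top 200 genes by truth-prediction Spearman; the per-gene
  percentage change `100 (U_pred - U_truth)/U_truth` is summarized by
  its median with a spot-bootstrap CI. Genes with `U_truth = 0` (an
  undefined denominator) are excluded with a recorded reason.

## Valuation

The value function `V(S)` is the validation slide's macro AUC of
predictors trained on subset S, with `V(empty) = 0.5` (chance AUC — the
natural baseline; configurable). Subset fits use the continuous ridge
head and score AUC from its predictions against the validation slide's
median-dichotomized labels: AUC is rank-based, so any monotone score is
valid, and ridge admits per-slide sufficient statistics (X'X, X'y) that
make every subset fit a small linear solve. That is what keeps exact
Shapley — all 2^n memoized coalitions via the subset-weighted form —
affordable at the cohort's n = 8, where it simply supersedes Monte
Carlo sampling (which exists for larger n, reports per-slide standard
errors, is validated against the exact values, and offers optional
truncated-permutation evaluation, off by default with 200 permutations
when used). Efficiency (`sum phi = V(full) - V(empty)`), the null-player
and symmetry axioms are enforced by tests at 1e-10.

Costs are `base(protocol) + perSpot * spots + labor(protocol) +
sequencing(protocol)`. Real assay prices are not public; the defaults
are labeled synthetic placeholders (traditional 1300/450/600, enhanced
800/150/600, 0.05 per spot) chosen once so a traditional capture area
(manual handling, one patient) costs more than an enhanced one hosting
two patients — the cost direction the comparison design assumes. Every
cost-dependent output carries the cost-model label.

Protocol comparisons report U, rank-biserial `r = 1 - 2U/(n1 n2)` and
two-sided exact p for: costs, phi per validation slide, and phi/cost
ratios. Note the sign convention carried in every output: with U
counting first-group wins, complete separation with the first group
below the second gives r = +1, i.e. positive r means the *second*-named
group tends larger.

## Problem sizes and runtime choices

The package's own test and reproduction runs use: cohorts of 4 + 4
training slides at ~920 spots (traditional) and ~1840 spots
(enhanced, two patients) with G = 50 genes; exact Shapley over 2^8
coalitions per validation slide; 10 cohort seeds for the directional
checks (6 in the acceptance script); bootstrap CIs at 200 replicates
in reproduction runs (the evaluation default is 1000); and coverage
checks at 100 simulations x 200 replicates. These sizes were chosen so
a complete reproduction runs on a single CPU in minutes while leaving
every statistical property testable.

## Known limitations

* The morphology-expression link is linear and noise-free at gain 1;
  real coupling is biological, nonlinear, and weaker. Absolute metric
  levels on synthetic cohorts are therefore optimistic and only
  directions/contrasts are meaningful.
* The reference featurizer ignores texture entirely; it is a stand-in
  interface for a deep backend, not a competitive predictor.
* Exact SpatialDE-style gene selection and aligned UMAP are out of
  scope; Moran's I ranking and truth-fit PCA stand behind the same
  interfaces.
* Serial-section drift, cost parameters, and artifact geometry are
  stylized single-parameter models.
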