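---
title: "Methods: from fruit cross-sections to trait-relevant morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from fruit cross-sections to trait-relevant morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`citrusect` links two sensorily scored citrus fruit quality traits —
easiness of peeling (Peeling) and fruit hardness (FruH), both scored by
breeders on a 1–5 ordinal scale — to quantitative morphology measured on
fruit cross-section images. This vignette documents the models, the
tunable parameters and their defaults, the design choices made where the
design was genuinely open, and what the tests do and do not establish.

## The synthetic world

Real scanner datasets of this kind (hundreds of varieties, several years,
breeder scores) are rarely public, so the package ships a parametric
generator whose outputs carry exact ground truth. A `fruit_spec()` draws a
cross-section as concentric rings around a jittered elliptical outline:

* `fruit_radius` (default 0.675 of the half image side) — fruit size;
  the prior range 0.55–0.8 spans roughly a two-fold area variation,
  typical for a diverse citrus panel.
* `flavedo_thickness` 0.08, `albedo_thickness` 0.10, `center_radius` 0.22
  — all as fractions of the fruit radius. Ring boundaries are defined on
  the jitter-normalized radius, so configured *area fractions* are exact
  up to rasterization regardless of outline jitter and ellipticity.
* `locule_count` 10 flesh segments separated by `septum_angle` 4° septa;
  `seed_count` 6 seeds placed inside locules (radially oriented ellipses,
  clipped to the flesh band so they can never overlap septa or peel).
* `degcenter_frac` 0.02 and `degalbedo_frac` 0.01 — target areas of the
  central-core cavity and of albedo gaps, as fractions of whole area.
* colors: near-black background (scanner-like); cavity, septa and
  degradation share one near-white color, so "degradation" is
  operationally the non-flesh, non-peel white inside Center/Albedo. This
  makes an otherwise unpublished degradation-area concept measurable.

Population structure: each genotype receives a latent spec from uniform
priors; each fruit jitters multiplicatively around it (relative SD 0.03);
each year multiplies the degradation fractions (×0.8 / ×1.25) and the
fruit radius (×0.98 / ×1.02). The year effect is deliberately injected
only there so the BLUP stage has a known effect to remove.

Trait scores follow a linear generative model on ground-truth features:
score = intercept + Σ coef·feature + genotype effect (SD 0.3) + year
effect (−0.2 / +0.2) + residual (SD 0.3), cut into five ordinal classes at
1.5/2.5/3.5/4.5. Coefficients were fixed once, before any test was run, so
that each term contributes an effect of plausible magnitude on the 1–5
scale given the prior ranges (e.g. DegCenter area spans ≈0–0.06, so its
coefficient −35 yields an effect SD ≈0.6): Peeling ← −35·DegCenter area
−25·DegAlbedo area +6·Whole area; FruH ← −35·DegCenter area +30·Seed area
+6·Flavedo area +5·Whole area. Signs encode the biology the analysis
should recover: core/albedo degradation (peel puffing) eases peeling and
softens fruit; seeds and thick flavedo harden it; bigger fruit are harder
and harder to peel.

Binary classes: the deposited labeling rule for the original data is not
public. Default: continuous score below the population median → easy/soft.
An optional two-threshold variant (lower/upper 40% quantiles, middles
dropped) exists, but the default keeps middles because misclassification
of mid-range fruit is an expected, realistic phenomenon.

**What the generator does not emulate:** illumination gradients,
off-center fruit, touching fruit on multi-fruit scan sheets, texture
within tissues, non-elliptical outlines beyond low-order sinusoids, and
color variation within a region beyond white noise. A green segmentation
or XAI test therefore establishes correctness of the algorithms on
well-posed scenes, not robustness to real scanner pathology.

## Segmentation

All rules operate in CIE L\*a\*b\* (D65, 2°, own converter verified
against an independent implementation to 10⁻³). Whole = largest
above-luminance component, holes filled. Flavedo = high-a\* (≥33) outer
tissue. Albedo and Center are both bright low-a\* tissue; they are
disconnected components (the flesh ring separates them) and are told apart
by mean normalized radius (≥0.55 → albedo). Seeds are yellowish (b\*≥25),
below-albedo lightness, compact components. Cavity-colored components
(L\*≥96.5, chroma ≤8) are assigned DegAlbedo if they lie radially within
the albedo band, DegCenter if within the core disc, septum otherwise.
Every threshold lives in `segmentation_config()`. Components smaller than
`min_size` (25 px) are dropped. Undetectable regions come back as all-zero
masks — never an error — so feature extraction applies the set-to-0 rule.

## Feature extraction

* **Perimeter / circularity.** Raw pixel-edge counting biases circularity
  low, so the boundary is traced as the 0.5 marching-squares iso-contour
  and smoothed with a circular moving average (half-width 3) before
  measuring length. Calibration on digital shapes: disc ≈0.996, square
  ≈0.796 (ideal π/4 ≈0.785), 2:1 ellipse ≈0.838 (ideal ≈0.841).
  Circularity is clipped at 1.05.
* **Radius** = √(Area/π) (equivalent-circle radius; the source material
  does not define it).
* **Locule angle** is read as the *mean* per-locule central angle; a
  `total` option exists because the singular noun is ambiguous. Angles are
  the circular extent (360 minus the largest gap of member-pixel polar
  angles), robust to the locule wrapping across 0°. Variance is the
  population (divide-by-n) variance.
* **Albedo thickness**: mean radial extent over 72 angular bins, +0.5 px
  discretization correction, divided by Radius.
* Area features are fractions of whole area; `Whole area` itself is the
  fraction of image pixels, which makes all normalized features invariant
  under resolution doubling (tested).

## Year adjustment (REML/BLUP)

One random effect means the REML likelihood can be profiled down to the
variance ratio λ = σ²g/σ²e and optimized in one dimension — exact,
dependency-light and easily testable against both a balanced-design closed
form and an independent mixed-model implementation (agreement ≈10⁻⁸ and
≈10⁻⁵ respectively in the tests). Ordinal trait scores are treated as
numeric, as is standard for this analysis. Expected genotype values are
the fixed-effect mean (averaged over years) plus the BLUP. Boundary fits
pin σ²g at 0 with a warning; single-year data drop the year effect with a
warning.

## Association battery

* **Collinearity filter** (|r| ≥ 0.95, greedy on the currently worst
  pair). Default tie-break is deterministic — drop the member with the
  larger mean |r| to all remaining features — because reproducibility
  matters more here than mimicking the original random selection; a
  `random` policy reproduces that behavior under a seed.
* **MLR** is OLS on z-scored features so coefficient magnitudes are
  comparable across features; raw-scale coefficients are also returned.
  Significance: two-sided coefficient t-tests (the original figure's
  asterisks are not further specified).
* **Random forest**: 500 CART trees, mtry = p/3, minimum node size 5,
  implemented in Rcpp with R's RNG so everything is seed-reproducible.
  Importance is OOB permutation importance. The shadow-feature procedure
  appends permuted copies of all undecided features, scores a "hit" when a
  real feature beats the best shadow, and decides by a two-sided binomial
  test at α = 0.05 — features need enough iterations to accumulate
  significance, so short runs leave more "tentative" features.
* **Interactions**: full iteratively reweighted forests are out of scope;
  the surrogate scores each feature pair by the fraction of
  root-to-leaf decision paths ending in large leaves (≥2% of samples) on
  which both features split, averaged over trees.
* **Cross-validation**: 10-fold × 5 repeats, identical partitions shared
  by both models within a repeat; metrics are out-of-fold Pearson r and
  RMSE; models are compared by a paired t-test across the five repeat
  means (the comparison test in the original table is unnamed).
* **Partial correlations** via the inverse correlation matrix,
  ρᵢⱼ·rest = −Ωᵢⱼ/√(ΩᵢᵢΩⱼⱼ), t-test with n−2−k degrees of freedom. The
  tests assert exact (10⁻¹⁰) agreement with the double-regression
  residual-correlation oracle on 1000 random instances.

## Bayesian networks

Gaussian (linear) node models on the continuous genotype values; no
discretization. The node score is the Gaussian log-likelihood minus
(|parents|+2)/2·log n — the "higher is better" BIC convention. Hill
climbing starts from the empty graph over add/delete/reverse moves;
score decomposability is exploited through a per-(node, parent-set) cache
and verified against full rescoring. Tabu search allows non-improving
moves while forbidding recently visited structures, and with tabu length
and stagnation 0 degenerates exactly to hill climbing. The blacklist
forbids every arc leading away from a trait, making traits network
endpoints; it is enforced move-by-move, so no learned structure can ever
violate it. **Tie-breaking is random (seeded), not lexicographic**: the
two orientations of a fresh arc between two nodes score identically
(score equivalence), and a deterministic tie-break would fabricate full
direction confidence out of nothing; random tie-breaking makes bootstrap
direction confidence ≈0.5 exactly when the data carry no orienting
information. Arc strength = fraction of bootstrap replicates containing
the arc in either direction; the consensus network keeps arcs with
strength ≥0.5 (the conventional model-averaging cut; the original work
labels but does not threshold strengths), orients by majority, and breaks
residual cycles by inserting arcs in decreasing strength order.

## CNN and Grad-CAM

The reference protocol fine-tunes ImageNet-pretrained backbones at
224×224, learning rate 10⁻⁵, batch 30, 50 epochs, with flip/90°-rotation
augmentation and min-validation-loss checkpointing. Desk-scale training of
such backbones is not feasible here, so a small from-scratch network
substitutes: three 3×3 convolution blocks (8/16/32 channels, leaky ReLU,
2×2 max pooling), a pool-flatten-dense(16)-dense(1) head, Adam on binary
cross-entropy, same augmentation and checkpointing. Those reference
hyperparameters remain the defaults of `train_config()`; the test profile
(`cnn_test_config()`) is 64×64, learning rate 10⁻³, **30 epochs**. Two
empirical findings drove the departures from an earlier sketch of this
profile (GAP head, plain ReLU, 10 epochs): a global-average-pooling head
dilutes a small central cavity ~256-fold and the classifier never left
chance within budget, plain-ReLU networks of this size occasionally
stalled in a dead-unit region, and ~50 Adam steps are simply too few for
from-scratch training — pretrained backbones need few epochs, fresh ones
do not. Leaky ReLU (slope 0.05), a flatten head and 30 epochs train to
perfect held-out accuracy on the cavity task in ~2 minutes on one CPU,
across seeds.

Grad-CAM: channel weights are the spatial mean of the class-score gradient
at the last convolution's activation maps; the map is the rectified
weighted sum, bilinearly upsampled and max-normalized (all-zero maps stay
zero). For the single-logit binary head the class-1 score is the logit and
the class-0 score its negative. Per-region relevance is averaged over the
seven non-Whole regions, only on correctly predicted prediction-set
images; empty regions are recorded as missing, not 0. Classes are compared
per region with a two-sided Mann–Whitney test (the original asterisks name
no test; a rank test is robust on bounded means) with Benjamini–Hochberg
adjusted p-values alongside the raw ones. Per-year training is represented
as independent runs on year-tagged subsets.

## Numerical and degenerate-input choices

* Empty masks: circularity 0, colors (0,0,0), thickness 0 (set-to-0
  rule); empty flesh → zero locules; empty scenes are the only
  segmentation error.
* Feature extraction rejects shape-mismatched inputs; trait generation
  rejects missing feature columns (schema errors).
* BIC of a singular parent design is −∞ (the move is simply never taken).
* All stochastic components — generator, forest, Boruta loop, CV folds,
  bootstrap, CNN initialization/augmentation — draw from R's RNG only, so
  a single `set.seed()` reproduces any pipeline run bit-for-bit.

## Known limitations

* The segmentation thresholds are tuned to the synthetic palette; real
  scanner images would need recalibrated `segmentation_config()` values
  and possibly illumination correction (out of scope).
* The interaction score is a path-co-occurrence surrogate, not the full
  iterated-reweighting procedure it stands in for.
* The Bayesian network assumes linear-Gaussian relations and no hidden
  variables; the consensus DAG is a summary of bootstrap support, not a
  causal claim.
* The CNN is a desk-scale stand-in: its accuracy numbers are not
  comparable to the published backbone accuracies, and only the
  qualitative Grad-CAM directions are asserted by the tests.
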