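---
title: "Classifying cortical morphometry with extreme learning machines"
author: "cortexELM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cortical morphometry with extreme learning machines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexELM)
```

# The problem

Structural MRI yields, after cortical reconstruction, a small set of
morphometric summaries for each anatomical parcel of the cortex: average
thickness, surface area, gray-matter volume, folding index and intrinsic
curvature. Over the 34 Desikan-Killiany parcels of each hemisphere this
gives a fixed table of 5 × 68 = 340 features per subject. The question
addressed by this package is whether such feature tables can discriminate a
clinical group (here, adolescents with ADHD, coded +1) from matched healthy
controls (coded −1), and which features carry the signal.

The pipeline has four fixed stages:

1. **Min–max normalization** of every feature to [0, 1] over the cohort.
2. **Fisher-score ranking** of all features, and evaluation of classifiers
   on the nested "experimental datasets" ED$_k$ formed by the top-$k$
   features, $k = 1, \dots, k_{\max}$.
3. **Sequential forward selection (SFS)** over the top-ranked pool, scored
   by leave-one-out cross-validated (LOOCV) accuracy.
4. **Validation**: ROC/AUC per classifier and a permutation test of the
   generalization rate.

# Models and statistics

## Fisher score

For feature $i$ with class means $\bar x_i^{+}, \bar x_i^{-}$, cohort mean
$\bar x_i$ and class sizes $n^{+}, n^{-}$:

$$
F(i) = \frac{(\bar x_i^{+}-\bar x_i)^2 + (\bar x_i^{-}-\bar x_i)^2}
{\tfrac{1}{n^{+}-1}\sum_k (x_{k,i}^{+}-\bar x_i^{+})^2 +
 \tfrac{1}{n^{-}-1}\sum_k (x_{k,i}^{-}-\bar x_i^{-})^2}.
$$

The denominator uses $(n-1)$ sample-variance divisors, the convention of
the criterion as originally proposed; the numerator uses the whole-cohort
mean. Degenerate features are defined to score 0 when numerator and
denominator both vanish and +∞ (flagged) when only the denominator does.
$F$ is invariant under positive per-feature affine maps, so ranking before
or after min–max normalization is identical up to ties; ties are broken by
ascending feature index so the ranking is deterministic.

## Extreme learning machine

The classifier at the core of the package is a single-hidden-layer
feedforward network whose input weights $W$ and biases $b$ are *random*
(uniform on $[-1, 1]$, seeded) and never trained. With the logistic sigmoid
$g$, the hidden output matrix is $H_{kj} = g(w_j \cdot x_k + b_j)$ and the
single output node's weights are obtained in closed form as the
minimum-norm least-squares solution

$$ \beta = H^{\dagger} T, $$

where $H^{\dagger}$ is the Moore–Penrose pseudoinverse and $T$ the ±1 label
vector. Prediction thresholds the continuous output at 0 (ties predict +1).
Because infinitely differentiable random hidden layers interpolate $N$
distinct points once $L \ge N$ hidden nodes are available, training error
vanishes in that regime; with the default $L = 20 \ll N$ the network is a
regularized random projection. The only stochasticity is the hidden layer,
so training-accuracy spread is reported over repeated random
initializations (default 20), while deterministic classifiers (the SVM
baselines) report fold-wise spread instead — the two "± SD" columns of the
reports therefore measure different things, which is stated here once and
deliberately.

Numerical choices: the pseudoinverse is computed by dense SVD with singular
values below $\max(N, L)\,\varepsilon\,\sigma_{\max}$ treated as zero; ±1
targets on a single output node are the minimal faithful coding for two
classes; input-weight and bias ranges are configurable.

## SVM baselines

Maximum-margin baselines (linear and RBF kernel) delegate to LIBSVM via
e1071 — re-implementing a QP solver is out of scope. The package owns the
protocol around the solver: hyperparameter grids follow the standard
exponential sequences $C \in 2^{-5}, 2^{-3}, \dots, 2^{15}$ and
$\gamma \in 2^{-15}, 2^{-13}, \dots, 2^{3}$; every grid point is scored by
stratified 5-fold cross-validation *on training data only*, with ties
resolved toward the smaller $C$ then smaller $\gamma$; decision scores are
oriented so positive means the patient class. Grid search runs once per
experimental dataset by default (`svmTuning = "once"`), with a nested
per-fold option for leakage-sensitivity analyses.

## Evaluation protocol

LOOCV holds out one subject per fold. Each fold of a stochastic classifier
draws its seed from a substream of the master seed, so folds are
exchangeable but the whole run is bit-reproducible. ROC curves sweep the
decision threshold over the unique scores; the trapezoid AUC equals the
tie-aware Mann–Whitney statistic, which a test verifies by exhaustive
pairwise comparison. The permutation test reshuffles the *full* label
vector before the LOOCV loop (the common convention when the statistic is a
cross-validated rate), repeats `nPerm` times, and reports the add-one
estimator $p = (1 + \#\{\text{null} \ge \text{observed}\})/(1 + n_{perm})$,
which is never exactly zero. Paired classifier comparisons use a two-sided
paired t-test over matched per-dataset accuracies; zero-variance differences
are reported as degenerate rather than silently producing NaN.

## Sequential forward selection

`sfs()` is a greedy wrapper: at each step it adds the candidate whose
augmented subset maximizes the criterion, ties toward the lowest feature
index. The run is *not* stopped at the first decline — published accuracy
traces routinely recover after local dips — it continues to
`min(maxSteps, pool)` and returns the earliest prefix attaining the
maximum. In the pipeline the criterion is the LOOCV accuracy of the primary
classifier; the pool defaults to the 46 top-ranked features (the span
within which all three classifiers' ranking curves peak) and 19 steps. The
SFS composition is chosen by the primary classifier and all configured
classifiers are then evaluated on each step's subset, which is what gives
the report a single feature column and three accuracy columns.

# The synthetic cohort generator

Real cohort data (the ADHD-200 Peking subset: 55 patients + 55 controls)
cannot ship with the package, so every pipeline stage is validated against
a generative model chosen to be the *minimal* structure under which
Fisher-score ranking and linear decision rules are provably sensible:
equal-covariance Gaussian classes. Within one (hemisphere, region) parcel
the five measures share an exchangeable correlation $\rho$ (default 0.3 —
thickness, area and volume of a parcel do co-vary in real data); distinct
parcels are independent. Informative features receive a mean shift of
$d \cdot \sigma$ in the patient class. Values are mapped into plausible
per-measure ranges (thickness ≈ 2.5 ± 0.15 mm, area ≈ 2500 ± 300 mm²,
volume ≈ 6000 ± 800 mm³, folding index ≈ 15 ± 3, curvature ≈ 0.13 ± 0.02);
the affine map cancels from every downstream statistic and exists only to
make fixtures realistic.

Defaults, fixed once: 55 + 55 subjects; 11 informative features placed at
the surface-area, volume and folding-index indices of occipital, temporal,
frontal and insular parcels (the feature classes most often reported as
discriminative in cortical-morphometry ADHD studies); $d = 1.0$, a
moderate-to-large single-feature effect typical of group-level morphometry
differences; unit latent noise.

The closed-form companion `theoreticalBayesAccuracy()` computes
$\Phi(\Delta/2)$ from the Mahalanobis separation $\Delta$ of the class
means, block by block. It upper-bounds what any classifier can achieve on
generated data, which turns "is the ELM close to optimal?" into a testable
quantity.

**What the generator does not emulate:** site and scanner effects, age and
medication covariates, heavy-tailed or skewed feature distributions,
long-range anatomical correlations across parcels, and FreeSurfer
segmentation noise. Tests passing on this model therefore demonstrate
correctness of the *algorithms and protocol*, not expected accuracy on real
cohorts.

# Design decisions worth recording

- **Normalization scope.** Whole-cohort min–max scaling precedes feature
  selection, matching the published stage order exactly; because the
  held-out subject contributes to the column extrema this leaks a small
  amount of information, so `loocv(..., perFoldNormalize = TRUE)` provides
  the hygienic variant for sensitivity analyses. Constant columns normalize
  to all zeros, keeping them in range and uninformative (their Fisher score
  is 0 either way).
- **Schema order.** The measure blocks are fixed as thickness, surface
  area, volume, folding index, curvature (indices 1–68, 69–136, 137–204,
  205–272, 273–340); within each block the left hemisphere's 34 parcels in
  standard FreeSurfer atlas order precede the right hemisphere's. Every
  published (index, measure, hemisphere, region) reference we could check
  is consistent with this order, and all downstream mathematics is
  order-invariant anyway.
- **Permutation scheme.** The full label vector is permuted before the
  LOOCV loop. Permuting only training labels within each fold would leave
  the held-out label fixed and bias the null upward; the chosen convention
  matches the usual definition of a classifier permutation test on a
  cross-validated statistic.
- **Problem sizes in the test-suite and acceptance runs.** The shipped
  checks run the full protocol at cohort sizes 16–110 subjects, ranking
  curves over 4–20 experimental datasets, SFS pools of 4–15, 99–199
  permutations, and 20–100 simulation replicates — sizes chosen so the
  entire suite completes on a laptop-class single core while keeping
  Monte-Carlo error well inside the asserted tolerances. All of them are
  plain configuration parameters; nothing in the implementation depends on
  these scales.

# Known limitations

- The minimum-norm pseudoinverse is the only capacity control for the ELM;
  no ridge-regularized or kernel variants are provided.
- The SFS wrapper inherits the optimistic bias of any selection procedure
  scored on the same LOOCV it reports; the permutation test quantifies the
  significance of the final rate but not selection-adjusted accuracy.
- AUC confidence intervals are not computed.
- FreeSurfer parsing covers the standard per-hemisphere `aparc` summary
  dialect only; subcortical segmentations are out of scope.

# Session info

```{r}
sessionInfo()
```
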