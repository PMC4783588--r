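---
title: "Weighted representational modeling with rdmfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted representational modeling with rdmfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdmfit)
```

## The problem

Representational similarity analysis (RSA) characterizes a neural
population code, or a behavioral judgment space, by its *representational
dissimilarity matrix* (RDM): the matrix of pairwise dissimilarities
between the responses evoked by a set of stimuli. `rdmfit` asks how well
two kinds of stimulus descriptions explain such a geometry: *categories*
(hierarchically nested labels such as "human", "mammal", "animal") and
*visual features* (parts and surface properties such as "eye", "circular",
"green"). Both kinds of description are encoded as binary dimensions over
stimuli, and each dimension `k` implies a single-dimension model RDM whose
entry for a stimulus pair `(i, j)` is the squared value difference
`(f_k(i) - f_k(j))^2` — 0 when the description applies to both or neither
image, 1 when it divides the pair.

Because squared differences sum across dimensions of a squared-Euclidean
representational space, scaling dimension `k` by a weight `w_k` multiplies
its single-dimension RDM by `w_k^2`, and a weighted model prediction is a
*non-negatively weighted sum of single-dimension RDMs*. Fitting a model to
a data RDM therefore reduces to non-negative least squares (NNLS) on the
vectorized RDMs:

> minimize  || d - Σ_k b_k m_k - b_0 1 ||²  subject to b_k ≥ 0,

where `d` is the data RDM vector, `m_k` the single-dimension model RDM
vectors, `b_0` the weight of a constant *confound-mean predictor* that
absorbs the overall mean dissimilarity, and the fitted dimension weights
are `w_k = sqrt(b_k)`. Non-negativity is what makes the weights
interpretable as (squared) axis scalings of the model's representational
space; no prior or penalty on the weights is used, deliberately.

## Pipeline overview

1. **RDM construction** (`rdm_from_patterns`): activity-pattern
   dissimilarity is 1 minus the Pearson correlation across measurement
   channels (0 identical, 1 uncorrelated, 2 anticorrelated). Per-session
   and per-subject RDMs are averaged entrywise (`average_rdms`); the mean
   is flat because plain averaging is associative, so session-then-subject
   averaging and one flat mean coincide.
2. **Model building** (`build_models_pipeline`): free descriptions become
   model dimensions through a generation threshold (kept when at least 3
   of 15 describers produced them), a validation threshold (an
   image-description pair scores 1 when at least 6 of 8 validators marked
   it), removal of all-zero dimensions, an optional manual exclusion list
   (human judgments are input data, not an algorithm), and iterative
   merging of highly correlated dimensions (while any pairwise Pearson
   r > 0.9, the single most correlated pair is averaged; ties break
   lexicographically so the procedure is deterministic).
3. **Judgment aggregation** (`aggregate_trials`): multi-arrangement trials
   record on-screen distances for item subsets at arbitrary per-trial
   scale. The aggregate alternates between rescaling each trial onto the
   current evidence-weighted average (a least-squares scale factor over
   the trial's pairs) and recomputing the average, until the average
   changes by less than `tol = 1e-6` in relative RMS (cap 1000
   iterations). The evidence weight of a pair within a trial is its
   squared scaled distance — close placements carry weak dissimilarity
   evidence; uniform weighting is available as a check. The result is
   RMS-normalized since only relative distances are meaningful.
4. **Cross-validated fitting** (`crossval_predict`): random held-out sets
   of 8 stimuli are drawn until every stimulus pair has co-occurred in at
   least one held-out set. Per fold, weights are estimated on pairs whose
   members are both in the training set, and only pairs entirely within
   the held-out set are predicted; pairs spanning the two sets are neither
   fitted nor predicted, so no held-out dissimilarity ever influences its
   own prediction. Pairs predicted by several folds are averaged with
   equal weight (folds are exchangeable).
5. **Inference** (`evaluate_model`, `randomization_test`,
   `bootstrap_compare`, `noise_ceiling`, `single_dimension_screen`):
   Kendall tau-a — the rank correlation with the full pair count in the
   denominator, so models that predict many tied dissimilarities are not
   rewarded — measured per subject; stimulus-label randomization tests
   (default 10,000 permutations, exhaustive below 8 conditions);
   stimulus-bootstrap model comparisons (default 1,000 draws);
   Benjamini–Hochberg FDR at 0.05; and a leave-one-subject-out noise
   ceiling.
6. **Second-order analysis** (`second_order_rdm`, `mds_embed`): distances
   between RDMs are 1 minus their Spearman correlation; a 2-D metric-stress
   MDS (SMACOF majorization, best of 8 seeded restarts) visualizes model–
   data relationships, reporting per-edge distortions.

## A worked miniature example

```{r example, eval = FALSE}
cfg <- scenario_config("judgment_like", n_stimuli = 48, seed = 7)
sc <- run_scenario(cfg)
models <- list(
  categorical = model_spec(single_dimension_rdms(sc$categorical),
                           label = "categorical"),
  feature = model_spec(single_dimension_rdms(sc$feature), label = "feature"))
models$combined <- combine_models(models$categorical, models$feature)
res <- fit_evaluate_pipeline(models, sc$subject_rdms,
                             run_config(seed = 7, n_perm = 2000))
res$comparison$pairs
res$ceiling
```

## Numerical and algorithmic choices

**NNLS solver.** The package solves NNLS with an active-set method on the
normal equations (`nnls_normal`, the fast-NNLS formulation of the
Lawson–Hanson algorithm). Working from `A'A` and `A'b` lets
cross-validation update each fold by *subtracting* the held-out rows'
contribution from the full-data crossproducts instead of refactoring a
4560 x 235 design per fold, and lets consecutive folds warm-start from
each other's active set; the solution satisfies the KKT conditions
regardless of the starting set. Rank-deficient passive sets (collinear
predictors) fall back to an SVD pseudo-inverse. Predictors that are
constant or all-zero on a training fold are retained with weight zero so
weight vectors stay aligned across folds.

**Tau-a.** Computed by Knight's O(m log m) merge-sort algorithm (C++),
with ties contributing zero concordance but counted in the denominator. A
constant vector yields tau 0 with a warning; the randomization test then
reports p = 1, keeping degenerate synthetic inputs from crashing a
pipeline.

**Randomization test.** Stimulus labels of the data RDM are permuted
jointly over rows and columns; p is `(1 + #{null >= observed}) / (1 +
n_perm)`. With 7 or fewer conditions all permutations are enumerated and p
is exact.

**Stimulus bootstrap with unique pairs.** Resampling stimuli with
replacement duplicates stimuli, and counting repeated pairs with
multiplicity overestimates the stimulus-sampling variance of pair-based
statistics — in this package's simulations against ground-truth stimulus
resampling, by a factor that *depends on how related the compared models
are* (SD inflation ~1.35 for weakly related models, ~1.10 for nearly
identical ones), so no single correction factor can calibrate the
multiplicity-counting test. Evaluating each realized pair once instead
(self-pairs of duplicated stimuli excluded: their dissimilarity is
identically zero) makes the bootstrap spread track ground-truth stimulus
resampling uniformly across both regimes, and the resulting tests are
calibrated without correction: in the package's null simulations the
empirical type-I error of the randomization test is 0.05 and of the
bootstrap comparison 0.035–0.06, within two percentage points of the
nominal 0.05. A residual `var_correction` argument remains for
sensitivity analyses. All models are evaluated on the same draws, so
comparisons are paired.

A caveat both for this implementation and for the procedure it mirrors:
bootstrap draws reuse the *fitted* predictions rather than refitting the
weights per draw, so a component of any model-performance difference that
stems from the particular noise realization the weights were fitted on is
treated as real. Differences between models that fit noise differently can
therefore reach significance even when the models are equivalent on
average over noise realizations.

**Noise ceiling.** Upper bound: mean tau-a of each subject's RDM with the
all-subject mean RDM (optimistic — the subject is included). Lower bound:
the same with the subject left out. This is the plain mean-RDM variant;
no per-subject refitting is attempted.

**Metric-stress MDS.** No installed package minimizes metric stress
directly (classical scaling optimizes a different criterion; the common
alternatives are nonmetric), so the package implements SMACOF
majorization: a Guttman-transform iteration from a classical-scaling start
plus seeded random restarts, keeping the lowest-stress solution; reported
stress is Kruskal's stress-1.

**Constant RDMs under the rank-percentile transform** map to 0.5
everywhere (with a warning), which keeps residual maps defined for
degenerate predictions.

## The synthetic-data generator

No stimulus images or measured data ship with the package; every analysis
input can be generated with known ground truth.

* **Dimensions** (`generate_dimension_matrix`): categories are indicator
  vectors of a random nesting tree (2–4-way splits with uneven child
  proportions down to single images, mirroring label hierarchies that run
  from "organism" to single-image subordinate labels). Features are
  binary vectors derived from a source category by independent entry
  flips calibrated to a target point-biserial correlation (default 0.88;
  1 copies the category, 0 is independent), plus category-unrelated
  random features. Features attach preferentially to *balanced* categories
  (attachment probability proportional to the indicator variance
  `s(n - s)`), because a meaningful correlation target requires a division
  that actually splits the set; a fraction of the major balanced divisions
  (default 25%, whole subtrees) is reserved feature-free, emulating
  category distinctions without visual-feature correlates.
* **Targets and patterns** (`generate_target_rdm`,
  `generate_subject_patterns`): the target is the forward model
  `sum w_k^2 RDM_k`. Channel patterns realizing it are built by linearly
  rescaling the target so its maximum correlation distance is 0.8 (the
  most dissimilar pair still correlates at 0.2, typical of multivoxel
  data, and moderate rescaling keeps weighted-sum targets exactly
  embeddable), converting to a correlation matrix, projecting to the
  nearest positive-semidefinite matrix when necessary (the adjustment is
  reported), factorizing, and rotating the factors into a channel basis
  orthogonal to the constant channel so that Pearson correlations across
  channels reproduce the target exactly at zero noise. Subjects share the
  signal and receive independent Gaussian channel noise; `noise_sd` is
  expressed relative to unit signal RMS.
* **Votes** (`generate_vote_tensor`) flip true/false marks with a given
  error rate; **arrangement trials** (`generate_arrangement_trials`) place
  the full set on trial one and then the items touching the
  least-evidenced pairs, at the 2-D classical-scaling configuration of the
  target sub-RDM plus placement noise and a random per-trial scale.

### Scenario calibration

`run_scenario` provides four named study conditions whose constants live
in `scenario_defaults()`:

* `it_like` (4 subjects, noise 2.5): the limiting case in which every
  category division has an exactly coextensive visual feature — each
  category receives one partner feature at correlation 1, so the two
  model families span the same representational structure and fitted
  categorical, feature-based and combined models perform statistically
  indistinguishably, the qualitative signature of high-level visual
  cortex in this framework. Generating weight lies on the identifiable
  separable category divisions; a 0.2%-mass tie-breaking component on
  category-unrelated features keeps the target free of exact value ties
  (rank-based recovery checks need a complete ordering) without
  measurably favoring the feature-based model.
* `judgment_like` (16 subjects, noise 0.8, feature–category correlation
  0.88): a shared component (categories with correlated feature partners,
  plus the partner features, mass-balanced) and a category-specific
  component on *reserved* divisions — whole subtrees excluded from
  feature attachment — scaled to three times the shared RDM-weight mass
  (`shared_variance_mix = 0.25`), so the categorical and combined models
  outperform the feature-based model and approach the noise ceiling, as
  similarity judgments do.
* `evc_like`: data generated from latent dimensions unrelated to either
  model; no model should survive FDR.
* `null`: pure channel noise.

Generating weight is confined to dimensions whose support is at least
`heldout_size + 1` away from empty and full, because a dimension supported
only on held-out stimuli vanishes from the training fold and its
contribution is unpredictable in principle; this mirrors the real
observation that weights of single-image dimensions do not generalize.
Effect sizes and noise levels were chosen, as the generator's own
calibration, so that each scenario's qualitative ordering holds in at
least 80% of seeds at 96 stimuli (and at the reduced sizes used by the
test suite); they are settings of the scenario configuration, not
hard-coded constants.

### What the generator does not emulate

Channel noise is additive, Gaussian, and independent across channels and
subjects; real fMRI noise is spatially and temporally correlated and
subject-specific. Dimension matrices are exactly binary before merging;
human labels carry correlated judgment error. Arrangement simulation uses
a fixed subset heuristic rather than the full adaptive "lift-the-weakest"
acquisition. Passing tests therefore demonstrate correctness of the
estimators and inference machinery under a faithful generative model of
the analysis assumptions — not robustness to every property of real data.

## Problem sizes used by the test suite

The acceptance-style checks run the full-size recovery analysis (96
stimuli, 114 + 120 dimensions, held-out sets of 8) once at zero noise, and
the stochastic scenario and calibration suites at reduced sizes (48
stimuli for scenario orderings over 20 seeds; 24 stimuli, 999
permutations, 200 bootstrap draws, 200 replicates for test calibration).
These sizes keep each property estimable with reasonable Monte-Carlo error
while the whole suite stays desk-scale.

## Known limitations

* The noise-ceiling upper bound uses the subject-inclusive mean RDM
  without refitting; variants that refit per subject can give slightly
  different bounds.
* The generation-threshold filter counts a subject once per description
  across all images by default (`per_image = TRUE` gives the stricter
  reading); the choice matters only for descriptions produced by few
  subjects on many images.
* Bootstrap p-values are two-sided for model comparisons and one-sided
  (tau > 0) for single-dimension screening; the variance correction factor
  2 is an asymptotic argument validated by simulation here, not an exact
  finite-sample result.
* The cross-validation fold count is random (coverage-driven); runtimes
  vary by a few percent across seeds.
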