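---
title: "Encoding models of category-selective visual regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding models of category-selective visual regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Category-selective regions of the human ventral visual stream — the
fusiform face area (FFA), parahippocampal place area (PPA) and
extrastriate body area (EBA) — are classically characterized by contrasts
between stimulus categories. `froienc` implements a stronger,
image-computable account: a linear readout of a fixed feature extractor's
layer activations that predicts each region's mean response to individual
images, and a set of probing tools that use the fitted model as a
high-throughput experimental instrument.

The pipeline's measured input is a table of per-stimulus response
estimates (betas from an event-related design, one value per stimulus and
region or voxel). Everything upstream of that — acquisition,
preprocessing, GLM estimation — is out of scope; betas arrive tabular.

# The model

Let $A_i \in \mathbb{R}^{H \times W \times D}$ be the activation tensor
of a chosen extractor layer for stimulus $i$. The factorized (two-stage)
readout is

$$\hat y_i = b + \sum_{d=1}^{D} w_d \cdot \frac{1}{HW}\sum_{x,y}
  m_{xy}\, A_i[x, y, d],$$

a rank-1-constrained linear map: a spatial mask $m$ (where the region
"looks" on the feature map) times a channel weight vector $w$ (what it is
tuned to). It is fitted by minimizing

$$L(m, w, b) = \frac{1}{n}\sum_i (y_i - \hat y_i)^2
  + \lambda_s \lVert m \rVert^2 + \lambda_d \lVert w \rVert^2$$

with full-batch Adam on the analytic gradients. Compared to an
unconstrained regression this has $HW + D$ rather than $HW \cdot D$
parameters. The factorization is identifiable only up to a scalar
exchanged between $m$ and $w$ (and a joint sign); fitted mappings are
therefore compared through the outer product $m w^\top$
(`outer_product()`), and the returned parameters are canonicalized to
$\sum m \ge 0$.

A plain ridge regression on the flattened tensor (`fit_ridge()`,
penalty fixed at 0.01, solved in closed form, dual form when $p > n$)
serves as the cheap screening mapper only; final models always use the
factorized form.

## Optimizer choices

No optimizer is canonical for this loss, so the package fixes one and
documents it: full-batch Adam, step 0.01, at most 2000 iterations, early
stop when the relative loss change over 50 iterations falls below
$10^{-6}$. $m$ and $w$ start from a seeded Gaussian (sd 0.01) — zero
initialization stalls because $\partial L/\partial m$ vanishes when
$w = 0$ — and $b$ starts at $\bar y$. The parameters at the best recorded
loss are returned; hitting the iteration cap sets `converged = FALSE` on
the result instead of raising, while a non-finite loss raises an
optimization-diverged error. A bias term is included by default
(configurable off via `opt_config(bias = FALSE)`), a choice left open by
the protocol description.

Only the two stated penalties are implemented; no spatial-smoothness term
is added to the mask.

# The locking protocol

Every free choice is frozen on data distinct from the data used for the
final score:

1. **Screening** (`screen_layers()`): every layer of every candidate
   extractor is scored per region with ridge at $\lambda = 0.01$, 5-fold
   cross-validation over 5 randomization seeds, pooling held-out
   predictions into one Pearson r and averaging over seeds. Averaging
   over seeds happens *before* any argmax (the alternative order is not
   exposed).
2. **Base model** (`select_base_model()`): integrative benchmarking —
   argmax over extractors of the mean across regions of the best-layer
   score. Ties break lexicographically by extractor id, making the lock
   deterministic.
3. **Layer per region** (`select_layer_cross_hemisphere()`): argmax on
   the *homologous* region's screening scores only; the target region's
   own data never inform its layer.
4. **Penalties** (`grid_search_hyperparams()`): a $6 \times 6$ grid,
   $10^{\mathrm{linspace}(-2, 2, 6)}$ per dimension (endpoints 0.01 and
   100 inclusive, base 10 — the only reading with exactly six points
   hitting both stated endpoints), evaluated by 10-fold cross-validation
   on the homologous region's responses. Folds are stimulus-wise, since
   the homologous data are a single region's response vector.
5. **Final score** (`final_score()`): one 10-fold cross-validation with a
   fresh seed for both fold assignment and weight initialization; pooled
   held-out predictions against observations, one Pearson r. Supplying
   the locking seeds triggers a protocol-violation warning on collision.

Cross-validated scores pool held-out predictions across folds into a
single correlation rather than averaging per-fold correlations: with
catalogs of one to two hundred stimuli, per-fold correlations on ~20
held-out values are too unstable to average meaningfully.

# Data conditioning and reliability

**Session normalization** (`normalize_session()`): within each session
group and target, responses are standardized by the mean and standard
deviation of that group's normalizer stimuli (a fixed subset repeated in
every session; the emulated design uses groups of 100 stimuli with 15
normalizers). The sample (n−1) standard deviation is used throughout —
with 15 normalizers the convention is material, so it is fixed and
documented. Normalizer rows transform like any other row, which makes the
operation idempotent. The pipeline normalizes before any split-half
computation (whether the original half-betas were normalized first is not
determinable from the protocol description; the order here is fixed and
configurable by simply skipping the call).

**Noise ceilings** (`split_half_ceiling()`): runs are randomly split in
half (sizes differing by at most one when odd), per-stimulus half-means
are correlated, and the correlation is Spearman-Brown corrected,
$2r/(1+r)$; 10 randomizations by default, mean and sd reported. For
run-noise sd $\sigma$, signal sd $s$ and $R$ runs the expected corrected
ceiling is $2\rho/(1+\rho)$ with $\rho = s^2/(s^2 + 2\sigma^2/R)$ — the
calibration tests check this closed form. Negative split correlations are
reported uncorrected but flag the target unreliable: the correction
formula presumes positive reliability. Across-subject ceilings
(`cross_subject_ceiling()`) correlate pooled $(n-1)$-subject data with
the held-out subject, or all ordered subject pairs, *without*
Spearman-Brown correction — they bound across-subject generalization
directly.

**Pooling** (`pool_subjects()`) is the unweighted mean across subjects;
no weighting scheme is part of the protocol.

# Evaluation

- `predictivity()` — Pearson r of cross-validated predictions against
  observations; constant vectors yield a flagged undefined score rather
  than an error.
- `voxelwise_predictivity()` — median across voxels of per-voxel r; with
  an even voxel count the median is the mean of the two central order
  statistics (the `stats::median` convention).
- `within_category_predictivity()` — r restricted to each category's
  stimuli; categories under 3 stimuli are skipped with a warning (a
  correlation on 2 points is vacuous).
- `shuffled_baseline()` — observations permuted only within category
  blocks, 100 iterations by default: a predictor carrying only category
  means is exactly shuffle-invariant, so any excess of the observed r
  over the shuffled distribution is image-level predictivity.
- `compute_rdm()` / `compare_rdms()` — Euclidean-distance representational
  dissimilarity matrices compared by Spearman correlation on the strictly
  upper triangle (the diagonal is identically zero and would only inflate
  agreement; this is the standard RSA convention).
- `wilcoxon_signed_rank()` — exact two-sided signed-rank test: zeros
  dropped, ties mid-ranked, the null distribution enumerated through its
  generating function for up to 25 retained pairs (mid-ranks are doubled
  to integers, so ties cost nothing), normal approximation with tie and
  continuity correction beyond. Zero-difference handling matters at
  $n = 6$ regions, hence the explicit convention.
- `filter_raters()` — test-retest reliability per rater on the repeat
  block; the retention threshold reads the stated cutoff of 0.85 as
  $\ge 0.85$ (the comparator is not stated; configurable).
  Ratings are used raw, not z-scored per rater, before correlation.
- `score_external_predictor()` — one predictor (a rater, or a model
  cross-validated over both subjects and images) correlated against each
  subject's responses, then the unweighted mean over subjects.

# Probing tools

**Screening** (`screen_images()`): images stream through the locked
predictor; the ranking is by predicted response, descending, with ties
broken by stimulus id so the result is invariant to stream order.
Undecodable images are counted and skipped. Histograms use 100
equal-width bins over the pooled score range (configurable).
`subsample_top()` inspects the deep tail by keeping the best 2 of each
block of 1000 within the top 100,000 (defaults give 200 images);
`exclusion_rescreen()` removes a labeled source or id set and returns the
remaining top 5000.

**Selective-unit control** (`select_selective_units()`): a unit (channel
× position) is "category-selective" iff its mean localizer response to
the target category strictly exceeds its mean response to every other
category — a deliberately literal transcription of the localizer
contrast. Selected units average into a pseudo-region
(`pseudo_froi_response()`) that can be modeled and screened like a real
region, testing whether contrast-defined units are as selective as the
regions they imitate.

**Importance maps** (`rise_importance()`): randomized occlusion masks —
7×7 binary grids with on-probability 0.5, bilinearly upsampled and
randomly shifted (the canonical parameters of the randomized-input
sampling method, all configurable) — weight the predictor's masked-image
responses, $S = (pN)^{-1} \sum_n f(I \odot M_n) M_n$, with $N = 2000$
masks by default. Maps are mean-centered before display so regions that
do not drive the model come out negative. For a locally linear predictor
$\mathbb{E}[S]$ is proportional to the per-pixel gradient and the
Monte-Carlo error shrinks as $1/\sqrt{N}$; both are tested.

**Synthesis** (`synthesize()`): activation maximization through a
generative prior. The latent is initialized from a standard normal
truncated to $[-2, 2]$ and scaled by the truncation parameter 0.5; the
class vector as $\alpha\,\mathrm{softmax}(n)$, $\alpha = 0.05$,
$n$ truncated-normal on $[0, 1]$ (inverse-CDF sampling, seeded). The
softmax is applied once at initialization; thereafter the class vector is
optimized jointly with the latent, unconstrained (freezing it is a
config option). Defaults are 30000 Adam steps at learning rate 0.001;
tests use a few hundred steps on toy generators. Gradients are analytic
when the generator supplies them and central finite differences
otherwise — adequate for the low-dimensional toy generators shipped for
testing, and replaceable wholesale for a differentiable generator stack.

# The synthetic-data module

`make_stimulus_set()` emulates the event-related catalog: four
categories whose default counts follow the stated per-category
composition (25 faces, 50 bodies, 50 scenes, 65 objects — these sum to
190 although the stated total is 185; the per-category counts are taken
as authoritative and everything is configurable), with 15 stimuli
designated session normalizers. Each category plants a distinct grating
(orientation × spatial frequency) in a distinct image quadrant over
seeded background noise — enough structure for rectified random filters
to develop category-tuned channels, which is what makes localizer-style
unit selection and screening enrichment testable downstream.

`make_toy_extractor()` builds the stand-in for pretrained networks: per
layer, an $H \times W$ grid of cells, each channel a fixed seeded 4×4×3
linear kernel resampled onto the cell, then rectified. No bias, so zero
images give zero activations; unit-sd kernel weights keep activation
variance $O(1)$ so readout weights of $O(1)$ suffice and the penalty grid
acts on a sensible scale.

`simulate_froi_responses()` is the generative twin of the fitted model —
identical bilinear form, including the $1/(HW)$ pooling factor — plus iid
Gaussian run noise, homoscedastic across stimuli. That noise model is
deliberately simple: it matches the split-half ceiling algebra exactly,
so ceiling calibration has a closed form. The pipeline's planted truths
(`category_tuned_truth`, internal) center the spatial mask on the
category's image quadrant and load the most diagnostic active channels
(positively or negatively — suppression is as diagnostic as excitation),
rescaled so the clean response has unit variance; `noise_sd` is then a
noise-to-signal ratio.

`simulate_raters()` squashes `true score + noise` into $[0,1]$ by a
per-rater affine rescale (emulating the bounded drag-rate response
format), with an independently re-noised 40-stimulus repeat block.

What the generator does *not* emulate: naturalistic image content,
hemodynamics, scanner drift, spatially correlated voxel noise, or
heteroscedasticity. Passing tests therefore demonstrate correctness of
the *machinery* under the stated statistical assumptions, not performance
on real fMRI data; the headline correlations of any real analysis depend
on real networks and real measurements.

# Problem sizes and numerical choices

The bundled `demo_config()` runs the complete protocol on a 48-stimulus,
3-subject, 20-run catalog with a 2-point penalty grid and a 300-iteration
optimizer budget — sizes chosen so a full run takes well under a minute
while every stage executes; the full `pipeline_config()` defaults keep
the protocol constants (6-point grid, 2000 masks, 100 shuffles, 10
ceiling splits, 5-fold × 5 seeds screening, 10-fold locking and final
CV). Calibration tests use 60–200 stimuli and 100 simulated targets,
where closed-form tolerances of ±0.03 are comfortably resolved.

Other fixed numerical conventions: ridge centers features and response
and leaves the intercept unpenalized, with $\lambda$ not scaled by $n$;
the degenerate 1×1 hyperparameter grid short-circuits without CV; k-fold
assignment is a seeded shuffle followed by a contiguous split, fold sizes
differing by at most one; all argmax ties anywhere in the locking
protocol break lexicographically.

# Known limitations

- The toy extractor is not a trained network; screening separations
  between its layers are smaller than between real network layers, which
  is why locking-rate checks run over many seeded worlds.
- Finite-difference synthesis gradients scale linearly in latent
  dimension; beyond toy generators an analytic `grad` should be supplied.
- The factorized optimizer is full-batch; catalogs far beyond $10^4$
  stimuli would want minibatching, which is out of scope.
- `wilcoxon_signed_rank()` is exact only to 25 retained pairs; beyond
  that the tie-corrected normal approximation is used.
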