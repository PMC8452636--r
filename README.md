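# froienc

Image-computable encoding models of category-selective regions of the
human ventral visual stream — the fusiform face area (FFA),
parahippocampal place area (PPA) and extrastriate body area (EBA) — for
researchers who want to go beyond category contrasts and model, validate
and probe the image-level response of a functionally localized region.

## The model

Given a fixed feature extractor (a pretrained network, or any object
implementing the embedding interface) with layer activations
*A<sub>i</sub>* ∈ ℝ<sup>H×W×D</sup> for stimulus *i*, the region's mean
response is modeled by a two-stage factorized linear readout

  ŷ<sub>i</sub> = b + Σ<sub>d</sub> w<sub>d</sub> · (1/HW) Σ<sub>x,y</sub> m<sub>xy</sub> A<sub>i</sub>[x,y,d]

— a learned spatial mask *m* over feature-map positions (*where* the
region reads from) times a learned weight vector *w* over channels
(*what* it is tuned to), fitted by penalized least squares

  L = (1/n) Σ<sub>i</sub> (y<sub>i</sub> − ŷ<sub>i</sub>)² + λ<sub>s</sub>‖m‖² + λ<sub>d</sub>‖w‖².

Around this core the package implements the full experimental protocol:

- **Data conditioning** — per-session standardization by normalizer
  stimuli, subject pooling (`normalize_session`, `pool_subjects`);
- **Reliability** — split-half noise ceilings with Spearman-Brown
  correction, across-subject ceilings (`split_half_ceiling`,
  `cross_subject_ceiling`);
- **Locking** — ridge screening of every candidate layer (λ = 0.01,
  5-fold × 5 seeds), base-model choice by integrative benchmarking,
  per-region layer choice from the homologous region in the opposite
  hemisphere, 6×6 log-spaced penalty grid search on homologous data, and
  a final 10-fold score with a fresh seed (`screen_layers`,
  `select_base_model`, `select_layer_cross_hemisphere`,
  `grid_search_hyperparams`, `final_score`);
- **Evaluation** — pooled / voxel-median / within-category predictivity,
  within-category shuffle baselines, Euclidean-distance RDM comparison by
  Spearman correlation, an exact Wilcoxon signed-rank test, rater
  filtering at test-retest ≥ 0.85 and external-predictor scoring
  (`predictivity`, `shuffled_baseline`, `compute_rdm`, `compare_rdms`,
  `wilcoxon_signed_rank`, `filter_raters`, `score_external_predictor`);
- **Probing** — ranked image screening with block subsampling and
  exclusion rescreens, localizer-contrast selective-unit controls,
  occlusion-mask importance maps, and activation-maximization synthesis
  through a generative prior (`screen_images`, `subsample_top`,
  `exclusion_rescreen`, `select_selective_units`, `rise_importance`,
  `synthesize`);
- **Synthetic data** — seeded stimulus catalogs with planted
  category-diagnostic patterns, toy feature extractors, ground-truth
  factorized mappings and multi-run response tables, so the whole
  pipeline runs and is tested without any external data
  (`make_stimulus_set`, `make_toy_extractor`, `simulate_froi_responses`,
  `simulate_raters`).

See `vignettes/encoding-models.Rmd` for the methods account: model
assumptions, locking protocol, numerical conventions, and what the
synthetic data do and do not emulate.

## Worked example

A complete protocol run on synthetic data — simulate, normalize, ceiling,
screen, lock, grid-search, final-score, evaluate, probe:

```r
library(froienc)
res <- run_pipeline(demo_config(seed = 1, out_dir = "demo_run"))

res$lock$base_model
#> [1] "ext_01"
unlist(res$lock$layers)
#> lFFA rFFA lEBA rEBA lPPA rPPA
#> "L1" "L1" "L1" "L1" "L1" "L1"
read.csv(file.path(res$out_dir, "evaluation_summary.csv"))
#>   froi final_r ceiling shuffle_mean_r
#> 1 lFFA   0.708   0.996          0.659
#> 2 rFFA   0.875   0.996          0.788
#> 3 lEBA   0.751   0.996          0.737
#> 4 rEBA   0.758   0.996          0.777
#> 5 lPPA   0.722   0.996          0.626
#> 6 rPPA   0.660   0.996          0.577
res$rdm_similarity
#> [1] 0.477
res$enrichment
#> [1] 20
```

Reading the output: the locking protocol recovered the generating
extractor (`ext_01`) and generating layer (`L1`) for all six simulated
regions without ever touching each region's own final-evaluation data.
`final_r` is the cross-validated Pearson correlation between predicted
and observed responses (here against a split-half ceiling of 0.996);
`shuffle_mean_r` is the within-category shuffled baseline — the gap
between it and `final_r` is image-level predictivity beyond category
structure. `rdm_similarity` is the Spearman agreement between observed
and predicted representational dissimilarity matrices across the six
regions. `enrichment = 20` means the top 1% of a fresh screened image
stream contained the face-preferring region's preferred category at 20
times its base rate (5% of the stream, 100% of the top).

Every artifact (beta tables, score tables, lockfile, ceilings, RDMs,
screening ranking, importance map, provenance) is written under
`out_dir` as plain CSV/JSON; rerunning the same config reproduces them
byte-identically.

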