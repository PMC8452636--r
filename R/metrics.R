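new_predictivity_score <- function(r, grain, froi = NULL, category = NULL,
                                   provenance = list(), pred = NULL,
                                   extra = list()) {
  structure(c(list(r = r, grain = grain, froi = froi, category = category,
                   undefined = is.na(r), provenance = provenance,
                   pred = pred), extra),
            class = "predictivity_score")
}

#' @export
print.predictivity_score <- function(x, ...) {
  cat(sprintf("predictivity [%s%s]: r = %s\n", x$grain,
              if (!is.null(x$froi)) paste0(", ", x$froi) else "",
              if (x$undefined) "undefined" else sprintf("%.4f", x$r)))
  invisible(x)
}

#' Neural predictivity: Pearson correlation of predictions and observations
#'
#' The core accuracy metric: the Pearson product-moment correlation between
#' cross-validated predictions and the observed responses.  A constant
#' input vector yields an undefined score (flagged, `r = NA`), not an
#' error.
#'
#' @param pred Numeric prediction vector.
#' @param obs Numeric observation vector of the same length (>= 3).
#' @param grain Label for the metric grain (default `"pooled"`).
#' @param froi Optional region label.
#' @return A `predictivity_score`.
#' @export
predictivity <- function(pred, obs, grain = "pooled", froi = NULL) {
  if (length(pred) != length(obs))
    stop_invalid("pred and obs lengths differ (", length(pred), " vs ",
                 length(obs), ")")
  if (length(pred) < 3L) stop_invalid("need at least 3 paired values")
  new_predictivity_score(safe_cor(pred, obs), grain = grain, froi = froi)
}

#' Voxelwise predictivity: median of per-voxel correlations
#'
#' Scores a voxel-resolved model by the median across voxels of the
#' per-voxel Pearson correlation between predicted and observed responses.
#' With an even voxel count the median is the mean of the two central order
#' statistics (the `stats::median` convention).  Voxels with undefined
#' correlations are dropped from the median; if all are undefined the score
#' is undefined.
#'
#' @param pred Stimuli x voxels prediction matrix.
#' @param obs Stimuli x voxels observation matrix of the same shape.
#' @return A `predictivity_score` with grain `"voxel_median"` and the
#'   per-voxel correlation vector in `$per_voxel`.
#' @export
voxelwise_predictivity <- function(pred, obs) {
  pred <- as.matrix(pred); obs <- as.matrix(obs)
  if (!identical(dim(pred), dim(obs)))
    stop_invalid("pred and obs shapes differ")
  if (ncol(pred) < 1L) stop_invalid("need at least 1 voxel")
  per_voxel <- vapply(seq_len(ncol(pred)), function(j)
    safe_cor(pred[, j], obs[, j]), numeric(1))
  med <- if (all(is.na(per_voxel))) NA_real_
         else stats::median(per_voxel, na.rm = TRUE)
  new_predictivity_score(med, grain = "voxel_median",
                         extra = list(per_voxel = per_voxel))
}

#' Within-category predictivity
#'
#' Restricts the prediction-observation correlation to the stimuli of each
#' category separately.  A model that captures only category-mean structure
#' scores ~0 here, so this metric isolates image-level predictivity beyond
#' category selectivity.  Categories with fewer than 3 stimuli are skipped
#' with a warning.
#'
#' @param pred,obs Aligned numeric vectors.
#' @param categories Character vector: category per stimulus.
#' @return Named list of `predictivity_score`s, one per evaluated category.
#' @export
within_category_predictivity <- function(pred, obs, categories) {
  stopifnot(length(pred) == length(obs), length(categories) == length(obs))
  out <- list()
  for (cat in unique(categories)) {
    idx <- which(categories == cat)
    if (length(idx) < 3L) {
      warning("category '", cat, "' has ", length(idx),
              " stimuli (< 3): skipped", call. = FALSE)
      next
    }
    out[[cat]] <- new_predictivity_score(safe_cor(pred[idx], obs[idx]),
                                         grain = "within_category",
                                         category = cat)
  }
  out
}

#' Within-category shuffled baseline
#'
#' The control for category-only predictivity: the observations are
#' permuted independently within each category block (category labels stay
#' in place, image identities within a category are scrambled), the
#' prediction-observation correlation is recomputed, and this repeats for
#' `n_iterations` (default 100).  A predictor carrying only category means
#' is invariant to the shuffle; genuine image-level predictivity places the
#' observed correlation above the shuffled distribution.
#'
#' @param pred,obs Aligned numeric vectors.
#' @param categories Category per stimulus (a partition of the stimuli).
#' @param n_iterations Number of shuffles (default 100).
#' @param seed Integer seed.
#' @return Object of class `shuffle_baseline`: list with `observed_r`,
#'   `shuffled_r` (length `n_iterations`), `categories`.
#' @export
shuffled_baseline <- function(pred, obs, categories, n_iterations = 100L,
                              seed = 1L) {
  stopifnot(length(pred) == length(obs), length(categories) == length(obs))
  check_scalar_number(n_iterations, "n_iterations", lower = 1)
  observed <- safe_cor(pred, obs)
  blocks <- split(seq_along(obs), categories)
  shuffled <- with_seed(seed, vapply(seq_len(n_iterations), function(i) {
    perm_obs <- obs
    for (idx in blocks) perm_obs[idx] <- obs[idx][sample.int(length(idx))]
    safe_cor(pred, perm_obs)
  }, numeric(1)))
  structure(list(observed_r = observed, shuffled_r = shuffled,
                 categories = unique(categories),
                 n_iterations = as.integer(n_iterations)),
            class = "shuffle_baseline")
}

#' Filter raters by test-retest reliability
#'
#' Computes each rater's Pearson correlation between first-pass and
#' repeat-pass ratings on the repeat stimuli and retains raters at or above
#' the threshold (default 0.85, matching the behavioral inclusion
#' criterion).  Raters with constant ratings have undefined reliability and
#' are excluded with a note.
#'
#' @param ratings Data frame as produced by [simulate_raters()]: columns
#'   `rater_id`, `stimulus_id`, `phase`, `rating`.
#' @param threshold Minimum test-retest correlation (default 0.85).
#' @return List with `retained` (rater ids), `reliability` (named vector of
#'   per-rater r), `excluded_undefined` (rater ids with undefined r).
#' @export
filter_raters <- function(ratings, threshold = 0.85) {
  stopifnot(all(c("rater_id", "stimulus_id", "phase", "rating") %in%
                  names(ratings)))
  raters <- unique(ratings$rater_id)
  rel <- stats::setNames(rep(NA_real_, length(raters)), raters)
  for (r in raters) {
    sub <- ratings[ratings$rater_id == r, ]
    rep_block <- sub[sub$phase == "repeat", ]
    if (nrow(rep_block) == 0L)
      stop_invalid("rater '", r, "' has an empty repeat block")
    first <- sub[sub$phase == "first", ]
    first_ratings <- stats::setNames(first$rating, first$stimulus_id)
    rel[r] <- safe_cor(first_ratings[rep_block$stimulus_id], rep_block$rating)
  }
  undefined <- names(rel)[is.na(rel)]
  retained <- names(rel)[!is.na(rel) & rel >= threshold]
  list(retained = retained, reliability = rel,
       excluded_undefined = undefined)
}

#' Score an external predictor against per-subject responses
#'
#' Correlates a per-stimulus predictor (e.g., one rater's category-likeness
#' ratings, or a model's subject-and-image cross-validated predictions)
#' with each subject's observed responses in a target region, then averages
#' the per-subject correlations (unweighted).
#'
#' @param predictor Named numeric vector of per-stimulus predictor values.
#' @param tables List of `beta_table`s, one per subject.
#' @param target Target (region) column.
#' @return A `predictivity_score` whose `r` is the mean over subjects, with
#'   per-subject values in `$per_subject`.
#' @export
score_external_predictor <- function(predictor, tables, target) {
  per_subject <- vapply(tables, function(t) {
    ids <- rownames(t$values)
    if (!all(ids %in% names(predictor)))
      stop_invalid("predictor does not cover all stimuli")
    safe_cor(predictor[ids], t$values[, target])
  }, numeric(1))
  new_predictivity_score(mean(per_subject), grain = "mean_over_subjects",
                         froi = target,
                         extra = list(per_subject = per_subject))
}
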