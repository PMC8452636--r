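#' Seeded k-fold cross-validation scheme
#'
#' Deterministic fold assignment: a seeded shuffle of the items followed by
#' a contiguous split into `k` folds whose sizes differ by at most one.
#' The screening protocol uses 5 folds over 5 seeds; hyperparameter search
#' and final scoring use 10 folds with fresh seeds.
#'
#' @param n Number of items.
#' @param k Number of folds (2 <= k <= n).
#' @param seed Integer seed.
#' @return Object of class `cv_scheme`: list with `n`, `k`, `seed`, and
#'   `fold` (fold id per item, 1..k).
#' @export
make_kfold <- function(n, k, seed = 1L) {
  check_scalar_number(n, "n", lower = 1)
  check_scalar_number(k, "k", lower = 2)
  if (k > n) stop_invalid("k (", k, ") exceeds n (", n, ")")
  fold <- integer(n)
  with_seed(seed, {
    perm <- sample.int(n)
    sizes <- rep(floor(n / k), k)
    extra <- n - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    idx <- 1L
    for (f in seq_len(k)) {
      fold[perm[idx:(idx + sizes[f] - 1L)]] <- f
      idx <- idx + sizes[f]
    }
  })
  structure(list(n = as.integer(n), k = as.integer(k),
                 seed = as.integer(seed), fold = fold),
            class = "cv_scheme")
}

# Pool held-out predictions across folds and score them with one Pearson r.
# (Alternative per-fold averaging is deliberately not used; pooling is
# stabler at ~200 stimuli.)
cv_pooled_r <- function(features, y, cv, fitter) {
  n <- length(y)
  stopifnot(cv$n == n)
  pred <- rep(NA_real_, n)
  for (f in seq_len(cv$k)) {
    test <- which(cv$fold == f)
    train <- which(cv$fold != f)
    mapping <- fitter(features[train], y[train])
    pred[test] <- predict(mapping, features[test])
  }
  list(r = safe_cor(pred, y), pred = pred)
}

ridge_fitter <- function(lambda = 0.01) {
  function(feats, y) fit_ridge(feats, y, lambda = lambda)
}

factorized_fitter <- function(lambda_s, lambda_d, opt = opt_config()) {
  function(feats, y) fit_factorized(feats, y, lambda_s = lambda_s,
                                    lambda_d = lambda_d, opt = opt)
}

#' Screen feature sets against every region with a fast ridge mapper
#'
#' For every (extractor, layer, target) combination: fits a ridge mapping
#' per cross-validation training fold (penalty fixed at 0.01, not tuned),
#' pools the held-out predictions across folds, scores them with one
#' Pearson correlation against the observations, and averages that score
#' over the randomization seeds (5-fold, 5 seeds by default).  The
#' resulting score table drives the locking protocol: base-model choice by
#' integrative benchmarking and layer choice on homologous-region data.
#'
#' @param extractors Named list of `feature_extractor`s.
#' @param stimuli A `stimulus_set` covering every stimulus in `betas`.
#' @param betas A `beta_table` (stimuli x regions).
#' @param lambda Ridge penalty, default 0.01.
#' @param k Folds per randomization (default 5).
#' @param seeds Integer vector of randomization seeds (default 1:5).
#' @return Data frame score table: `extractor_id`, `layer`, `froi`,
#'   `metric` (`"pooled"`), `score`, `cv` (descriptor string).
#' @export
screen_layers <- function(extractors, stimuli, betas, lambda = 0.01,
                          k = 5L, seeds = 1:5) {
  stopifnot(inherits(betas, "beta_table"))
  ids <- rownames(betas$values)
  if (!all(ids %in% names(stimuli$images)))
    stop_invalid("stimuli set does not cover all stimuli in betas")
  if (is.null(names(extractors)))
    names(extractors) <- vapply(extractors, `[[`, character(1), "id")
  rows <- list()
  for (ex_id in names(extractors)) {
    ex <- extractors[[ex_id]]
    for (layer in names(ex$layers)) {
      feats <- extract_layer(ex, stimuli, layer)[ids]
      for (froi in colnames(betas$values)) {
        y <- betas$values[, froi]
        per_seed <- vapply(seeds, function(s) {
          cv <- make_kfold(length(y), k, seed = s)
          cv_pooled_r(feats, y, cv, ridge_fitter(lambda))$r
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          extractor_id = ex_id, layer = layer, froi = froi,
          metric = "pooled", score = mean(per_seed),
          cv = sprintf("%dfold_x%dseeds", k, length(seeds)),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Choose the base model by integrative benchmarking
#'
#' Picks the extractor with the numerically highest cross-validated
#' predictive accuracy averaged across all regions: for each extractor the
#' best layer score per region is taken, those are averaged over regions,
#' and the argmax wins.  Ties break by extractor id in lexicographic order.
#'
#' @param scores Score table from [screen_layers()].
#' @return The selected extractor id (character scalar), with the
#'   per-extractor means attached as attribute `"means"`.
#' @export
select_base_model <- function(scores) {
  frois <- unique(scores$froi)
  extractors <- sort(unique(scores$extractor_id))
  means <- vapply(extractors, function(ex) {
    sub <- scores[scores$extractor_id == ex, ]
    if (!all(frois %in% sub$froi))
      stop_invalid("incomplete screen: extractor '", ex,
                   "' missing regions: ",
                   paste(setdiff(frois, sub$froi), collapse = ", "))
    best_per_froi <- vapply(frois, function(fr)
      max(sub$score[sub$froi == fr]), numeric(1))
    mean(best_per_froi)
  }, numeric(1))
  sel <- extractors[which.max(means)]  # which.max takes first: lexicographic tie-break
  attr(sel, "means") <- means
  sel
}

#' Choose a region's layer from its homologous region's scores
#'
#' The layer used to model a target region is locked using only the
#' screening scores of the homologous region in the opposite hemisphere,
#' so the target region's own data never inform the choice.  Ties break
#' lexicographically by layer name.
#'
#' @param scores Score table from [screen_layers()].
#' @param extractor_id The locked base model.
#' @param homologous_froi The opposite-hemisphere region whose scores drive
#'   the choice.
#' @return Selected layer name.
#' @export
select_layer_cross_hemisphere <- function(scores, extractor_id,
                                          homologous_froi) {
  sub <- scores[scores$extractor_id == extractor_id &
                  scores$froi == homologous_froi, ]
  if (nrow(sub) == 0L)
    stop_invalid("incomplete screen: no scores for extractor '",
                 extractor_id, "' on region '", homologous_froi, "'")
  sub <- sub[order(sub$layer), ]
  sub$layer[which.max(sub$score)]
}

#' Default regularization grid for the factorized mapper
#'
#' Six points evenly spaced on a base-10 logarithmic scale spanning
#' 0.01 to 100 inclusive.
#'
#' @return Numeric vector of length 6.
#' @export
default_lambda_grid <- function() 10^seq(-2, 2, length.out = 6)

#' Grid-search the factorized mapper's two regularization strengths
#'
#' Evaluates every (lambda_s, lambda_d) pair on the supplied grid by
#' k-fold cross-validation (10-fold by default) of the factorized mapper,
#' scoring pooled held-out predictions with Pearson r, and returns the
#' argmax pair.  In the locking protocol the responses supplied here are
#' the homologous region's, keeping the final evaluation data untouched.
#' A 1 x 1 grid short-circuits without cross-validation.
#'
#' @param features Named list of feature tensors.
#' @param y Homologous-region response vector.
#' @param grid Per-dimension lambda values (default [default_lambda_grid()]).
#' @param k CV folds (default 10).
#' @param seed CV seed.
#' @param opt An [opt_config()] for the inner fits.
#' @return List with `lambda_s`, `lambda_d`, and `results` (data frame of
#'   all evaluated pairs and their held-out r).
#' @export
grid_search_hyperparams <- function(features, y, grid = default_lambda_grid(),
                                    k = 10L, seed = 1L, opt = opt_config()) {
  if (length(grid) < 1L) stop_invalid("grid must be nonempty")
  if (length(grid) == 1L)
    return(list(lambda_s = grid, lambda_d = grid,
                results = data.frame(lambda_s = grid, lambda_d = grid,
                                     r = NA_real_)))
  cv <- make_kfold(length(y), k, seed = seed)
  pairs <- expand.grid(lambda_s = grid, lambda_d = grid)
  pairs$r <- vapply(seq_len(nrow(pairs)), function(i) {
    cv_pooled_r(features, y, cv,
                factorized_fitter(pairs$lambda_s[i], pairs$lambda_d[i],
                                  opt))$r
  }, numeric(1))
  if (all(is.na(pairs$r))) stop_invalid("grid failure: all scores undefined")
  best <- which.max(pairs$r)
  list(lambda_s = pairs$lambda_s[best], lambda_d = pairs$lambda_d[best],
       results = pairs)
}

#' Final cross-validated score of a locked model
#'
#' Runs a single k-fold cross-validation (10-fold by default, with a seed
#' distinct from every locking seed) of the factorized mapper at the locked
#' hyperparameters, pooling held-out predictions into one Pearson r.  The
#' provenance field records the locked choices and seeds; supplying a
#' `locking_seeds` vector that contains `seed` triggers a protocol-violation
#' warning.
#'
#' @param features Named list of feature tensors.
#' @param y Target-region response vector.
#' @param lambda_s,lambda_d Locked penalties.
#' @param k CV folds (default 10).
#' @param seed Fresh CV/initialization seed.
#' @param opt An [opt_config()]; its seed is re-derived from `seed`.
#' @param locking_seeds Optional integer vector of seeds used during
#'   locking, for the hygiene check.
#' @return Object of class `predictivity_score` (see [predictivity()]) with
#'   grain `"pooled"` and full provenance.
#' @export
final_score <- function(features, y, lambda_s, lambda_d, k = 10L, seed = 1L,
                        opt = opt_config(), locking_seeds = NULL) {
  if (!is.null(locking_seeds) && seed %in% locking_seeds)
    warning("protocol violation: final CV seed ", seed,
            " collides with a locking seed", call. = FALSE)
  opt$seed <- split_seed(seed, "final_init")
  cv <- make_kfold(length(y), k, seed = seed)
  res <- cv_pooled_r(features, y, cv,
                     factorized_fitter(lambda_s, lambda_d, opt))
  new_predictivity_score(res$r, grain = "pooled",
                         provenance = list(lambda_s = lambda_s,
                                           lambda_d = lambda_d,
                                           k = k, seed = seed,
                                           locking_seeds = locking_seeds),
                         pred = res$pred)
}

#' Across-subject generalization schemes
#'
#' Scores a mapper under the three generalization regimes: training on the
#' pooled data of all-but-one subject and testing on the held-out subject's
#' held-out stimuli (`pool_heldout_subject`); ordinary k-fold within one
#' subject (`within_subject`); and training on one subject and testing
#' another subject's held-out stimuli for every ordered pair
#' (`cross_subject_transfer`).  All schemes cross-validate over stimuli, so
#' test stimuli are never seen in training.
#'
#' @param features Named list of feature tensors covering the stimuli.
#' @param tables List of >= 2 aligned `beta_table`s, one per subject.
#' @param target Target (region) column to model.
#' @param scheme One of `"pool_heldout_subject"`, `"within_subject"`,
#'   `"cross_subject_transfer"`.
#' @param k CV folds (default 10).
#' @param seed CV seed.
#' @param mapper `"ridge"` or `"factorized"`.
#' @param lambda Ridge penalty if `mapper = "ridge"`.
#' @param lambda_s,lambda_d Penalties if `mapper = "factorized"`.
#' @param opt An [opt_config()] for factorized fits.
#' @return Data frame with columns `scheme`, `train`, `test`, `r`.
#' @export
generalization_schemes <- function(features, tables, target,
                                   scheme = c("pool_heldout_subject",
                                              "within_subject",
                                              "cross_subject_transfer"),
                                   k = 10L, seed = 1L,
                                   mapper = c("ridge", "factorized"),
                                   lambda = 0.01, lambda_s = 0.01,
                                   lambda_d = 0.01, opt = opt_config()) {
  scheme <- match.arg(scheme)
  mapper <- match.arg(mapper)
  if (length(tables) < 2L && scheme != "within_subject")
    stop_invalid("scheme '", scheme, "' needs at least 2 subjects")
  fitter <- if (mapper == "ridge") ridge_fitter(lambda)
            else factorized_fitter(lambda_s, lambda_d, opt)
  ids <- rownames(tables[[1]]$values)
  feats <- features[ids]
  n <- length(ids)
  subj <- vapply(tables, function(t) paste(t$subject, collapse = "+"),
                 character(1))
  yy <- function(t) t$values[ids, target]
  cv <- make_kfold(n, k, seed = seed)
  rows <- list()
  add <- function(train, test, r)
    rows[[length(rows) + 1L]] <<- data.frame(scheme = scheme, train = train,
                                             test = test, r = r,
                                             stringsAsFactors = FALSE)
  if (scheme == "within_subject") {
    for (i in seq_along(tables))
      add(subj[i], subj[i], cv_pooled_r(feats, yy(tables[[i]]), cv, fitter)$r)
  } else if (scheme == "pool_heldout_subject") {
    for (i in seq_along(tables)) {
      y_train <- yy(pool_subjects(tables[-i]))
      y_test <- yy(tables[[i]])
      pred <- rep(NA_real_, n)
      for (f in seq_len(cv$k)) {
        te <- which(cv$fold == f); tr <- which(cv$fold != f)
        mp <- fitter(feats[tr], y_train[tr])
        pred[te] <- predict(mp, feats[te])
      }
      add(paste0("pool_minus_", subj[i]), subj[i], safe_cor(pred, y_test))
    }
  } else {
    for (i in seq_along(tables)) for (j in seq_along(tables)) {
      if (i == j) next
      y_train <- yy(tables[[i]]); y_test <- yy(tables[[j]])
      pred <- rep(NA_real_, n)
      for (f in seq_len(cv$k)) {
        te <- which(cv$fold == f); tr <- which(cv$fold != f)
        mp <- fitter(feats[tr], y_train[tr])
        pred[te] <- predict(mp, feats[te])
      }
      add(subj[i], subj[j], safe_cor(pred, y_test))
    }
  }
  do.call(rbind, rows)
}
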