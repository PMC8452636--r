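#' Configuration for an end-to-end synthetic pipeline run
#'
#' Collects every tunable of the protocol in one validated object.  The
#' analysis defaults mirror the study protocol: ridge penalty 0.01 with
#' 5-fold cross-validation over 5 seeds for screening; a 6-point base-10
#' logarithmic grid on [0.01, 100] for each factorized penalty, searched
#' with 10-fold cross-validation on homologous-region data; final 10-fold
#' scoring with a fresh seed; 10 split-half randomizations for ceilings;
#' 100 within-category shuffles; 2000 occlusion masks; screening constants
#' 5000 / 100000 / 1000 / 2; synthesis at 30000 steps, learning rate
#' 0.001, class scale 0.05, truncation 0.5; rater threshold 0.85.  The
#' data-scale arguments control the synthetic study the run emulates.
#' Unknown keys are rejected.
#'
#' @param seed Master seed; per-stage seeds are derived from it by the
#'   package's documented splitting rule.
#' @param out_dir Artifact directory.
#' @param counts_per_category,image_size,normalizer_count Stimulus catalog
#'   (see [make_stimulus_set()]).
#' @param n_subjects,n_runs,noise_sd Simulated measurement design.
#' @param session_size Stimuli per session group for normalization.
#' @param layer_specs Layer specifications for each toy extractor.
#' @param n_extractors Number of candidate toy extractors.
#' @param true_layer Name of the layer generating the planted responses.
#' @param screen_lambda,screen_k,screen_seeds Ridge screening protocol.
#' @param grid,grid_k Factorized hyperparameter search.
#' @param final_k Folds for final scoring.
#' @param opt An [opt_config()] for factorized fits.
#' @param n_ceiling_splits,n_shuffles Evaluation settings.
#' @param screen_counts Category counts of the fresh probing image stream
#'   (the preferred category is kept rare so enrichment is measurable).
#' @param n_masks Occlusion masks for the importance map.
#' @param synthesis_steps Steps for the toy synthesis demo (0 disables).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = tempfile("froienc_run_"),
                            counts_per_category = c(face = 25, body = 50,
                                                    scene = 50, object = 65),
                            image_size = c(32L, 32L),
                            normalizer_count = 15L,
                            n_subjects = 4L,
                            n_runs = 20L,
                            noise_sd = 1,
                            session_size = 100L,
                            layer_specs = list(
                              list(name = "L1", H = 4, W = 4, D = 8),
                              list(name = "L2", H = 2, W = 2, D = 16)),
                            n_extractors = 2L,
                            true_layer = "L1",
                            screen_lambda = 0.01,
                            screen_k = 5L,
                            screen_seeds = 1:5,
                            grid = default_lambda_grid(),
                            grid_k = 10L,
                            final_k = 10L,
                            opt = opt_config(),
                            n_ceiling_splits = 10L,
                            n_shuffles = 100L,
                            screen_counts = c(face = 30, body = 190,
                                              scene = 190, object = 190),
                            n_masks = 2000L,
                            synthesis_steps = 0L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Scaled-down configuration for a complete demonstration run
#'
#' A configuration whose catalog, optimizer budget, grid and mask counts
#' are sized so the whole protocol — simulate, normalize, ceiling, screen,
#' lock, grid-search, final fit, evaluate, probe — completes in minutes on
#' one CPU while exercising every stage.
#'
#' @param seed Master seed.
#' @param out_dir Artifact directory.
#' @return A `pipeline_config`.
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("froienc_demo_")) {
  pipeline_config(
    seed = seed, out_dir = out_dir,
    counts_per_category = c(face = 12, body = 12, scene = 12, object = 12),
    image_size = c(16L, 16L), normalizer_count = 8L,
    n_subjects = 3L, n_runs = 20L, noise_sd = 0.5, session_size = 24L,
    grid = c(0.01, 100), grid_k = 5L,
    opt = opt_config(max_iter = 300L),
    screen_counts = c(face = 20, body = 130, scene = 130, object = 120),
    n_masks = 200L, synthesis_steps = 200L)
}

# Category-tuned ground truth.  Each category's planted image signature
# occupies a fixed quadrant, so the truth's spatial mask is centered on
# that quadrant of the activation map and channel diagnosticity is judged
# on quadrant-pooled activations (a whole-map pool would dilute the
# signature with background cells).  The channel weights load the top few
# diagnostic channels, softmax-weighted by margin, and the whole mapping
# is rescaled so the clean response has unit standard deviation across the
# catalog — noise_sd is then a noise-to-signal ratio.
category_quadrant <- function(category, H, W) {
  hh <- seq_len(ceiling(H / 2)); wh <- seq_len(ceiling(W / 2))
  switch(category,
         face   = list(rows = hh, cols = wh),
         body   = list(rows = hh, cols = setdiff(seq_len(W), wh)),
         scene  = list(rows = setdiff(seq_len(H), hh), cols = wh),
         object = list(rows = setdiff(seq_len(H), hh),
                       cols = setdiff(seq_len(W), wh)),
         stop_invalid("unknown category: ", category))
}

category_tuned_truth <- function(extractor, layer, stimuli, category,
                                 noise_sd, n_runs, seed, offset = c(0, 0)) {
  feats <- extract_layer(extractor, stimuli, layer)
  dm <- dim(feats[[1]])
  quad <- category_quadrant(category, dm[1], dm[2])
  pooled <- t(vapply(feats, function(A)
    apply(A[quad$rows, quad$cols, , drop = FALSE], 3, mean),
    numeric(dm[3])))                                # stimuli x channels
  cats <- stimuli$manifest$category
  cat_means <- vapply(sort(unique(cats)), function(cc)
    colMeans(pooled[cats == cc, , drop = FALSE]), numeric(dm[3]))
  others <- cat_means[, setdiff(colnames(cat_means), category),
                      drop = FALSE]
  # a channel is diagnostic if the category sits above every other
  # category's mean (positive loading) or below every other's (negative
  # loading: suppression is as informative as excitation)
  margin_pos <- cat_means[, category] - apply(others, 1, max)
  margin_neg <- apply(others, 1, min) - cat_means[, category]
  margin <- pmax(margin_pos, margin_neg)
  sgn <- ifelse(margin_pos >= margin_neg, 1, -1)
  # restrict to active channels (rectified units can be dead everywhere)
  active <- which(apply(pooled, 2, stats::sd) > 0)
  if (length(active) == 0L)
    stop_invalid("layer '", layer, "' has no active channels on this catalog")
  top <- active[order(margin[active],
                      decreasing = TRUE)][seq_len(min(3L, length(active)))]
  if (any(margin[top] > 0)) top <- top[margin[top] > 0]
  w <- numeric(dm[3])
  w[top] <- exp(margin[top] - max(margin[top])) * sgn[top]
  w <- w / sqrt(sum(w^2))
  cx <- mean(quad$rows) + offset[1]; cy <- mean(quad$cols) + offset[2]
  m <- outer(seq_len(dm[1]), seq_len(dm[2]), function(x, y)
    exp(-((x - cx)^2 + (y - cy)^2) / (2 * 1.0^2)))
  clean <- vapply(feats, function(A) sum(vapply(seq_len(dm[3]), function(d)
    w[d] * sum(m * A[, , d]) / (dm[1] * dm[2]), numeric(1))), numeric(1))
  scale <- stats::sd(clean)
  if (scale > 0) {             # unit signal sd, scale split across factors
    m <- m / sqrt(scale)
    w <- w / sqrt(scale)
  }
  ground_truth(m = m, w = w, b = 0.5, noise_sd = noise_sd,
               n_runs = n_runs, seed = seed)
}

# Session groups guaranteeing >= 2 normalizers per group: normalizers are
# dealt round-robin across groups first, remaining stimuli fill up.
assign_sessions <- function(ids, normalizer_ids, session_size) {
  n_groups <- max(1L, ceiling(length(ids) / session_size))
  if (length(normalizer_ids) < 2L * n_groups) n_groups <- 1L
  groups <- stats::setNames(rep(NA_character_, length(ids)), ids)
  gnames <- sprintf("session_%02d", seq_len(n_groups))
  groups[normalizer_ids] <-
    gnames[((seq_along(normalizer_ids) - 1L) %% n_groups) + 1L]
  rest <- setdiff(ids, normalizer_ids)
  groups[rest] <- gnames[((seq_along(rest) - 1L) %% n_groups) + 1L]
  groups
}

#' Run the full encoding-model protocol on synthetic data
#'
#' Executes, end to end and deterministically given the config seed:
#' stimulus/extractor simulation with planted category-tuned factorized
#' ground truths for six regions (left and right face-, body- and
#' scene-preferring); multi-run response simulation for every subject;
#' session normalization; split-half and across-subject noise ceilings;
#' ridge screening of every extractor layer; base-model choice by
#' integrative benchmarking; per-region layer choice from the homologous
#' region; hyperparameter grid search on homologous data; final 10-fold
#' scoring with a fresh seed; within-category predictivity, shuffle
#' baselines, region-level RDM comparison; and probing of the locked
#' face-region model (screening a fresh image stream for enrichment,
#' block subsampling, an occlusion importance map, optionally a toy
#' synthesis).  Every artifact is written under `config$out_dir` together
#' with a provenance record; rerunning with the same config reproduces
#' identical numeric outputs.
#'
#' @param config A [pipeline_config()] (see [demo_config()] for a
#'   desk-scale version).
#' @return Invisibly, a list with the key results (`lock`, `final_scores`,
#'   `ceilings`, `rdm_similarity`, `screening`, `enrichment`, paths).
#' @export
run_pipeline <- function(config = demo_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(stimuli = split_seed(cfg$seed, "stimuli"),
                extractor = split_seed(cfg$seed, "extractor"),
                truth = split_seed(cfg$seed, "truth"),
                ceiling = split_seed(cfg$seed, "ceiling"),
                grid = split_seed(cfg$seed, "grid"),
                final = split_seed(cfg$seed, "final"),
                shuffle = split_seed(cfg$seed, "shuffle"),
                probe = split_seed(cfg$seed, "probe"))

  # --- simulate ------------------------------------------------------------
  stimuli <- make_stimulus_set(cfg$counts_per_category, cfg$image_size,
                               cfg$normalizer_count, seed = seeds$stimuli)
  extractors <- lapply(seq_len(cfg$n_extractors), function(i)
    make_toy_extractor(cfg$layer_specs, seed = seeds$extractor + i))
  names(extractors) <- sprintf("ext_%02d", seq_len(cfg$n_extractors))
  gen_extractor <- extractors[[1L]]

  frois <- c("lFFA", "rFFA", "lEBA", "rEBA", "lPPA", "rPPA")
  froi_category <- c(lFFA = "face", rFFA = "face", lEBA = "body",
                     rEBA = "body", lPPA = "scene", rPPA = "scene")
  homologous <- c(lFFA = "rFFA", rFFA = "lFFA", lEBA = "rEBA",
                  rEBA = "lEBA", lPPA = "rPPA", rPPA = "lPPA")
  offsets <- list(l = c(-0.5, -0.5), r = c(0.5, 0.5))

  truths <- lapply(frois, function(fr)
    category_tuned_truth(gen_extractor, cfg$true_layer, stimuli,
                         froi_category[[fr]], noise_sd = cfg$noise_sd,
                         n_runs = cfg$n_runs,
                         seed = split_seed(seeds$truth, fr),
                         offset = offsets[[substr(fr, 1, 1)]]))
  names(truths) <- frois

  ids <- stimuli$manifest$stimulus_id
  cats <- stats::setNames(stimuli$manifest$category, ids)
  sessions <- assign_sessions(ids, stimuli$normalizer_ids, cfg$session_size)

  clean <- lapply(truths, function(tr)
    simulate_froi_responses(stimuli, gen_extractor, cfg$true_layer, tr))
  run_data <- lapply(seq_len(cfg$n_subjects), function(s) {
    lapply(frois, function(fr) {
      tr <- truths[[fr]]
      tr$seed <- split_seed(tr$seed, paste0("subj", s))
      simulate_froi_responses(stimuli, gen_extractor, cfg$true_layer,
                              tr)$runs
    })
  })
  tables <- lapply(seq_len(cfg$n_subjects), function(s) {
    vals <- vapply(seq_along(frois), function(i)
      rowMeans(run_data[[s]][[i]]), numeric(length(ids)))
    colnames(vals) <- frois
    rownames(vals) <- ids
    normalize_session(beta_table(vals, subject = sprintf("subj_%02d", s),
                                 categories = cats, sessions = sessions),
                      stimuli$normalizer_ids)
  })
  pooled <- pool_subjects(tables)
  for (s in seq_along(tables))
    write_beta_table(tables[[s]],
                     file.path(cfg$out_dir, sprintf("betas_subj_%02d.csv", s)))
  write_beta_table(pooled, file.path(cfg$out_dir, "betas_pooled.csv"))

  # --- reliability ---------------------------------------------------------
  ceilings <- lapply(frois, function(fr) {
    i <- match(fr, frois)
    pooled_runs <- Reduce(`+`, lapply(run_data, `[[`, i)) / cfg$n_subjects
    split_half_ceiling(pooled_runs, cfg$n_ceiling_splits,
                       seed = split_seed(seeds$ceiling, fr))
  })
  names(ceilings) <- frois
  for (fr in frois)
    write_ceiling(ceilings[[fr]],
                  file.path(cfg$out_dir, sprintf("ceiling_%s.json", fr)))
  xsub <- cross_subject_ceiling(tables, "pooled_vs_heldout")
  utils::write.csv(xsub, file.path(cfg$out_dir, "ceiling_cross_subject.csv"),
                   row.names = FALSE)

  # --- screen & lock -------------------------------------------------------
  scores <- screen_layers(extractors, stimuli, pooled,
                          lambda = cfg$screen_lambda, k = cfg$screen_k,
                          seeds = cfg$screen_seeds)
  write_scores(scores, file.path(cfg$out_dir, "screen_scores.csv"))
  base_model <- as.character(select_base_model(scores))
  layers <- vapply(frois, function(fr)
    select_layer_cross_hemisphere(scores, base_model, homologous[[fr]]),
    character(1))

  feats_by_layer <- lapply(unique(layers), function(ly)
    extract_layer(extractors[[base_model]], stimuli, ly)[ids])
  names(feats_by_layer) <- unique(layers)

  lambdas <- lapply(frois, function(fr) {
    gs <- grid_search_hyperparams(
      feats_by_layer[[layers[[fr]]]], pooled$values[, homologous[[fr]]],
      grid = cfg$grid, k = cfg$grid_k,
      seed = split_seed(seeds$grid, fr), opt = cfg$opt)
    gs[c("lambda_s", "lambda_d")]
  })
  names(lambdas) <- frois
  lock <- list(base_model = base_model, layers = as.list(layers),
               lambdas = lambdas,
               seeds = list(screen = cfg$screen_seeds, grid = seeds$grid,
                            final = seeds$final))
  write_lockfile(lock, file.path(cfg$out_dir, "lockfile.json"))

  # --- final scoring & evaluation -----------------------------------------
  locking_seeds <- c(cfg$screen_seeds,
                     vapply(frois, function(fr) split_seed(seeds$grid, fr),
                            numeric(1)))
  final_scores <- lapply(frois, function(fr)
    final_score(feats_by_layer[[layers[[fr]]]], pooled$values[, fr],
                lambda_s = lambdas[[fr]]$lambda_s,
                lambda_d = lambdas[[fr]]$lambda_d,
                k = cfg$final_k, seed = split_seed(seeds$final, fr),
                opt = cfg$opt, locking_seeds = locking_seeds))
  names(final_scores) <- frois

  within_cat <- lapply(frois, function(fr)
    within_category_predictivity(final_scores[[fr]]$pred,
                                 pooled$values[, fr], unname(cats)))
  names(within_cat) <- frois
  shuffles <- lapply(frois, function(fr)
    shuffled_baseline(final_scores[[fr]]$pred, pooled$values[, fr],
                      unname(cats), n_iterations = cfg$n_shuffles,
                      seed = split_seed(seeds$shuffle, fr)))
  names(shuffles) <- frois
  shuffle_test <- wilcoxon_signed_rank(
    vapply(frois, function(fr) shuffles[[fr]]$observed_r, numeric(1)),
    vapply(frois, function(fr) mean(shuffles[[fr]]$shuffled_r), numeric(1)))

  obs_patterns <- t(pooled$values)                       # regions x stimuli
  pred_patterns <- t(vapply(frois, function(fr)
    final_scores[[fr]]$pred, numeric(length(ids))))
  colnames(pred_patterns) <- ids
  rdm_obs <- compute_rdm(obs_patterns)
  rdm_pred <- compute_rdm(pred_patterns)
  rdm_similarity <- compare_rdms(rdm_obs, rdm_pred)
  write_rdm(rdm_obs, file.path(cfg$out_dir, "rdm_observed.csv"))
  write_rdm(rdm_pred, file.path(cfg$out_dir, "rdm_predicted.csv"))

  eval_summary <- data.frame(
    froi = frois,
    final_r = vapply(frois, function(fr) final_scores[[fr]]$r, numeric(1)),
    ceiling = vapply(frois, function(fr) ceilings[[fr]]$mean, numeric(1)),
    shuffle_mean_r = vapply(frois, function(fr)
      mean(shuffles[[fr]]$shuffled_r), numeric(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(eval_summary,
                   file.path(cfg$out_dir, "evaluation_summary.csv"),
                   row.names = FALSE)

  # --- probing -------------------------------------------------------------
  probe_froi <- "lFFA"
  probe_layer <- layers[[probe_froi]]
  probe_fit <- fit_factorized(feats_by_layer[[probe_layer]],
                              pooled$values[, probe_froi],
                              lambda_s = lambdas[[probe_froi]]$lambda_s,
                              lambda_d = lambdas[[probe_froi]]$lambda_d,
                              opt = cfg$opt)
  write_mapping(probe_fit, file.path(cfg$out_dir, "mapping_lFFA.json"),
                layer = probe_layer, extractor_id = base_model,
                training_ids = ids)
  predictor <- make_predictor(probe_fit, extractors[[base_model]],
                              probe_layer)
  stream <- make_stimulus_set(cfg$screen_counts, cfg$image_size,
                              normalizer_count = 0,
                              seed = split_seed(seeds$probe, "stream"))
  stream_cats <- stats::setNames(stream$manifest$category,
                                 stream$manifest$stimulus_id)
  screening <- screen_images(predictor, stream$images,
                             sources = unname(stream_cats))
  utils::write.csv(screening$ranking,
                   file.path(cfg$out_dir, "screening_ranking.csv"),
                   row.names = FALSE)
  n_top <- max(1L, round(0.01 * nrow(screening$ranking)))
  pref <- froi_category[[probe_froi]]
  top_frac <- mean(stream_cats[screening$ranking$stimulus_id[seq_len(n_top)]]
                   == pref)
  base_rate <- mean(stream_cats == pref)
  enrichment <- top_frac / base_rate
  sub_ids <- subsample_top(screening, top_n = nrow(screening$ranking),
                           block = max(2L, nrow(screening$ranking) %/% 10L),
                           per_block = 2L)
  top_image <- stream$images[[screening$ranking$stimulus_id[1L]]]
  imap <- rise_importance(predictor, top_image, n_masks = cfg$n_masks,
                          seed = split_seed(seeds$probe, "masks"))
  utils::write.csv(as.data.frame(unclass(imap)),
                   file.path(cfg$out_dir, "importance_top_image.csv"),
                   row.names = FALSE)
  synthesis <- NULL
  if (cfg$synthesis_steps > 0L) {
    gen <- function(z) {
      h <- cfg$image_size[1]; w <- cfg$image_size[2]
      xs <- matrix(seq(-1, 1, length.out = h), h, w)
      ys <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
      bump <- exp(-((xs - z[1])^2 + (ys - z[2])^2) / 0.08)
      array(rep(bump, 3), dim = c(h, w, 3))
    }
    synthesis <- synthesize(
      gen, predictor,
      synthesis_config(steps = cfg$synthesis_steps, lr = 0.01, z_dim = 2L,
                       seed = split_seed(seeds$probe, "synth")))
  }

  provenance <- list(config = unclass(cfg)[setdiff(names(cfg), c("opt"))],
                     seeds = seeds, locked = lock,
                     version = as.character(utils::packageVersion("froienc")),
                     timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(provenance, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(stimuli = stimuli, extractors = extractors, lock = lock,
                 tables = tables, pooled = pooled, ceilings = ceilings,
                 final_scores = final_scores, within_category = within_cat,
                 shuffles = shuffles, shuffle_test = shuffle_test,
                 rdm_similarity = rdm_similarity, screening = screening,
                 enrichment = enrichment, subsampled = sub_ids,
                 importance = imap, synthesis = synthesis,
                 out_dir = cfg$out_dir))
}
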