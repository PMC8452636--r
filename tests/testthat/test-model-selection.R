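test_that("k-fold schemes partition items into near-equal seeded folds", {
  cv <- make_kfold(10, 5, seed = 1)
  expect_equal(sort(unique(cv$fold)), 1:5)
  expect_true(all(table(cv$fold) == 2))
  expect_identical(cv$fold, make_kfold(10, 5, seed = 1)$fold)
  expect_false(identical(cv$fold, make_kfold(10, 5, seed = 2)$fold))
  cv2 <- make_kfold(23, 10, seed = 3)
  expect_true(all(abs(table(cv2$fold) - 23 / 10) <= 1))
  expect_error(make_kfold(4, 5), "exceeds")
})

test_that("screening ranks the generating layer above noise features", {
  fx <- screen_fixture(seed = 11)
  # second extractor provides pure-noise feature spaces for the same stimuli
  noise_ex <- make_toy_extractor(list(list(name = "L1", H = 4, W = 4, D = 8)),
                                 seed = 999)
  scores <- screen_layers(list(gen = fx$setup$extractor, noise = noise_ex),
                          fx$setup$stimuli, fx$betas, k = 5, seeds = 1:2)
  gen_score <- scores$score[scores$extractor_id == "gen" &
                              scores$layer == "L1"]
  noise_score <- scores$score[scores$extractor_id == "noise"]
  expect_gt(gen_score, noise_score)
  # duplicated extractor under two ids scores identically
  scores_dup <- screen_layers(list(a = fx$setup$extractor,
                                   b = fx$setup$extractor),
                              fx$setup$stimuli, fx$betas, k = 5, seeds = 1:2)
  expect_equal(scores_dup$score[scores_dup$extractor_id == "a"],
               scores_dup$score[scores_dup$extractor_id == "b"])
})

test_that("base-model choice averages best-layer scores across regions", {
  tbl <- expand.grid(extractor_id = c("A", "B"), layer = c("l1", "l2"),
                     froi = paste0("r", 1:6), stringsAsFactors = FALSE)
  tbl$metric <- "pooled"; tbl$cv <- "x"
  # B wins on mean despite losing on regions r1, r2
  tbl$score <- ifelse(tbl$extractor_id == "A", 0.5, 0.7)
  tbl$score[tbl$extractor_id == "A" & tbl$froi %in% c("r1", "r2")] <- 0.9
  sel <- select_base_model(tbl)
  expect_equal(as.character(sel), "B")
  means <- attr(sel, "means")
  expect_equal(unname(means["A"]), mean(c(0.9, 0.9, 0.5, 0.5, 0.5, 0.5)))
  # single extractor selects itself
  expect_equal(as.character(select_base_model(tbl[tbl$extractor_id == "A", ])),
               "A")
  # leave-one-region-out stability on this fixture
  for (fr in paste0("r", 3:6))
    expect_equal(as.character(select_base_model(tbl[tbl$froi != fr, ])), "B")
  expect_error(select_base_model(tbl[!(tbl$extractor_id == "B" &
                                         tbl$froi == "r6"), ]),
               "incomplete screen")
})

test_that("layer locking reads only the homologous region's scores", {
  tbl <- expand.grid(extractor_id = "A", layer = c("l1", "l2", "l3"),
                     froi = c("lFFA", "rFFA"), stringsAsFactors = FALSE)
  tbl$metric <- "pooled"; tbl$cv <- "x"
  tbl$score <- c(0.1, 0.9, 0.2, 0.8, 0.3, 0.4)  # rFFA argmax: l1 (0.8)
  pick <- select_layer_cross_hemisphere(tbl, "A", "rFFA")
  expect_equal(pick, "l1")
  # adversarial permutation of the target region's own scores: no effect
  tbl2 <- tbl
  tbl2$score[tbl2$froi == "lFFA"] <- rev(tbl2$score[tbl2$froi == "lFFA"])
  expect_equal(select_layer_cross_hemisphere(tbl2, "A", "rFFA"), pick)
  expect_error(select_layer_cross_hemisphere(tbl, "A", "rPPA"),
               "incomplete screen")
})

test_that("synthetic hemisphere pair locks the generating layer", {
  hits <- vapply(1:10, function(s) {
    fx <- screen_fixture(seed = s, noise_sd = 0.3)
    # homologous "hemisphere": same clean signal, independent noise
    y_hom <- fx$y + stats::rnorm(length(fx$y), sd = 0.3)
    vals <- cbind(target = fx$betas$values[, 1], homolog = y_hom)
    betas2 <- beta_table(vals)
    scores <- screen_layers(list(gen = fx$setup$extractor),
                            fx$setup$stimuli, betas2, k = 5, seeds = 1:3)
    select_layer_cross_hemisphere(scores, "gen", "homolog") == "L1"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("hyperparameter grid search matches an exhaustive oracle", {
  expect_equal(default_lambda_grid()[c(1, 6)], c(0.01, 100))
  expect_length(default_lambda_grid(), 6L)

  fx <- recovery_fixture(n = 40, H = 2, W = 2, D = 4, seed = 41,
                         noise_sd = 0.8)
  grid <- c(0.01, 1)
  opt <- opt_config(max_iter = 200, seed = 7)
  gs <- grid_search_hyperparams(fx$features, fx$y, grid = grid, k = 4,
                                seed = 9, opt = opt)
  expect_equal(nrow(gs$results), 4L)   # 2 x 2 pairs all evaluated
  # independently coded exhaustive re-evaluation with the same folds
  cv <- make_kfold(40, 4, seed = 9)
  oracle <- vapply(seq_len(nrow(gs$results)), function(i) {
    pred <- rep(NA_real_, 40)
    for (f in 1:4) {
      te <- which(cv$fold == f); tr <- which(cv$fold != f)
      mp <- fit_factorized(fx$features[tr], fx$y[tr],
                           gs$results$lambda_s[i], gs$results$lambda_d[i],
                           opt)
      pred[te] <- predict(mp, fx$features[te])
    }
    stats::cor(pred, fx$y)
  }, numeric(1))
  expect_equal(gs$results$r, oracle, tolerance = 1e-10)
  best <- which.max(oracle)
  expect_equal(c(gs$lambda_s, gs$lambda_d),
               c(gs$results$lambda_s[best], gs$results$lambda_d[best]))
  # selected pair is at least as good as the grid corner
  corner <- oracle[gs$results$lambda_s == 0.01 & gs$results$lambda_d == 0.01]
  expect_gte(max(oracle), corner)
  # degenerate 1-point grid short-circuits
  one <- grid_search_hyperparams(fx$features, fx$y, grid = 0.5)
  expect_equal(c(one$lambda_s, one$lambda_d), c(0.5, 0.5))
})

test_that("final scoring recovers planted signal and nulls out permutations", {
  fx <- recovery_fixture(n = 120, H = 2, W = 2, D = 4, seed = 43)
  sc <- final_score(fx$features, fx$y, 1e-6, 1e-6, k = 10, seed = 77,
                    opt = opt_config(max_iter = 1500))
  expect_gte(sc$r, 0.99)
  expect_equal(sc$provenance$seed, 77)
  expect_warning(final_score(fx$features, fx$y, 1e-6, 1e-6, seed = 5,
                             opt = opt_config(max_iter = 10),
                             locking_seeds = c(5, 9)),
                 "protocol violation")
  # permuted responses: correlations concentrate near zero
  withr::with_seed(44, {
    rs <- vapply(1:5, function(i)
      final_score(fx$features, sample(fx$y), 0.01, 0.01, k = 5,
                  seed = 100 + i, opt = opt_config(max_iter = 150))$r,
      numeric(1))
  })
  expect_lt(mean(abs(rs)), 2.6 / sqrt(120))
})

test_that("generalization schemes score the designed train/test pairs", {
  withr::with_seed(51, {
    n <- 40; D <- 5
    feats <- lapply(seq_len(n), function(i) array(stats::rnorm(D), c(1, 1, D)))
    names(feats) <- sprintf("s%02d", seq_len(n))
    beta <- stats::rnorm(D)
    clean <- vapply(feats, function(A) sum(beta * A), numeric(1))
    ids <- names(feats)
    mk <- function(y, s) beta_table(matrix(y, ncol = 1,
                                           dimnames = list(ids, "roi")),
                                    subject = s)
    # identical noiseless subjects: all schemes near-perfect with ridge
    tabs0 <- lapply(1:3, function(s) mk(clean, paste0("s", s)))
    for (sch in c("pool_heldout_subject", "within_subject",
                  "cross_subject_transfer")) {
      res <- generalization_schemes(feats, tabs0, "roi", sch, k = 5,
                                    seed = 2, mapper = "ridge",
                                    lambda = 1e-8)
      expect_true(all(res$r >= 0.99), info = sch)
    }
    tabs4 <- lapply(1:4, function(s) mk(clean, paste0("s", s)))
    res4 <- generalization_schemes(feats, tabs4, "roi",
                                   "cross_subject_transfer", k = 5, seed = 2,
                                   mapper = "ridge", lambda = 1e-8)
    expect_equal(nrow(res4), 12L)

    # noisy subjects (SNR 1): pooled training beats single-subject transfer
    diffs <- vapply(1:10, function(rep) {
      tabs <- lapply(1:4, function(s)
        mk(clean + stats::rnorm(n, sd = stats::sd(clean)), paste0("s", s)))
      pool_r <- mean(generalization_schemes(feats, tabs, "roi",
                                            "pool_heldout_subject", k = 5,
                                            seed = rep, mapper = "ridge",
                                            lambda = 0.01)$r)
      xfer_r <- mean(generalization_schemes(feats, tabs, "roi",
                                            "cross_subject_transfer", k = 5,
                                            seed = rep, mapper = "ridge",
                                            lambda = 0.01)$r)
      pool_r - xfer_r
    }, numeric(1))
    expect_gt(mean(diffs), 0)
  })
})
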