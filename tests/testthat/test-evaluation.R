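test_that("predictivity is the Pearson correlation with degenerate flags", {
  expect_equal(predictivity(c(1, 2, 3, 5), c(1, 2, 3, 5))$r, 1)
  expect_equal(predictivity(c(1, 2, 3), c(6, 4, 2))$r, -1)
  s <- predictivity(c(1, 2, 3), c(4, 4, 4))
  expect_true(s$undefined)
  expect_true(is.na(s$r))
  expect_error(predictivity(1:4, 1:5), "lengths differ")
  expect_error(predictivity(1:2, 1:2), "at least 3")
})

test_that("voxelwise predictivity is the median of per-voxel correlations", {
  withr::with_seed(61, {
    n <- 2000
    sig <- stats::rnorm(n)
    # noise titration: per-voxel r = 1/sqrt(1 + sigma^2) for unit signal
    target_r <- c(0.2, 0.5, 0.9)
    sigmas <- sqrt(1 / target_r^2 - 1)
    obs <- vapply(sigmas, function(s) sig + stats::rnorm(n, sd = s),
                  numeric(n))
    pred <- matrix(sig, n, 3)
    vs <- voxelwise_predictivity(pred, obs)
    expect_equal(vs$r, 0.5, tolerance = 0.05)
    expect_equal(vs$per_voxel, target_r, tolerance = 0.06)
  })
  # single voxel reduces to plain predictivity
  expect_equal(voxelwise_predictivity(matrix(1:5), matrix(c(2, 1, 4, 3, 5)))$r,
               predictivity(1:5, c(2, 1, 4, 3, 5))$r)
  # even voxel count: mean of the two central order statistics
  p <- matrix(rep(1:10, 4), 10, 4)
  o <- cbind(1:10, c(1:9, 5), 10:1, c(10:2, 5))
  vs2 <- voxelwise_predictivity(p, o)
  expect_equal(vs2$r, mean(sort(vs2$per_voxel)[2:3]))
})

test_that("within-category predictivity isolates image-level structure", {
  withr::with_seed(62, {
    cats <- rep(c("face", "body", "scene"), each = 10)
    obs <- stats::rnorm(30) + 3 * (cats == "face")
    # category-means-only predictor: no within-category variance
    pred_cm <- stats::ave(obs, cats)
    wc <- within_category_predictivity(pred_cm, obs, cats)
    for (s in wc) expect_true(s$undefined || abs(s$r) < 0.3)
    # the observations themselves: perfect within-category recovery
    wc2 <- within_category_predictivity(obs, obs, cats)
    for (s in wc2) expect_gte(s$r, 0.8)
    expect_warning(
      within_category_predictivity(1:12, 1:12, rep(c("a", "b"), c(10, 2))),
      "skipped")
  })
})

test_that("within-category shuffles detect image-level predictivity", {
  withr::with_seed(63, {
    cats <- rep(c("face", "body"), each = 15)
    obs <- stats::rnorm(30) + 2 * (cats == "face")
    # shuffle-invariance for a category-mean predictor, exactly
    sb0 <- shuffled_baseline(stats::ave(obs, cats), obs, cats, 50, seed = 1)
    expect_true(all(sb0$shuffled_r == sb0$observed_r))
    # planted image-level signal at zero noise beats all 100 shuffles
    sb1 <- shuffled_baseline(obs, obs, cats, 100, seed = 2)
    expect_equal(sb1$n_iterations, 100L)
    expect_gt(sb1$observed_r, max(sb1$shuffled_r))
  })
})

test_that("shuffle null is calibrated when predictor carries no signal", {
  withr::with_seed(64, {
    cats <- rep(c("a", "b"), each = 20)
    cover <- vapply(1:60, function(i) {
      obs <- stats::rnorm(40)
      pred <- stats::rnorm(40)
      sb <- shuffled_baseline(pred, obs, cats, 100, seed = i)
      q <- stats::quantile(sb$shuffled_r, c(0.025, 0.975))
      sb$observed_r >= q[1] && sb$observed_r <= q[2]
    }, logical(1))
    expect_gt(mean(cover), 0.85)
  })
})

test_that("RDMs satisfy the metric axioms and known distances", {
  pats <- rbind(c(0, 3, 1), c(0, 4, 1))       # 2 targets x 3 stimuli
  colnames(pats) <- c("a", "b", "c")
  rdm <- compute_rdm(pats)
  expect_equal(unname(rdm["a", "b"]), 5)       # sqrt(3^2 + 4^2)
  expect_equal(diag(unclass(rdm)), stats::setNames(c(0, 0, 0), c("a", "b", "c")))
  expect_true(isSymmetric(unclass(rdm)))
  expect_true(all(rdm >= 0))
  # identical patterns: all-zero RDM
  same <- matrix(1, 3, 4, dimnames = list(NULL, letters[1:4]))
  expect_true(all(compute_rdm(same) == 0))
  # sampled triangle inequality on a random RDM
  withr::with_seed(65, {
    r <- compute_rdm(matrix(stats::rnorm(5 * 12), 5, 12,
                            dimnames = list(NULL, paste0("s", 1:12))))
    for (k in 1:30) {
      ijk <- sample(12, 3)
      expect_lte(r[ijk[1], ijk[3]],
                 r[ijk[1], ijk[2]] + r[ijk[2], ijk[3]] + 1e-12)
    }
  })
  expect_error(compute_rdm(matrix(c(1, NA, 2, 3), 2, 2,
                                  dimnames = list(NULL, c("a", "b")))),
               "missing")
})

test_that("RDM comparison is a rank correlation on the upper triangle", {
  withr::with_seed(66, {
    r1 <- compute_rdm(matrix(stats::rnorm(3 * 4), 3, 4,
                             dimnames = list(NULL, letters[1:4])))
  })
  expect_equal(compare_rdms(r1, r1), 1)
  sq <- structure(unclass(r1)^2, class = class(r1))
  expect_equal(compare_rdms(r1, sq), 1)   # monotone-transform invariance
  # brute-force rank oracle on the 6 upper-triangle pairs
  r2 <- r1; r2[] <- 0
  vals <- c(2.5, 1.0, 4.0, 0.5, 3.0, 6.0)
  r2[upper.tri(r2)] <- vals
  r2 <- structure(unclass(r2) + t(unclass(r2)), class = class(r1))
  dimnames(r2) <- dimnames(r1)
  a <- unclass(r1)[upper.tri(r1)]
  rank_a <- order(order(a)); rank_b <- order(order(vals))
  oracle <- 1 - 6 * sum((rank_a - rank_b)^2) / (6 * (6^2 - 1))
  expect_equal(compare_rdms(r1, r2), oracle, tolerance = 1e-12)
  expect_error(compare_rdms(r1, compute_rdm(matrix(1:6, 2, 3,
    dimnames = list(NULL, c("x", "y", "z"))))), "sizes differ")
})

test_that("exact signed-rank test agrees with brute-force enumeration", {
  # n = 6, all differences one sign: minimum attainable two-sided p
  res <- wilcoxon_signed_rank(1:6 + 10, 1:6)
  expect_equal(res$p_value, 2 / 2^6)
  expect_true(res$exact)
  # all-zero differences
  expect_warning(res0 <- wilcoxon_signed_rank(1:4, 1:4), "zero")
  expect_equal(res0$p_value, 1)
  # brute-force oracle over all sign assignments, including ties
  brute_p <- function(d) {
    d <- d[d != 0]; n <- length(d)
    rk <- rank(abs(d))
    W <- sum(rk[d > 0]); mu <- sum(rk) / 2
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- as.numeric(signs %*% rk)
    mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
  }
  withr::with_seed(67, {
    for (i in 1:5) {
      d <- round(stats::rnorm(8), 1)   # rounding induces occasional ties
      x <- d; y <- rep(0, 8)
      expect_equal(wilcoxon_signed_rank(x, y)$p_value, brute_p(d),
                   tolerance = 1e-12)
    }
  })
  # tie-free case cross-checked against the standard implementation
  x <- c(1.3, 2.1, -0.5, 4.2, 0.7, -2.2, 3.3)
  expect_equal(wilcoxon_signed_rank(x, rep(0, 7))$p_value,
               stats::wilcox.test(x, exact = TRUE)$p.value)
  # large n: normal approximation stays close to wilcox.test's
  withr::with_seed(68, {
    xl <- stats::rnorm(40, mean = 0.3)
    expect_equal(wilcoxon_signed_rank(xl, rep(0, 40))$p_value,
                 stats::wilcox.test(xl, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 0.02)
  })
})

test_that("rater filtering matches the analytic attenuation prediction", {
  withr::with_seed(69, {
    scores <- stats::setNames(stats::rnorm(60), sprintf("s%02d", 1:60))
    # noise at half the signal sd: expected retest r = 1/(1 + 0.25) = 0.8
    noise_sd <- 0.5 * stats::sd(scores)
    rt <- simulate_raters(scores, n_raters = 200, rater_noise_sd = noise_sd,
                          seed = 5)
    fl <- filter_raters(rt, threshold = 0.8)
    expect_equal(mean(fl$reliability), 0.8, tolerance = 0.05)
    # thresholds far below / above the expected reliability retain nearly
    # all / none of the raters
    expect_gte(length(filter_raters(rt, threshold = 0.6)$retained) / 200, 0.9)
    expect_lte(length(filter_raters(rt, threshold = 0.95)$retained) / 200, 0.1)
  })
  # constant rater has undefined reliability and is excluded
  const <- data.frame(rater_id = "r1",
                      stimulus_id = c(letters[1:5], letters[1:2]),
                      phase = c(rep("first", 5), rep("repeat", 2)),
                      rating = 0.5)
  fl2 <- filter_raters(const)
  expect_equal(fl2$excluded_undefined, "r1")
  expect_length(fl2$retained, 0L)
})

test_that("external predictors score as mean per-subject correlation", {
  withr::with_seed(70, {
    ids <- sprintf("s%02d", 1:40)
    signal <- stats::setNames(stats::rnorm(40), ids)
    cats <- rep(c("a", "b"), each = 20)
    tabs <- lapply(1:3, function(s)
      beta_table(matrix(signal + stats::rnorm(40, sd = 0.3), ncol = 1,
                        dimnames = list(ids, "roi")),
                 subject = paste0("s", s)))
    # each subject's own responses as predictor: r = 1
    self_r <- vapply(seq_along(tabs), function(s)
      score_external_predictor(stats::setNames(tabs[[s]]$values[, 1], ids),
                               tabs[s], "roi")$r, numeric(1))
    expect_true(all(self_r == 1))
    # category-mean predictor loses to the full-signal predictor
    full <- score_external_predictor(signal, tabs, "roi")
    coarse <- score_external_predictor(
      stats::setNames(stats::ave(signal, cats), ids), tabs, "roi")
    expect_gt(full$r, coarse$r)
    expect_length(full$per_subject, 3L)
  })
})

test_that("region-mean and voxel-median metrics rank models concordantly", {
  withr::with_seed(71, {
    n <- 150; n_vox <- 8
    sig <- stats::rnorm(n)
    vox_obs <- matrix(sig, n, n_vox) + matrix(stats::rnorm(n * n_vox, sd = 1),
                                              n, n_vox)
    roi_obs <- rowMeans(vox_obs)
    # 10 synthetic models of decreasing quality
    model_noise <- seq(0.1, 3, length.out = 10)
    froi_r <- numeric(10); vox_r <- numeric(10)
    for (i in 1:10) {
      pred <- sig + stats::rnorm(n, sd = model_noise[i])
      froi_r[i] <- predictivity(pred, roi_obs)$r
      vox_r[i] <- voxelwise_predictivity(matrix(pred, n, n_vox), vox_obs)$r
    }
    expect_gte(stats::cor(froi_r, vox_r, method = "spearman"), 0.9)
  })
})
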