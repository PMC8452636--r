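test_that("screening ranks by score with deterministic id tie-breaks", {
  withr::with_seed(81, {
    imgs <- lapply(1:200, function(i) array(stats::runif(8 * 8 * 3),
                                            c(8, 8, 3)))
    names(imgs) <- sprintf("im%04d", sample(1000, 200))
    pred <- function(img) round(mean(img), 3)   # rounding induces ties
    sr <- screen_images(pred, imgs)
    # brute-force sort oracle
    scores <- vapply(imgs, pred, numeric(1))
    ord <- order(-scores, names(imgs))
    expect_equal(sr$ranking$stimulus_id, names(imgs)[ord])
    expect_true(all(diff(sr$ranking$score) <= 0))
    # order invariance: permuting the input stream changes nothing
    perm <- sample(200)
    sr2 <- screen_images(pred, imgs[perm])
    expect_equal(sr2$ranking, sr$ranking)
    # constant predictor: pure id-order ranking
    sr3 <- screen_images(function(img) 1, imgs)
    expect_equal(sr3$ranking$stimulus_id, sort(names(imgs)))
    # histogram counts cover every screened image
    expect_equal(sum(sr$histograms$default$counts), 200L)
    # failing images are skipped with a count, not fatal
    sr4 <- screen_images(function(img) if (mean(img) > 0.5) stop("bad")
                         else mean(img), imgs)
    expect_equal(sr4$n_skipped + nrow(sr4$ranking), 200L)
  })
})

test_that("block subsampling keeps the best of each rank block", {
  fake <- fake_screening(stats::rnorm(100000))
  ids <- subsample_top(fake, top_n = 100000, block = 1000, per_block = 2)
  expect_length(ids, 200L)
  # hand enumeration on a small configuration: ranks {1, 2, 6, 7}
  fake10 <- fake_screening(10:1)
  expect_equal(subsample_top(fake10, top_n = 10, block = 5, per_block = 2),
               fake10$ranking$stimulus_id[c(1, 2, 6, 7)])
  # block = per_block = 1 over everything is the identity
  expect_equal(subsample_top(fake10, top_n = 10, block = 1, per_block = 1),
               fake10$ranking$stimulus_id)
  expect_error(subsample_top(fake10, top_n = 10, block = 2, per_block = 3),
               "per_block")
  expect_error(subsample_top(fake10, top_n = 99), "exceeds")
})

test_that("exclusion rescreen equals the set-difference-then-sort oracle", {
  withr::with_seed(82, {
    fake <- fake_screening(stats::rnorm(500),
                           sources = rep(c("faces", "objects"), 250))
    excl <- sample(fake$ranking$stimulus_id, 150)
    got <- exclusion_rescreen(fake, excluded_ids = excl, k = 100)
    oracle <- setdiff(fake$ranking$stimulus_id, excl)[1:100]
    expect_equal(got, oracle)
    expect_length(intersect(got, excl), 0L)
    # empty exclusion is plain top-k
    expect_equal(exclusion_rescreen(fake, k = 10),
                 fake$ranking$stimulus_id[1:10])
    # excluding a whole source label
    got_src <- exclusion_rescreen(fake, excluded_source = "faces", k = 50)
    expect_true(all(fake$ranking$source[match(got_src,
                                              fake$ranking$stimulus_id)]
                    == "objects"))
    expect_warning(
      out <- exclusion_rescreen(fake, excluded_source = c("faces", "objects")),
      "removed every")
    expect_length(out, 0L)
  })
})

test_that("localizer-contrast unit selection finds planted tuned channels", {
  setup <- tiny_setup(seed = 83)
  sel <- select_selective_units(setup$extractor, "L1", setup$stimuli, "face")
  feats <- extract_layer(setup$extractor, setup$stimuli, "L1")
  cats <- setup$stimuli$manifest$category
  flat <- t(vapply(feats, as.numeric, numeric(4 * 4 * 8)))
  # direct mean-comparison oracle per unit
  for (u in seq_len(ncol(flat))) {
    mns <- tapply(flat[, u], cats, mean)
    is_sel <- all(mns["face"] > mns[names(mns) != "face"])
    expect_equal(u %in% sel$units$flat, is_sel)
  }
  # a constant unit is never selected (identical category means)
  expect_false(any(apply(flat[, sel$units$flat, drop = FALSE], 2,
                         stats::sd) == 0))
  # pseudo-region response prefers the target category on average
  if (nrow(sel$units) > 0) {
    pr <- pseudo_froi_response(setup$extractor, "L1", sel, setup$stimuli)
    mns <- tapply(pr, cats, mean)
    expect_equal(names(which.max(mns)), "face")
  }
})

test_that("pseudo-region control loop runs the full screening cycle", {
  setup <- tiny_setup(seed = 84)
  sel <- select_selective_units(setup$extractor, "L1", setup$stimuli, "face")
  expect_gt(nrow(sel$units), 0)   # planted patterns guarantee tuned units
  y <- pseudo_froi_response(setup$extractor, "L1", sel, setup$stimuli)
  feats <- extract_layer(setup$extractor, setup$stimuli, "L2")
  fit <- fit_factorized(feats, y, 0.01, 0.01,
                        opt_config(max_iter = 300, seed = 1))
  predictor <- make_predictor(fit, setup$extractor, "L2")
  stream <- make_stimulus_set(c(face = 10, body = 10, scene = 10,
                                object = 10), c(16, 16), 0, seed = 85)
  sr <- screen_images(predictor, stream$images,
                      sources = stream$manifest$category)
  top <- sr$ranking$stimulus_id[1:10]
  cats <- stats::setNames(stream$manifest$category,
                          stream$manifest$stimulus_id)
  frac_nontarget <- mean(cats[top] != "face")
  expect_gte(frac_nontarget, 0)
  expect_lte(frac_nontarget, 1)
})

test_that("importance maps localize a linear predictor's support", {
  img <- array(1, c(16, 16, 3))
  # predictor = total intensity in the top-left quadrant
  predq <- function(im) sum(im[1:8, 1:8, ])
  im <- rise_importance(predq, img, n_masks = 2000, seed = 3)
  expect_identical(dim(unclass(im)), c(16L, 16L))
  expect_equal(mean(im), 0, tolerance = 1e-12)   # mean-centered
  inside <- mean(im[1:8, 1:8]); outside <- mean(im[9:16, 9:16])
  expect_gt(inside, outside)
  expect_gt(inside - outside, 5)   # strong contrast, far beyond MC noise
  # determinism
  im2 <- rise_importance(predq, img, n_masks = 2000, seed = 3)
  expect_identical(unclass(im), unclass(im2))
  # constant predictor: centered map is only mask-sampling residue
  imc <- rise_importance(function(x) 1, img, n_masks = 2000, seed = 4)
  expect_lt(max(abs(imc)), 0.1)
  expect_error(make_mask_set(10, c(16, 16), p = 1), "degenerate")
})

test_that("Monte-Carlo error of importance maps scales as 1/sqrt(N)", {
  img <- array(1, c(16, 16, 3))
  predq <- function(im) sum(im[1:8, 1:8, ])
  Ns <- c(500, 2000, 8000)
  mc_sd <- vapply(Ns, function(N) {
    reps <- vapply(1:4, function(r)
      as.numeric(rise_importance(predq, img, n_masks = N,
                                 seed = 100 * r + N)),
      numeric(256))
    mean(apply(reps, 1, stats::sd))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(mc_sd) ~ log(Ns)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.15)
})

test_that("synthesis climbs a concave toy objective to its maximum", {
  # generator: Gaussian bump centered at z; encoder: intensity at center
  gen <- function(z) {
    xs <- matrix(seq(-1, 1, length.out = 16), 16, 16)
    ys <- t(xs)
    array(rep(exp(-((xs - z[1])^2 + (ys - z[2])^2) / 0.1), 3), c(16, 16, 3))
  }
  target <- c(16 %/% 2, 16 %/% 2)
  pred <- function(im) im[target[1], target[2], 1]
  res <- synthesize(gen, pred,
                    synthesis_config(steps = 500, lr = 0.01, z_dim = 2,
                                     seed = 4))
  analytic_max <- 1   # bump exactly centered on the probed pixel
  expect_gte(utils::tail(res$trace, 1), 0.99 * analytic_max)
  expect_gte(utils::tail(res$trace, 1), res$trace[1])
  # running maximum of the activation trace is non-decreasing
  expect_true(all(diff(cummax(res$trace)) >= 0))
  expect_length(res$trace, 501L)
  # determinism of the seeded initialization
  res2 <- synthesize(gen, pred,
                     synthesis_config(steps = 5, lr = 0.01, z_dim = 2,
                                      seed = 4))
  expect_equal(res2$z + 0, res2$z)  # finite
  expect_equal(res$trace[1], res2$trace[1])
})

test_that("class-vector initialization follows the scaled softmax scheme", {
  calls <- new.env(); calls$cls <- NULL
  gen <- function(z, cls) { calls$cls <- cls; array(sum(z), c(4, 4, 3)) }
  pred <- function(im) mean(im)
  res <- synthesize(gen, pred,
                    synthesis_config(steps = 1, lr = 1e-6, z_dim = 2,
                                     class_dim = 10, alpha = 0.05, seed = 9))
  init_cls <- res$class_vector
  expect_length(init_cls, 10L)
  # after one near-zero step the class vector still sums to ~alpha
  expect_equal(sum(init_cls), 0.05, tolerance = 1e-3)
  expect_true(all(init_cls > 0))
})
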