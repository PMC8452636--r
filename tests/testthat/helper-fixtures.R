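# Shared fixture builders.  Everything is generated in code under fixed
# seeds; nothing is read from disk.

# Small catalog + extractor pair used across module tests.
tiny_setup <- function(seed = 1L, counts = c(face = 8, body = 8, scene = 8,
                                             object = 8),
                       image_size = c(16L, 16L), normalizers = 4L) {
  stimuli <- make_stimulus_set(counts, image_size, normalizers, seed = seed)
  extractor <- make_toy_extractor(
    list(list(name = "L1", H = 4, W = 4, D = 8),
         list(name = "L2", H = 2, W = 2, D = 16)), seed = seed)
  list(stimuli = stimuli, extractor = extractor)
}

# Raw tensor fixture with a known factorized generator (no image pipeline):
# n iid Gaussian tensors plus the noiseless factorized responses.
recovery_fixture <- function(n = 200L, H = 4L, W = 4L, D = 8L, seed = 1L,
                             noise_sd = 0) {
  withr::with_seed(seed, {
    feats <- lapply(seq_len(n), function(i)
      array(stats::rnorm(H * W * D), c(H, W, D)))
    names(feats) <- sprintf("s%04d", seq_len(n))
    m <- matrix(stats::runif(H * W), H, W)
    w <- stats::rnorm(D)
    b <- 0.7
    y <- vapply(feats, function(A) {
      pooled <- vapply(seq_len(D), function(d)
        sum(m * A[, , d]) / (H * W), numeric(1))
      b + sum(w * pooled)
    }, numeric(1))
    if (noise_sd > 0) y <- y + stats::rnorm(n, sd = noise_sd)
    list(features = feats, y = y, m = m, w = w, b = b)
  })
}

# Catalog + extractor + responses planted in layer L1 of the extractor,
# packaged for screening/locking tests.
screen_fixture <- function(seed = 11, noise_sd = 0) {
  setup <- tiny_setup(seed = seed)
  feats <- extract_layer(setup$extractor, setup$stimuli, "L1")
  withr::with_seed(seed + 100, {
    m <- matrix(stats::runif(16), 4, 4)
    w <- stats::rnorm(8)
    y <- vapply(feats, function(A) {
      pooled <- vapply(1:8, function(d) sum(m * A[, , d]) / 16, numeric(1))
      sum(w * pooled)
    }, numeric(1))
    y <- y / stats::sd(y)
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), sd = noise_sd)
  })
  ids <- names(feats)
  vals <- matrix(y, ncol = 1, dimnames = list(ids, "roi"))
  list(setup = setup, feats = feats, betas = beta_table(vals), y = y)
}

# A screening_result built directly from a score vector (for ranking
# arithmetic that does not need real images).
fake_screening <- function(scores, sources = "default") {
  ids <- sprintf("img_%06d", seq_along(scores))
  df <- data.frame(stimulus_id = ids, score = scores,
                   source = rep(sources, length.out = length(scores)),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$stimulus_id), ]
  df$rank <- seq_len(nrow(df))
  structure(list(ranking = df[, c("rank", "stimulus_id", "score", "source")],
                 histograms = list(), n_skipped = 0L),
            class = "screening_result")
}
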