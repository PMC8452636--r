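#' Generate a seeded synthetic stimulus catalog
#'
#' Builds a catalog of small RGB images in four categories (face, body,
#' scene, object), each category carrying a distinct planted pattern — a
#' grating of category-specific orientation and spatial frequency confined to
#' a category-specific quadrant — on top of seeded pixel noise.  The planted
#' signatures guarantee that toy feature extractors develop category-tuned
#' channels, so category selectivity, localizer-style unit selection and
#' screening enrichment are all testable downstream.
#'
#' A subset of stimuli is designated as session normalizers, mirroring the
#' design in which a fixed set of images repeats in every scanning session
#' and anchors the per-session standardization of response estimates.
#'
#' @param counts_per_category Named integer vector or list giving the number
#'   of stimuli per category.  Names must be a subset of
#'   `c("face", "body", "scene", "object")`.  Defaults to the event-related
#'   catalog composition: 25 faces, 50 bodies, 50 scenes, 65 objects.
#' @param image_size Integer pair `c(height, width)`, both at least 8 (the
#'   planted quadrant patterns need room).  Default `c(32, 32)`.
#' @param normalizer_count Number of stimuli to designate as normalizers
#'   (default 15).  Chosen as the first `normalizer_count` ids of a seeded
#'   shuffle of the whole catalog.
#' @param seed Integer seed; the catalog is byte-identical for identical
#'   arguments and seed.
#'
#' @return An object of class `stimulus_set`: a list with `images` (named
#'   list of `H x W x 3` arrays with intensities in `[0, 1]`), `manifest`
#'   (data frame with columns `stimulus_id`, `category`, `is_normalizer`),
#'   and `normalizer_ids`.
#' @seealso [make_toy_extractor()], [simulate_froi_responses()]
#' @export
make_stimulus_set <- function(counts_per_category = c(face = 25, body = 50,
                                                      scene = 50, object = 65),
                              image_size = c(32L, 32L),
                              normalizer_count = 15L,
                              seed = 1L) {
  counts <- unlist(counts_per_category)
  known <- c("face", "body", "scene", "object")
  if (is.null(names(counts)) || !all(names(counts) %in% known))
    stop_invalid("counts_per_category must be named with categories among: ",
                 paste(known, collapse = ", "))
  if (any(counts < 0)) stop_invalid("category counts must be >= 0")
  if (length(image_size) != 2L || any(image_size < 8L))
    stop_invalid("image_size must be a pair of integers >= 8 ",
                 "(planted patterns need room)")
  total <- sum(counts)
  if (total < 1L) stop_invalid("catalog must contain at least one stimulus")
  check_scalar_number(normalizer_count, "normalizer_count", lower = 0)
  if (normalizer_count > total)
    stop_invalid("normalizer_count (", normalizer_count,
                 ") exceeds total stimulus count (", total, ")")

  h <- as.integer(image_size[1]); w <- as.integer(image_size[2])
  categories <- rep(names(counts), counts)

  with_seed(seed, {
    ids <- sprintf("stim_%03d", seq_len(total))
    images <- vector("list", total)
    names(images) <- ids
    for (i in seq_len(total)) {
      images[[i]] <- planted_image(categories[i], h, w)
    }
    normalizer_ids <- ids[sample.int(total)][seq_len(normalizer_count)]
    manifest <- data.frame(stimulus_id = ids,
                           category = categories,
                           is_normalizer = as.integer(ids %in% normalizer_ids),
                           stringsAsFactors = FALSE)
    structure(list(images = images, manifest = manifest,
                   normalizer_ids = normalizer_ids,
                   image_size = c(h, w), seed = as.integer(seed)),
              class = "stimulus_set")
  })
}

# One synthetic image: mid-gray + pixel noise + a category-diagnostic grating
# confined to a category-specific quadrant.  Orientation/frequency/quadrant
# differ per category so linear filters can separate the categories.
planted_image <- function(category, h, w) {
  img <- array(stats::runif(h * w * 3, 0.35, 0.65), dim = c(h, w, 3))
  half_h <- seq_len(floor(h / 2)); half_w <- seq_len(floor(w / 2))
  xs <- matrix(rep(seq_len(h), w), h, w)
  ys <- matrix(rep(seq_len(w), each = h), h, w)
  pat <- switch(category,
    face   = list(rows = half_h, cols = half_w,
                  wave = sin(2 * pi * xs / 4)),                      # top-left, fine vertical
    body   = list(rows = half_h, cols = floor(w / 2) + half_w,
                  wave = sin(2 * pi * ys / 8)),                      # top-right, coarse horizontal
    scene  = list(rows = floor(h / 2) + half_h, cols = half_w,
                  wave = sin(2 * pi * (xs + ys) / 6)),               # bottom-left, diagonal
    object = list(rows = floor(h / 2) + half_h, cols = floor(w / 2) + half_w,
                  wave = sign(sin(2 * pi * xs / 8) * sin(2 * pi * ys / 8)) * 0.8),
    stop_invalid("unknown category: ", category))
  # clip cols index range to w (odd sizes)
  pat$cols <- pat$cols[pat$cols <= w]; pat$rows <- pat$rows[pat$rows <= h]
  amp <- 0.3
  for (ch in 1:3) {
    block <- img[pat$rows, pat$cols, ch] + amp * pat$wave[pat$rows, pat$cols]
    img[pat$rows, pat$cols, ch] <- block
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

#' @export
print.stimulus_set <- function(x, ...) {
  tab <- table(x$manifest$category)
  cat("Synthetic stimulus set:", nrow(x$manifest), "stimuli (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  cat("  image size:", paste(x$image_size, collapse = "x"),
      " normalizers:", length(x$normalizer_ids), "\n")
  invisible(x)
}

#' Build a toy feature extractor from seeded localized linear filters
#'
#' Constructs a deterministic, image-computable feature extractor satisfying
#' the embedding interface used throughout the package: given an image, it
#' returns one `H x W x D` activation tensor per named layer.  Each layer
#' partitions the image into an `H x W` grid of cells; every channel applies
#' a fixed seeded linear filter (a 4x4x3 kernel resampled onto the cell)
#' followed by half-wave rectification.  There is no bias term, so an
#' all-zero image yields all-zero activations.
#'
#' This stands in for the pretrained convolutional networks whose layer
#' activations the real analysis consumes; any object implementing
#' [extract_features()] with the same contract can be used instead.
#'
#' @param layer_specs List of layer specifications, each a list or named
#'   vector with elements `name`, `H`, `W`, `D` (grid height, grid width,
#'   channels; all >= 1).
#' @param seed Integer seed for the filter bank; distinct seeds give
#'   distinct feature spaces.
#' @return An object of class `feature_extractor` with fields `layers`
#'   (kernels per layer) and `id`.
#' @export
make_toy_extractor <- function(layer_specs, seed = 1L) {
  if (length(layer_specs) < 1L) stop_invalid("need at least one layer spec")
  layers <- with_seed(seed, lapply(layer_specs, function(sp) {
    sp <- as.list(sp)
    H <- as.integer(sp$H); W <- as.integer(sp$W); D <- as.integer(sp$D)
    if (any(c(H, W, D) < 1L)) stop_invalid("layer dims H, W, D must be >= 1")
    if (is.null(sp$name)) stop_invalid("layer spec needs a name")
    # One 4x4x3 kernel per channel.  Unit-sd weights keep the across-
    # stimulus variance of the activations at O(1), so readout weights of
    # O(1) suffice and the regularization grid acts on a sensible scale.
    kern <- array(stats::rnorm(4 * 4 * 3 * D), dim = c(4, 4, 3, D))
    list(name = as.character(sp$name), H = H, W = W, D = D, kernel = kern)
  }))
  names(layers) <- vapply(layers, `[[`, character(1), "name")
  structure(list(layers = layers, seed = as.integer(seed),
                 id = paste0("toy_extractor_seed", seed)),
            class = "feature_extractor")
}

#' Extract layer activations for one image
#'
#' @param extractor A `feature_extractor` (see [make_toy_extractor()]).
#' @param image `H_img x W_img x 3` numeric array with finite entries.
#' @return Named list of `H x W x D` activation arrays, one per layer.
#' @export
extract_features <- function(extractor, image) {
  UseMethod("extract_features")
}

#' @export
extract_features.feature_extractor <- function(extractor, image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop_invalid("image must be an H x W x 3 array")
  lapply(extractor$layers, function(ly) {
    if (d[1] < ly$H || d[2] < ly$W)
      stop_invalid("image (", d[1], "x", d[2], ") smaller than layer grid (",
                   ly$H, "x", ly$W, "): below filter support")
    act <- array(0, dim = c(ly$H, ly$W, ly$D))
    row_edges <- round(seq(0, d[1], length.out = ly$H + 1))
    col_edges <- round(seq(0, d[2], length.out = ly$W + 1))
    for (i in seq_len(ly$H)) for (j in seq_len(ly$W)) {
      ri <- (row_edges[i] + 1):row_edges[i + 1]
      ci <- (col_edges[j] + 1):col_edges[j + 1]
      # resample the cell onto the fixed 4x4 kernel grid (nearest neighbor)
      rs <- ri[pmax(1L, round(seq(1, length(ri), length.out = 4)))]
      cs <- ci[pmax(1L, round(seq(1, length(ci), length.out = 4)))]
      patch <- image[rs, cs, , drop = FALSE]
      dim(patch) <- c(4, 4, 3)
      for (dd in seq_len(ly$D)) {
        v <- sum(patch * ly$kernel[, , , dd])
        act[i, j, dd] <- max(v, 0)
      }
    }
    act
  })
}

#' Extract one layer's activations for every stimulus in a set
#'
#' Convenience wrapper returning the input format the mapping functions
#' expect: a named list of `H x W x D` tensors, in catalog order.
#'
#' @param extractor A `feature_extractor`.
#' @param stimuli A `stimulus_set`.
#' @param layer Layer name.
#' @return Named list of activation arrays (one per stimulus).
#' @export
extract_layer <- function(extractor, stimuli, layer) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  if (!layer %in% names(extractor$layers))
    stop_invalid("unknown layer: ", layer)
  out <- lapply(stimuli$images, function(img)
    extract_features(extractor, img)[[layer]])
  out
}

#' Define the generative ground truth for a simulated region
#'
#' Bundles the true factorized mapping (spatial mask, channel weights, bias)
#' together with the run-noise model used by [simulate_froi_responses()].
#'
#' @param m Numeric `H x W` matrix: true spatial mask.
#' @param w Numeric length-`D` vector: true channel weights.
#' @param b Scalar bias.
#' @param noise_sd Standard deviation of iid Gaussian run noise (>= 0).
#' @param n_runs Number of measurement runs (>= 1); the study design uses 20.
#' @param seed Integer seed for the noise draws.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(m, w, b = 0, noise_sd = 0, n_runs = 20L, seed = 1L) {
  if (!all(is.finite(m)) || !all(is.finite(w)) || !is.finite(b))
    stop_invalid("ground truth parameters must be finite")
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (n_runs < 1L) stop_invalid("n_runs must be >= 1")
  structure(list(m = as.matrix(m), w = as.numeric(w), b = as.numeric(b),
                 noise_sd = noise_sd, n_runs = as.integer(n_runs),
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Simulate multi-run region responses from a planted factorized mapping
#'
#' The clean response to stimulus *s* is the factorized readout of the
#' chosen extractor layer,
#' `y_s = b + sum_d w_d * meanPool(m * A_s[,,d])`, where `meanPool` divides
#' by `H * W` — exactly the model form fitted by [fit_factorized()], so
#' parameter recovery is well posed.  Each run observes `y_s` plus iid
#' Gaussian noise; averaging over runs converges to the clean signal.
#'
#' @param stimuli A `stimulus_set`.
#' @param extractor A `feature_extractor`.
#' @param layer Layer name whose shape must match the truth's `m` and `w`.
#' @param truth A `ground_truth` object.
#' @return List with `clean` (named vector of noiseless responses), `runs`
#'   (stimuli x runs matrix, columns `run_001`, ...), and `features` (the
#'   extracted tensors, for reuse).
#' @export
simulate_froi_responses <- function(stimuli, extractor, layer, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  feats <- extract_layer(extractor, stimuli, layer)
  dm <- dim(feats[[1]])
  if (!identical(dim(truth$m), dm[1:2]) || length(truth$w) != dm[3])
    stop_invalid("ground truth shape (", paste(dim(truth$m), collapse = "x"),
                 ", D=", length(truth$w), ") does not match layer '", layer,
                 "' shape (", paste(dm, collapse = "x"), ")")
  clean <- vapply(feats, function(A) {
    pooled <- vapply(seq_len(dm[3]), function(d)
      sum(truth$m * A[, , d]) / (dm[1] * dm[2]), numeric(1))
    truth$b + sum(truth$w * pooled)
  }, numeric(1))
  runs <- with_seed(truth$seed, {
    eps <- matrix(stats::rnorm(length(clean) * truth$n_runs,
                               sd = truth$noise_sd),
                  nrow = length(clean))
    sweep(eps, 1, clean, `+`)
  })
  rownames(runs) <- names(clean)
  colnames(runs) <- sprintf("run_%03d", seq_len(truth$n_runs))
  list(clean = clean, runs = runs, features = feats)
}

#' Simulate behavioral raters with a repeat block
#'
#' Each simulated rater rates every stimulus once and then re-rates a fixed
#' subset (the repeat block), emulating the drag-rate arrangement task with
#' its test-retest reliability check.  A rater's rating is a monotone squash
#' of `true_score + noise` into `[0, 1]` (per-rater affine rescale of the
#' first-pass range, applied identically to the repeat pass); repeat ratings
#' draw fresh noise of the same magnitude.
#'
#' @param true_scores Named numeric vector of latent scores per stimulus.
#' @param n_raters Number of raters (>= 1).
#' @param rater_noise_sd Gaussian noise sd added per rating.
#' @param repeat_ids Stimulus ids in the repeat block (subset of
#'   `names(true_scores)`); defaults to the first 40 stimuli, matching the
#'   study's 40-image retest subset.
#' @param seed Integer seed.
#' @return Data frame with columns `rater_id`, `stimulus_id`, `phase`
#'   (`"first"` or `"repeat"`), `rating`.
#' @export
simulate_raters <- function(true_scores, n_raters, rater_noise_sd,
                            repeat_ids = utils::head(names(true_scores), 40L),
                            seed = 1L) {
  if (is.null(names(true_scores)))
    stop_invalid("true_scores must be named by stimulus id")
  if (!all(repeat_ids %in% names(true_scores)))
    stop_invalid("repeat_ids must be a subset of the stimulus ids")
  if (n_raters < 1L) stop_invalid("n_raters must be >= 1")
  check_scalar_number(rater_noise_sd, "rater_noise_sd", lower = 0)
  ids <- names(true_scores)
  with_seed(seed, {
    out <- vector("list", n_raters)
    for (r in seq_len(n_raters)) {
      first_raw <- true_scores + stats::rnorm(length(ids), sd = rater_noise_sd)
      rng <- range(first_raw)
      squash <- if (diff(rng) > 0)
        function(x) pmin(1, pmax(0, (x - rng[1]) / diff(rng)))
      else function(x) rep(0.5, length(x))
      rep_raw <- true_scores[repeat_ids] +
        stats::rnorm(length(repeat_ids), sd = rater_noise_sd)
      out[[r]] <- rbind(
        data.frame(rater_id = sprintf("rater_%03d", r), stimulus_id = ids,
                   phase = "first", rating = squash(first_raw),
                   stringsAsFactors = FALSE),
        data.frame(rater_id = sprintf("rater_%03d", r),
                   stimulus_id = repeat_ids,
                   phase = "repeat", rating = squash(rep_raw),
                   stringsAsFactors = FALSE))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
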