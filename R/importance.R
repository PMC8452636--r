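# Bilinear resize of a matrix to H2 x W2 (align-corners = FALSE convention).
bilinear_resize <- function(mat, H2, W2) {
  h <- nrow(mat); w <- ncol(mat)
  ri <- (seq_len(H2) - 0.5) * h / H2 - 0.5
  ci <- (seq_len(W2) - 0.5) * w / W2 - 0.5
  r0 <- pmin(pmax(floor(ri), 0), h - 1); r1 <- pmin(r0 + 1, h - 1)
  c0 <- pmin(pmax(floor(ci), 0), w - 1); c1 <- pmin(c0 + 1, w - 1)
  fr <- matrix(pmin(pmax(ri - r0, 0), 1), H2, W2)
  fc <- matrix(pmin(pmax(ci - c0, 0), 1), H2, W2, byrow = TRUE)
  top <- mat[r0 + 1, c0 + 1, drop = FALSE] * (1 - fc) +
    mat[r0 + 1, c1 + 1, drop = FALSE] * fc
  bot <- mat[r1 + 1, c0 + 1, drop = FALSE] * (1 - fc) +
    mat[r1 + 1, c1 + 1, drop = FALSE] * fc
  top * (1 - fr) + bot * fr
}

#' Generate a seeded set of smooth random occlusion masks
#'
#' Randomized-input-sampling masks: each mask starts as an `h x w` binary
#' grid whose cells are on with probability `p`, is bilinearly upsampled to
#' slightly beyond the image size, and is cropped at a random sub-cell
#' shift, yielding smooth occlusion patterns in `[0, 1]` at image
#' resolution.  Defaults (7 x 7 grid, p = 0.5) are the method's canonical
#' choices.
#'
#' @param n_masks Number of masks (>= 1); the probing default is 2000.
#' @param image_size `c(height, width)` of the probed image.
#' @param grid `c(h, w)` low-resolution grid size (default `c(7, 7)`).
#' @param p Cell on-probability, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return Object of class `mask_set`: list with `masks` (list of
#'   `height x width` matrices in `[0, 1]`) and the generation parameters.
#' @export
make_mask_set <- function(n_masks = 2000L, image_size, grid = c(7L, 7L),
                          p = 0.5, seed = 1L) {
  check_scalar_number(n_masks, "n_masks", lower = 1)
  if (p <= 0 || p >= 1)
    stop_invalid("degenerate masks: p must lie strictly between 0 and 1")
  H <- image_size[1]; W <- image_size[2]
  h <- grid[1]; w <- grid[2]
  ch <- ceiling(H / h); cw <- ceiling(W / w)
  up_h <- (h + 1L) * ch; up_w <- (w + 1L) * cw
  masks <- with_seed(seed, lapply(seq_len(n_masks), function(i) {
    cells <- matrix(as.numeric(stats::runif(h * w) < p), h, w)
    big <- bilinear_resize(cells, up_h, up_w)
    dx <- sample.int(ch, 1L) - 1L
    dy <- sample.int(cw, 1L) - 1L
    big[(dx + 1L):(dx + H), (dy + 1L):(dy + W)]
  }))
  structure(list(masks = masks, grid = grid, p = p, seed = as.integer(seed),
                 image_size = c(H, W)),
            class = "mask_set")
}

#' Occlusion-based importance map for an image under an encoding model
#'
#' Estimates which image regions drive a model's predicted response by
#' randomized occlusion: the image is multiplied elementwise by each mask,
#' the predictor is evaluated on every masked image, and the masks are
#' linearly combined weighted by those predictions,
#' \deqn{S = \frac{1}{pN} \sum_n f(I \odot M_n)\, M_n,}
#' followed by mean-centering (so regions that do not activate the model
#' come out negative).  For a locally linear predictor the expectation of
#' the uncentered map is proportional to the predictor's per-pixel
#' gradient, and its Monte-Carlo standard error shrinks as `1/sqrt(N)`.
#'
#' @param predictor Function `image -> scalar` (see [make_predictor()]).
#' @param image `H x W x 3` array.
#' @param masks A `mask_set`, or NULL to generate one.
#' @param n_masks Number of masks when generating (default 2000).
#' @param grid,p Mask-generation parameters (see [make_mask_set()]).
#' @param seed Seed for mask generation.
#' @return Object of class `importance_map`: the centered `H x W` matrix
#'   with attributes `uncentered` and `params`.
#' @export
rise_importance <- function(predictor, image, masks = NULL, n_masks = 2000L,
                            grid = c(7L, 7L), p = 0.5, seed = 1L) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L)
    stop_invalid("image must be an H x W x 3 array")
  if (is.null(masks))
    masks <- make_mask_set(n_masks, image_size = d[1:2], grid = grid, p = p,
                           seed = seed)
  stopifnot(inherits(masks, "mask_set"))
  if (!identical(as.integer(masks$image_size), as.integer(d[1:2])))
    stop_invalid("mask size does not match image size")
  N <- length(masks$masks)
  acc <- matrix(0, d[1], d[2])
  for (M in masks$masks) {
    masked <- image * array(M, dim = d)  # same mask on all color channels
    f <- predictor(masked)
    acc <- acc + f * M
  }
  S <- acc / (masks$p * N)
  centered <- S - mean(S)
  structure(centered, class = c("importance_map", "matrix"),
            uncentered = S,
            params = list(n_masks = N, grid = masks$grid, p = masks$p,
                          seed = masks$seed))
}
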