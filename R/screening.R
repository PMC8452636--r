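#' Build an image-computable predictor from a mapping and extractor
#'
#' Composes a fitted mapping with a feature extractor into a single
#' closure `image -> predicted response`, the form consumed by the
#' high-throughput probing tools (screening, importance maps, synthesis).
#'
#' @param mapping A fitted `ridge_mapping` or `factorized_mapping`.
#' @param extractor A `feature_extractor`.
#' @param layer Layer name to read out.
#' @return Function taking an `H x W x 3` image and returning a scalar.
#' @export
make_predictor <- function(mapping, extractor, layer) {
  force(mapping); force(extractor); force(layer)
  function(image) {
    feats <- extract_features(extractor, image)[[layer]]
    unname(predict(mapping, list(img = feats)))
  }
}

#' Screen an image collection through an encoding model
#'
#' Runs every image through the predictor, ranks them by predicted
#' response (descending; ties broken by stimulus id ascending, so the
#' ranking is invariant to the input order), and accumulates per-source
#' histograms of the predicted responses over a common set of equal-width
#' bins.  Images whose evaluation fails are skipped and counted, not
#' fatal.  This is the desk-scale version of screening millions of images
#' from labeled databases to find the stimuli predicted to drive a region
#' hardest.
#'
#' @param predictor Function `image -> scalar` (see [make_predictor()]).
#' @param images Named list of `H x W x 3` arrays.
#' @param sources Optional character vector (recycled or named by image id)
#'   labeling each image's database of origin; default `"default"`.
#' @param n_bins Histogram bins over the pooled score range (default 100).
#' @return Object of class `screening_result`: `ranking` (data frame
#'   `rank`, `stimulus_id`, `score`, `source`), `histograms` (per source:
#'   `breaks`, `counts`), `n_skipped`.
#' @export
screen_images <- function(predictor, images, sources = NULL, n_bins = 100L) {
  if (is.null(names(images))) stop_invalid("images must be named by id")
  ids <- names(images)
  if (is.null(sources)) sources <- rep("default", length(images))
  if (length(sources) == 1L) sources <- rep(sources, length(images))
  stopifnot(length(sources) == length(images))
  scores <- rep(NA_real_, length(images))
  for (i in seq_along(images)) {
    scores[i] <- tryCatch(predictor(images[[i]]), error = function(e) NA_real_)
  }
  ok <- !is.na(scores)
  n_skipped <- sum(!ok)
  df <- data.frame(stimulus_id = ids[ok], score = scores[ok],
                   source = sources[ok], stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$stimulus_id), ]
  df$rank <- seq_len(nrow(df))
  df <- df[, c("rank", "stimulus_id", "score", "source")]
  rownames(df) <- NULL
  rng <- range(df$score)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  histograms <- lapply(split(df$score, df$source), function(s) {
    h <- graphics::hist(s, breaks = breaks, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  })
  structure(list(ranking = df, histograms = histograms,
                 n_skipped = n_skipped),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("screening_result:", nrow(x$ranking), "images ranked,",
      x$n_skipped, "skipped;", length(x$histograms), "source(s)\n")
  invisible(x)
}

#' Subsample the best images from each block of the top of a ranking
#'
#' Partitions ranks `1..top_n` into consecutive blocks of size `block` and
#' keeps the `per_block` best-ranked images of each block, so the whole
#' depth of the top list is inspected at manageable cost.  The defaults
#' (top 100,000; blocks of 1000; 2 per block) yield 200 images.
#'
#' @param result A `screening_result`.
#' @param top_n Depth of the ranking to cover (default 100000).
#' @param block Block size (default 1000).
#' @param per_block Images retained per block (default 2).
#' @return Character vector of stimulus ids, ordered by rank.
#' @export
subsample_top <- function(result, top_n = 100000L, block = 1000L,
                          per_block = 2L) {
  stopifnot(inherits(result, "screening_result"))
  if (per_block > block) stop_invalid("per_block exceeds block size")
  if (top_n > nrow(result$ranking))
    stop_invalid("top_n (", top_n, ") exceeds number screened (",
                 nrow(result$ranking), ")")
  if (block > top_n) stop_invalid("block exceeds top_n")
  ranks <- seq_len(top_n)
  blk <- ceiling(ranks / block)
  keep <- unlist(lapply(split(ranks, blk), function(r)
    r[seq_len(min(per_block, length(r)))]), use.names = FALSE)
  result$ranking$stimulus_id[sort(keep)]
}

#' Re-screen after excluding images
#'
#' Removes a set of images (by id, or every image from a labeled source)
#' from a screening ranking and returns the top `k` of what remains.  This
#' is the falsification probe: after deleting every image the source
#' database labels as the preferred category, do the remaining
#' top-predicted images still belong to it?
#'
#' @param result A `screening_result`.
#' @param excluded_ids Stimulus ids to remove.
#' @param excluded_source Alternatively, a source label whose images are
#'   all removed.
#' @param k Number of top images to return (default 5000).
#' @return Character vector of stimulus ids (possibly shorter than `k`;
#'   empty with a warning if the exclusion removes everything).
#' @export
exclusion_rescreen <- function(result, excluded_ids = character(),
                               excluded_source = NULL, k = 5000L) {
  stopifnot(inherits(result, "screening_result"))
  df <- result$ranking
  if (!is.null(excluded_source))
    excluded_ids <- union(excluded_ids,
                          df$stimulus_id[df$source %in% excluded_source])
  unknown <- setdiff(excluded_ids, df$stimulus_id)
  if (length(unknown) > 0L && length(unknown) == length(excluded_ids) &&
      length(excluded_ids) > 0L)
    stop_invalid("exclusion does not resolve against screened ids")
  df <- df[!df$stimulus_id %in% excluded_ids, ]
  if (nrow(df) == 0L) {
    warning("exclusion removed every screened image", call. = FALSE)
    return(character())
  }
  df$stimulus_id[seq_len(min(k, nrow(df)))]
}

#' Select category-selective units from an extractor layer
#'
#' The localizer-contrast control: a unit (one channel at one spatial
#' position) is selected iff its mean response to the target category's
#' localizer stimuli strictly exceeds its mean response to every other
#' category.  The selected units' responses can then be averaged into a
#' pseudo-region response (see [pseudo_froi_response()]) and modeled like a
#' real region, testing whether such units are as selective as the brain
#' regions they imitate.
#'
#' @param extractor A `feature_extractor`.
#' @param layer Layer name.
#' @param stimuli A `stimulus_set` (the localizer snapshots, >= 2 stimuli
#'   per category).
#' @param target_category Category whose preferred units are sought.
#' @return List with `units` (data frame `x`, `y`, `d`, `flat` index into
#'   the flattened `H*W*D` tensor) — empty with a warning if no unit
#'   qualifies — and `category_means` (units x categories matrix).
#' @export
select_selective_units <- function(extractor, layer, stimuli,
                                   target_category) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  cats <- stimuli$manifest$category
  tab <- table(cats)
  if (any(tab < 2L)) stop_invalid("need >= 2 localizer stimuli per category")
  if (!target_category %in% names(tab))
    stop_invalid("target category '", target_category, "' not in stimuli")
  feats <- extract_layer(extractor, stimuli, layer)
  dm <- dim(feats[[1]])
  flat <- t(vapply(feats, as.numeric, numeric(prod(dm))))  # stimuli x units
  means <- vapply(sort(unique(cats)), function(cc)
    colMeans(flat[cats == cc, , drop = FALSE]), numeric(ncol(flat)))
  target_m <- means[, target_category]
  others <- means[, setdiff(colnames(means), target_category), drop = FALSE]
  sel <- which(vapply(seq_len(nrow(means)), function(u)
    all(target_m[u] > others[u, ]), logical(1)))
  if (length(sel) == 0L)
    warning("no unit is selective for '", target_category, "'",
            call. = FALSE)
  coords <- arrayInd(sel, dm)
  units <- data.frame(x = coords[, 1], y = coords[, 2], d = coords[, 3],
                      flat = sel)
  list(units = units, category_means = means, dims = dm, layer = layer)
}

#' Average selected units into a pseudo-region response
#'
#' @param extractor A `feature_extractor`.
#' @param layer Layer name (must match the unit selection).
#' @param units Unit selection from [select_selective_units()].
#' @param stimuli A `stimulus_set`.
#' @return Named numeric vector: mean selected-unit activation per stimulus.
#' @export
pseudo_froi_response <- function(extractor, layer, units, stimuli) {
  if (nrow(units$units) == 0L) stop_invalid("empty unit selection")
  feats <- extract_layer(extractor, stimuli, layer)
  vapply(feats, function(A) mean(as.numeric(A)[units$units$flat]), numeric(1))
}
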