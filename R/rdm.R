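#' Representational dissimilarity matrix from response patterns
#'
#' Computes the Euclidean distance between every pair of stimuli's response
#' patterns (the columns of a targets x stimuli matrix), yielding a
#' symmetric, zero-diagonal dissimilarity matrix.  For the 185-image
#' catalog this is choose(185, 2) = 17020 unique pairs.  Euclidean rather
#' than correlation distance is used because mean-response differences are
#' themselves informative for these regions.
#'
#' @param patterns Numeric targets x stimuli matrix (column names are
#'   stimulus ids); >= 2 stimuli, >= 1 target, no missing values.
#' @return Object of class `rdm`: the n x n distance matrix with stimulus
#'   ids as dimnames.
#' @export
compute_rdm <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (ncol(patterns) < 2L) stop_invalid("need at least 2 stimuli")
  if (anyNA(patterns) || !all(is.finite(patterns)))
    stop_invalid("patterns contain missing or non-finite values")
  d <- as.matrix(stats::dist(t(patterns), method = "euclidean"))
  dimnames(d) <- list(colnames(patterns), colnames(patterns))
  structure(d, class = c("rdm", "matrix"))
}

#' Compare two dissimilarity matrices by rank correlation
#'
#' Spearman correlation between the strictly-upper-triangle entries of two
#' aligned RDMs (diagonal excluded; using both triangles would only
#' duplicate every pair).  Rank correlation makes the comparison invariant
#' to monotone transforms of either matrix's distances.
#'
#' @param a,b `rdm` objects (or plain square matrices) of the same size and
#'   stimulus order.
#' @return Spearman's rho (scalar).
#' @export
compare_rdms <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (!identical(dim(a), dim(b)))
    stop_invalid("RDM sizes differ")
  if (!is.null(dimnames(a)[[1]]) && !is.null(dimnames(b)[[1]]) &&
      !identical(dimnames(a)[[1]], dimnames(b)[[1]]))
    stop_invalid("RDM stimulus orders differ")
  ut <- upper.tri(a)
  safe_cor(a[ut], b[ut], method = "spearman")
}
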