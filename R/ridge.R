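# Feature handling shared by the two mappers: a feature set is a named list
# of H x W x D tensors (one per stimulus); internally flattened to n x p.
stack_features <- function(features) {
  if (is.matrix(features))
    return(list(X = features, dims = c(1L, 1L, ncol(features)),
                ids = rownames(features)))
  stopifnot(is.list(features), length(features) >= 1L)
  dm <- dim(features[[1]])
  if (is.null(dm) || length(dm) != 3L)
    stop_invalid("each feature tensor must be a 3-d H x W x D array")
  for (f in features) if (!identical(dim(f), dm))
    stop_invalid("inconsistent tensor shapes: expected ",
                 paste(dm, collapse = "x"), ", received ",
                 paste(dim(f), collapse = "x"))
  X <- t(vapply(features, as.numeric, numeric(prod(dm))))
  if (!all(is.finite(X))) stop_invalid("feature tensors must be finite")
  list(X = X, dims = dm, ids = names(features))
}

#' Fit a ridge-regression mapping from layer activations to responses
#'
#' The fast screening mapper: an L2-penalized linear readout of the
#' flattened `H x W x D` activations.  Features and responses are centered,
#' the intercept is left unpenalized and recovered from the means, and the
#' solution agrees exactly with the normal-equations closed form
#' `(X'X + lambda I)^-1 X'y` on the centered data.  When there are more
#' features than stimuli the equivalent dual (kernel) form
#' `X'(XX' + lambda I)^-1 y` is solved instead; both are exact.  The
#' regularization strength is fixed at 0.01 during screening, a value not
#' tuned per feature set.
#'
#' @param features Named list of `H x W x D` tensors, or an `n x p` matrix.
#' @param y Numeric response vector (length n, nonzero variance).
#' @param lambda Ridge penalty (>= 0), default 0.01.
#' @return Object of class `ridge_mapping` with `weights`, `intercept`,
#'   `lambda`, `dims`.
#' @export
fit_ridge <- function(features, y, lambda = 0.01) {
  st <- stack_features(features)
  X <- st$X
  n <- nrow(X)
  if (n < 2L) stop_invalid("need at least 2 training stimuli")
  if (length(y) != n) stop_invalid("length(y) != number of stimuli")
  if (!all(is.finite(y))) stop_invalid("y must be finite")
  if (stats::sd(y) == 0) stop_invalid("degenerate target: y has zero variance")
  check_scalar_number(lambda, "lambda", lower = 0)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  p <- ncol(X)
  if (p <= n) {
    A <- crossprod(Xc)
    diag(A) <- diag(A) + lambda
    w <- solve(A, crossprod(Xc, yc))
  } else {
    K <- tcrossprod(Xc)
    diag(K) <- diag(K) + lambda
    alpha <- solve(K, yc)
    w <- crossprod(Xc, alpha)
  }
  w <- as.numeric(w)
  structure(list(weights = w, intercept = ym - sum(xm * w),
                 lambda = lambda, dims = st$dims,
                 feature_names = colnames(X)),
            class = "ridge_mapping")
}

#' Predict responses from a fitted ridge mapping
#'
#' @param object A `ridge_mapping`.
#' @param features Feature tensors (same shape as at fit time).
#' @param ... Unused.
#' @return Numeric vector of predicted responses, one per stimulus.
#' @export
predict.ridge_mapping <- function(object, features, ...) {
  st <- stack_features(features)
  if (!identical(st$dims, object$dims))
    stop_invalid("feature shape mismatch: expected ",
                 paste(object$dims, collapse = "x"), ", received ",
                 paste(st$dims, collapse = "x"))
  pred <- as.numeric(st$X %*% object$weights) + object$intercept
  names(pred) <- st$ids
  pred
}
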