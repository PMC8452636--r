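#' Optimizer configuration for the factorized mapper
#'
#' Full-batch adaptive-moment (Adam) gradient descent.  Defaults: step
#' 0.01, at most 2000 iterations, early stop when the relative loss change
#' over 50 consecutive iterations falls below 1e-6.  Parameters `m` and `w`
#' are initialized from a seeded Gaussian (sd 0.01) — a zero initialization
#' stalls, because the gradient of the spatial mask vanishes when the
#' channel weights are zero — and the bias starts at `mean(y)`.
#'
#' @param step Learning rate (> 0).
#' @param max_iter Maximum iterations (>= 1).
#' @param tol Relative-change convergence tolerance.
#' @param patience Window (iterations) over which the relative change is
#'   measured.
#' @param seed Seed for the parameter initialization.
#' @param bias Logical: include an additive bias term (default TRUE).
#' @return List of class `opt_config`.
#' @export
opt_config <- function(step = 0.01, max_iter = 2000L, tol = 1e-6,
                       patience = 50L, seed = 1L, bias = TRUE) {
  check_scalar_number(step, "step", lower = .Machine$double.eps)
  check_scalar_number(max_iter, "max_iter", lower = 1)
  structure(list(step = step, max_iter = as.integer(max_iter), tol = tol,
                 patience = as.integer(patience), seed = as.integer(seed),
                 bias = isTRUE(bias)),
            class = "opt_config")
}

#' Fit the two-stage factorized spatial-by-channel mapping
#'
#' The final-model mapper: a rank-1-constrained linear readout that first
#' applies a learned spatial mask `m` over the `H x W` positions of the
#' activation map, averages the masked activations over space, and then
#' takes a learned weighted sum `w` over the `D` channels:
#'
#' \deqn{\hat y_i = b + \sum_d w_d \frac{1}{HW}\sum_{x,y} m_{xy} A_i[x,y,d]}
#'
#' minimizing the penalized mean squared error
#' \deqn{L = \frac{1}{n}\sum_i (y_i - \hat y_i)^2 + \lambda_s \|m\|^2 +
#'   \lambda_d \|w\|^2}
#' by full-batch Adam with analytic gradients (the residual-weighted
#' activation sums).  Compared with an unconstrained regression on the
#' flattened tensor, this separable "where times what" form has `H*W + D`
#' rather than `H*W*D` parameters.
#'
#' The factorization is identifiable only up to a scale exchanged between
#' `m` and `w`; the returned parameters are sign-canonicalized so that
#' `sum(m) >= 0`, and model comparisons should use the rank-1 product
#' `outer(m, w)` (see [outer_product()]).  The parameters at the best
#' recorded loss are returned; non-convergence within `max_iter` sets
#' `converged = FALSE` rather than raising an error, while a NaN loss
#' raises an optimization-diverged error.
#'
#' @param features Named list of `H x W x D` tensors.
#' @param y Numeric response vector.
#' @param lambda_s Spatial-mask penalty (>= 0).
#' @param lambda_d Channel-weight penalty (>= 0).
#' @param opt An [opt_config()].
#' @return Object of class `factorized_mapping` with fields `m` (H x W
#'   matrix), `w` (length D), `b`, `lambda_s`, `lambda_d`, `trace` (loss per
#'   iteration), `converged`.
#' @export
fit_factorized <- function(features, y, lambda_s = 0.01, lambda_d = 0.01,
                           opt = opt_config()) {
  st <- stack_features(features)
  X <- st$X
  n <- nrow(X)
  if (n < 2L) stop_invalid("need at least 2 training stimuli")
  if (length(y) != n) stop_invalid("length(y) != number of stimuli")
  check_scalar_number(lambda_s, "lambda_s", lower = 0)
  check_scalar_number(lambda_d, "lambda_d", lower = 0)
  H <- st$dims[1]; W <- st$dims[2]; D <- st$dims[3]
  hw <- H * W

  par <- with_seed(opt$seed, list(
    m = stats::rnorm(hw, sd = 0.01),
    w = stats::rnorm(D, sd = 0.01),
    b = if (opt$bias) mean(y) else 0))

  loss_fn <- function(m, w, b) {
    pred <- b + as.numeric(X %*% as.numeric(outer(m, w))) / hw
    mean((y - pred)^2) + lambda_s * sum(m^2) + lambda_d * sum(w^2)
  }

  # Adam state
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  zeros <- function(k) numeric(k)
  st1 <- list(m = zeros(hw), w = zeros(D), b = 0)
  st2 <- list(m = zeros(hw), w = zeros(D), b = 0)
  trace <- numeric(opt$max_iter)
  best <- list(loss = Inf, par = par)
  converged <- FALSE
  m <- par$m; w <- par$w; b <- par$b

  for (it in seq_len(opt$max_iter)) {
    pred <- b + as.numeric(X %*% as.numeric(outer(m, w))) / hw
    r <- pred - y
    loss <- mean(r^2) + lambda_s * sum(m^2) + lambda_d * sum(w^2)
    if (!is.finite(loss))
      stop_invalid("optimization diverged: non-finite loss at iteration ", it)
    trace[it] <- loss
    if (loss < best$loss) best <- list(loss = loss, par = list(m = m, w = w, b = b))

    G <- matrix(crossprod(X, r), nrow = hw, ncol = D)   # sum_i r_i A_i
    g_w <- as.numeric(crossprod(G, m)) * (2 / (n * hw)) + 2 * lambda_d * w
    g_m <- as.numeric(G %*% w) * (2 / (n * hw)) + 2 * lambda_s * m
    g_b <- if (opt$bias) 2 * mean(r) else 0

    upd <- function(g, s1, s2) {
      s1 <- beta1 * s1 + (1 - beta1) * g
      s2 <- beta2 * s2 + (1 - beta2) * g^2
      hat1 <- s1 / (1 - beta1^it); hat2 <- s2 / (1 - beta2^it)
      list(delta = opt$step * hat1 / (sqrt(hat2) + eps), s1 = s1, s2 = s2)
    }
    um <- upd(g_m, st1$m, st2$m); st1$m <- um$s1; st2$m <- um$s2
    uw <- upd(g_w, st1$w, st2$w); st1$w <- uw$s1; st2$w <- uw$s2
    m <- m - um$delta
    w <- w - uw$delta
    if (opt$bias) {
      ub <- upd(g_b, st1$b, st2$b); st1$b <- ub$s1; st2$b <- ub$s2
      b <- b - ub$delta
    }

    if (it > opt$patience) {
      prev <- trace[it - opt$patience]
      if (abs(prev - loss) / max(abs(prev), .Machine$double.eps) < opt$tol) {
        converged <- TRUE
        trace <- trace[seq_len(it)]
        break
      }
    }
  }
  if (!converged && length(trace) > opt$max_iter) trace <- trace[seq_len(opt$max_iter)]

  m <- matrix(best$par$m, nrow = H, ncol = W)
  w <- best$par$w
  if (sum(m) < 0) { m <- -m; w <- -w }   # canonical sign
  structure(list(m = m, w = w, b = best$par$b,
                 lambda_s = lambda_s, lambda_d = lambda_d,
                 dims = st$dims, trace = trace, loss = best$loss,
                 converged = converged, opt = opt),
            class = "factorized_mapping")
}

#' Predict responses from a fitted factorized mapping
#'
#' Deterministic, one value per stimulus, linear in the activations for
#' fixed parameters: all-zero features predict the bias, and doubling every
#' activation of a zero-bias mapping's input doubles its prediction.
#'
#' @param object A `factorized_mapping`.
#' @param features Feature tensors of the training shape.
#' @param ... Unused.
#' @return Named numeric vector of predictions.
#' @export
predict.factorized_mapping <- function(object, features, ...) {
  st <- stack_features(features)
  if (!identical(st$dims, object$dims))
    stop_invalid("feature shape mismatch: expected ",
                 paste(object$dims, collapse = "x"), ", received ",
                 paste(st$dims, collapse = "x"))
  hw <- object$dims[1] * object$dims[2]
  pred <- object$b +
    as.numeric(st$X %*% as.numeric(outer(as.numeric(object$m), object$w))) / hw
  names(pred) <- st$ids
  pred
}

#' Rank-1 product of a factorized mapping's parameters
#'
#' The factorization `(m, w)` is identifiable only up to a scalar exchanged
#' between the factors, so fitted mappings are compared through the outer
#' product `m w'` (an `(H*W) x D` matrix), which is scale-exchange
#' invariant up to overall sign.
#'
#' @param mapping A `factorized_mapping` or `ground_truth`.
#' @return Numeric `(H*W) x D` matrix.
#' @export
outer_product <- function(mapping) {
  outer(as.numeric(mapping$m), as.numeric(mapping$w))
}
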