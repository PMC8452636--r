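#' Configuration for generator-coupled activation maximization
#'
#' Defaults follow the study protocol: 30000 optimizer steps at a fixed
#' learning rate of 0.001; the latent code is drawn from a standard normal
#' truncated to `[-2, 2]` and scaled by the truncation parameter 0.5; the
#' class vector is initialized as `alpha * softmax(n)` with `alpha = 0.05`
#' and `n` drawn from a standard normal truncated to `[0, 1]` — a
#' near-uniform, low-magnitude class mixture.  The softmax is applied once
#' at initialization; both the latent and the class vector are optimized
#' jointly afterwards.
#'
#' @param steps Optimizer steps (>= 1; tests use a few hundred).
#' @param lr Learning rate (> 0).
#' @param z_dim Latent dimensionality.
#' @param class_dim Class-vector dimensionality (0 for class-free
#'   generators).
#' @param alpha Class initialization scale (default 0.05).
#' @param truncation Latent truncation scale (default 0.5).
#' @param seed Integer seed for initialization.
#' @return List of class `synthesis_config`.
#' @export
synthesis_config <- function(steps = 30000L, lr = 0.001, z_dim = 2L,
                             class_dim = 0L, alpha = 0.05, truncation = 0.5,
                             seed = 1L) {
  check_scalar_number(steps, "steps", lower = 1)
  check_scalar_number(lr, "lr", lower = .Machine$double.eps)
  structure(list(steps = as.integer(steps), lr = lr,
                 z_dim = as.integer(z_dim), class_dim = as.integer(class_dim),
                 alpha = alpha, truncation = truncation,
                 seed = as.integer(seed)),
            class = "synthesis_config")
}

#' Synthesize a maximally activating image through a generative prior
#'
#' Activation maximization with the image parameterized by a generator:
#' the objective is the predicted response of the encoding model to the
#' generated image, and gradient ascent (adaptive-moment updates) is run
#' jointly on the generator's latent code and class vector.  Gradients are
#' taken analytically when `grad` is supplied and by central finite
#' differences otherwise (adequate for the low-dimensional toy generators
#' used in testing; a differentiable generator stack can pass its own
#' gradient).
#'
#' @param generator Function `(z, class_vector) -> image` (the class
#'   argument is omitted when `class_dim = 0`).
#' @param predictor Function `image -> scalar` (see [make_predictor()]).
#' @param config A [synthesis_config()].
#' @param grad Optional function `(z, class_vector) -> list(z =, class =)`
#'   giving the gradient of the objective.
#' @return List with `image` (final generated image), `trace` (objective
#'   per step, length `steps + 1` including the initial value), `z`,
#'   `class_vector`, `config`.
#' @export
synthesize <- function(generator, predictor, config = synthesis_config(),
                       grad = NULL) {
  stopifnot(inherits(config, "synthesis_config"))
  gen <- function(z, cls) {
    if (config$class_dim > 0L) generator(z, cls) else generator(z)
  }
  objective <- function(z, cls) predictor(gen(z, cls))

  init <- with_seed(config$seed, {
    z <- config$truncation * rtruncnorm(config$z_dim, -2, 2)
    cls <- if (config$class_dim > 0L) {
      n <- rtruncnorm(config$class_dim, 0, 1)
      e <- exp(n - max(n))
      config$alpha * e / sum(e)
    } else numeric(0)
    list(z = z, cls = cls)
  })
  z <- init$z; cls <- init$cls
  npar <- length(z) + length(cls)

  num_grad <- function(z, cls) {
    eps <- 1e-4
    g <- numeric(npar)
    par <- c(z, cls)
    for (i in seq_len(npar)) {
      up <- par; up[i] <- up[i] + eps
      dn <- par; dn[i] <- dn[i] - eps
      g[i] <- (objective(up[seq_along(z)], up[-seq_along(z)]) -
                 objective(dn[seq_along(z)], dn[-seq_along(z)])) / (2 * eps)
    }
    list(z = g[seq_along(z)], class = if (length(cls)) g[-seq_along(z)]
         else numeric(0))
  }
  grad_fn <- grad %||% num_grad

  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8
  m1 <- numeric(npar); m2 <- numeric(npar)
  trace <- numeric(config$steps + 1L)
  trace[1L] <- objective(z, cls)
  last_finite <- list(z = z, cls = cls, value = trace[1L])
  for (it in seq_len(config$steps)) {
    g <- grad_fn(z, cls)
    gv <- c(g$z, g$class)
    m1 <- beta1 * m1 + (1 - beta1) * gv
    m2 <- beta2 * m2 + (1 - beta2) * gv^2
    step <- config$lr * (m1 / (1 - beta1^it)) /
      (sqrt(m2 / (1 - beta2^it)) + aeps)
    par <- c(z, cls) + step                       # ascent on the response
    z <- par[seq_along(z)]
    if (length(cls)) cls <- par[-seq_along(z)]
    val <- objective(z, cls)
    if (!is.finite(val))
      stop_invalid("synthesis diverged at step ", it,
                   " (last finite objective: ", signif(last_finite$value, 6),
                   ")")
    trace[it + 1L] <- val
    last_finite <- list(z = z, cls = cls, value = val)
  }
  list(image = gen(z, cls), trace = trace, z = z, class_vector = cls,
       config = config)
}
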