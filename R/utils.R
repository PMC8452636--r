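# Internal helpers: seeded evaluation, argument checks, truncated normal.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage-specific child seed from a registry seed.  Documented
# splitting rule: child = (seed * 1000003 + stage_index) mod (2^31 - 1).
split_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  idx <- if (is.character(stage)) sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) else as.numeric(stage)
  as.integer((abs(as.numeric(seed)) * 1000003 + idx) %% (2^31 - 1))
}

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower)
    stop_invalid("`", name, "` must be a single finite number",
                 if (is.finite(lower)) paste0(" >= ", lower) else "")
  invisible(x)
}

# Inverse-CDF sampler for a standard normal truncated to [a, b].
rtruncnorm <- function(n, a, b) {
  u <- stats::runif(n, stats::pnorm(a), stats::pnorm(b))
  stats::qnorm(u)
}

# Sample Pearson correlation guarded against zero-variance inputs: returns
# NA_real_ (never an error) when either vector is constant.
safe_cor <- function(x, y, method = "pearson") {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}
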