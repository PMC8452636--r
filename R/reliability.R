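#' Split-half noise ceiling with Spearman-Brown correction
#'
#' Estimates the maximum attainable model-data correlation implied by the
#' data's own test-retest reliability.  The measurement runs are randomly
#' split into two halves; per-stimulus means are computed in each half;
#' their Pearson correlation `r` is Spearman-Brown corrected to
#' `2 r / (1 + r)` (the predicted reliability of the full-data mean); the
#' randomization is repeated and the mean and standard deviation over
#' randomizations are reported.  The study design uses 20 runs and 10
#' randomizations.
#'
#' With an odd number of runs the halves differ in size by one.  A split
#' with zero correlation denominator (constant half-means) raises an error.
#' Negative split correlations are reported uncorrected but flagged: the
#' Spearman-Brown formula presumes positive reliability.
#'
#' @param runs Numeric stimuli x runs matrix for one target (>= 2 runs).
#' @param n_randomizations Number of random splits (default 10).
#' @param seed Integer seed for the split randomization.
#' @return Object of class `ceiling_estimate`: list with `mean`, `sd`,
#'   `n_splits`, `per_split` (corrected values per randomization), and
#'   `unreliable` (TRUE if any split correlation was <= 0).
#' @export
split_half_ceiling <- function(runs, n_randomizations = 10L, seed = 1L) {
  runs <- as.matrix(runs)
  R <- ncol(runs)
  if (R < 2L) stop_invalid("need at least 2 runs for a split-half estimate")
  if (!all(is.finite(runs))) stop_invalid("runs must be finite")
  check_scalar_number(n_randomizations, "n_randomizations", lower = 1)
  split_r <- with_seed(seed, vapply(seq_len(n_randomizations), function(i) {
    perm <- sample.int(R)
    half1 <- perm[seq_len(ceiling(R / 2))]
    half2 <- setdiff(perm, half1)
    m1 <- rowMeans(runs[, half1, drop = FALSE])
    m2 <- rowMeans(runs[, half2, drop = FALSE])
    if (stats::sd(m1) == 0 || stats::sd(m2) == 0)
      stop_invalid("undefined correlation: constant half-means in split ", i)
    stats::cor(m1, m2)
  }, numeric(1)))
  per_split <- 2 * split_r / (1 + split_r)
  structure(list(mean = mean(per_split),
                 sd = stats::sd(per_split),
                 n_splits = as.integer(n_randomizations),
                 per_split = per_split,
                 split_r = split_r,
                 unreliable = any(split_r <= 0)),
            class = "ceiling_estimate")
}

#' @export
print.ceiling_estimate <- function(x, ...) {
  cat(sprintf("Split-half ceiling: %.3f (sd %.3f over %d splits)%s\n",
              x$mean, x$sd, x$n_splits,
              if (isTRUE(x$unreliable)) " [unreliable: r <= 0 in a split]" else ""))
  invisible(x)
}

#' Across-subject noise ceilings
#'
#' Quantifies how well one subject's data predict another's, the relevant
#' ceiling for across-subject generalization tests.  Two schemes:
#' `"pooled_vs_heldout"` correlates the pooled data of the n-1 remaining
#' subjects with each held-out subject (one value per held-out subject and
#' target); `"pairwise"` correlates every ordered subject pair (excluding
#' self-pairs).  Correlations are reported directly, without Spearman-Brown
#' correction.
#'
#' @param tables List of >= 2 aligned `beta_table`s, one per subject.
#' @param scheme `"pooled_vs_heldout"` or `"pairwise"`.
#' @return Data frame with columns `target`, `heldout` (or `train` and
#'   `test` for pairwise), and `r`.
#' @export
cross_subject_ceiling <- function(tables,
                                  scheme = c("pooled_vs_heldout", "pairwise")) {
  scheme <- match.arg(scheme)
  if (length(tables) < 2L) stop_invalid("need at least 2 subjects")
  pooled_check <- pool_subjects(tables)  # validates alignment
  targets <- colnames(pooled_check$values)
  n <- length(tables)
  subj <- vapply(tables, function(t) paste(t$subject, collapse = "+"),
                 character(1))
  rows <- list()
  if (scheme == "pooled_vs_heldout") {
    for (i in seq_len(n)) {
      pooled <- pool_subjects(tables[-i])
      for (tg in targets) {
        rows[[length(rows) + 1L]] <- data.frame(
          target = tg, heldout = subj[i],
          r = safe_cor(pooled$values[, tg], tables[[i]]$values[, tg]),
          stringsAsFactors = FALSE)
      }
    }
  } else {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      for (tg in targets) {
        rows[[length(rows) + 1L]] <- data.frame(
          target = tg, train = subj[i], test = subj[j],
          r = safe_cor(tables[[i]]$values[, tg], tables[[j]]$values[, tg]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
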