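#' Construct a table of per-stimulus response estimates
#'
#' A `beta_table` holds one response estimate ("beta") per stimulus and
#' target, where a target is a region of interest or a voxel, together with
#' the stimulus-level metadata the pipeline needs: the category of each
#' stimulus and the session group it was measured in.
#'
#' @param values Numeric matrix, stimuli in rows (rownames = stimulus ids),
#'   targets in columns (colnames = target ids).  All entries finite.
#' @param subject Subject identifier (or identifiers, after pooling).
#' @param categories Optional named character vector: category per stimulus.
#' @param sessions Optional named vector: session group per stimulus.
#' @return An object of class `beta_table`.
#' @export
beta_table <- function(values, subject = "subj_01", categories = NULL,
                       sessions = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_invalid("values must have stimulus rownames and target colnames")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop_invalid("stimulus and target ids must be unique")
  if (!all(is.finite(values))) stop_invalid("values must be finite")
  ids <- rownames(values)
  if (!is.null(categories)) {
    if (!all(ids %in% names(categories)))
      stop_invalid("categories must cover every stimulus id")
    categories <- categories[ids]
  }
  if (!is.null(sessions)) {
    if (!all(ids %in% names(sessions)))
      stop_invalid("sessions must cover every stimulus id")
    sessions <- sessions[ids]
  }
  structure(list(values = values, subject = subject,
                 categories = categories, sessions = sessions),
            class = "beta_table")
}

#' @export
print.beta_table <- function(x, ...) {
  cat("beta_table:", nrow(x$values), "stimuli x", ncol(x$values),
      "targets; subject(s):", paste(x$subject, collapse = ", "), "\n")
  invisible(x)
}

#' Standardize response estimates per session by the normalizer stimuli
#'
#' Within each session group and target, subtracts the mean and divides by
#' the standard deviation (sample convention, n-1 denominator) of the
#' responses to that group's normalizer stimuli.  This mirrors the practice
#' of normalizing each session's data by a fixed set of images repeated in
#' every session; the default study design uses groups of 100 stimuli with
#' 15 normalizers each.  Normalizer rows are transformed identically to the
#' rest of their group, so normalization is idempotent.
#'
#' @param betas A `beta_table`.
#' @param normalizer_ids Stimulus ids of the normalizer images.
#' @param session_groups Optional named vector mapping stimulus id to
#'   session group; defaults to the table's `sessions` metadata.  If neither
#'   is supplied all stimuli form one group.
#' @return A normalized `beta_table` with the same shape and metadata.
#' @export
normalize_session <- function(betas, normalizer_ids, session_groups = NULL) {
  stopifnot(inherits(betas, "beta_table"))
  ids <- rownames(betas$values)
  if (!all(normalizer_ids %in% ids))
    stop_invalid("normalizer ids absent from the table: ",
                 paste(setdiff(normalizer_ids, ids), collapse = ", "))
  groups <- session_groups %||% betas$sessions %||%
    stats::setNames(rep("all", length(ids)), ids)
  groups <- groups[ids]
  out <- betas$values
  for (g in unique(groups)) {
    rows <- which(groups == g)
    norm_rows <- intersect(rows, which(ids %in% normalizer_ids))
    if (length(norm_rows) < 2L)
      stop_invalid("session group '", g, "' has fewer than 2 normalizers")
    for (j in seq_len(ncol(out))) {
      mu <- mean(out[norm_rows, j])
      sdv <- stats::sd(out[norm_rows, j])
      if (sdv == 0)
        stop_invalid("degenerate normalizers (sd = 0) in session group '",
                     g, "', target '", colnames(out)[j], "'")
      out[rows, j] <- (out[rows, j] - mu) / sdv
    }
  }
  betas$values <- out
  betas
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pool response tables across subjects
#'
#' Elementwise (unweighted) mean across subjects of aligned tables,
#' producing the pooled response each region-level model is fitted to.
#'
#' @param tables List of `beta_table`s sharing stimulus and target ids.
#' @return A pooled `beta_table`; its `subject` field records the
#'   contributing subject ids.
#' @export
pool_subjects <- function(tables) {
  stopifnot(length(tables) >= 1L)
  ref <- tables[[1]]
  for (t in tables[-1]) {
    if (!identical(rownames(t$values), rownames(ref$values)) ||
        !identical(colnames(t$values), colnames(ref$values)))
      stop_invalid("tables are not aligned: differing stimulus/target ids (",
                   "subject ", paste(t$subject, collapse = ","), " vs ",
                   paste(ref$subject, collapse = ","), ")")
  }
  pooled <- Reduce(`+`, lapply(tables, `[[`, "values")) / length(tables)
  beta_table(pooled,
             subject = unlist(lapply(tables, `[[`, "subject")),
             categories = ref$categories, sessions = ref$sessions)
}
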