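# Plain-text readers/writers for the pipeline's artifact types.  Floats are
# written with 17 significant digits so write-then-read round-trips are
# exact at double precision.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a beta table as CSV
#'
#' Layout: one row per stimulus; columns `stimulus_id`, optional `category`
#' and `session`, then one column per target id.  Floats carry 17
#' significant digits (exact double round-trip).
#'
#' @param betas A `beta_table`.
#' @param path Output CSV path.
#' @return `write_beta_table` returns `path` invisibly; `read_beta_table`
#'   returns a `beta_table`.
#' @export
write_beta_table <- function(betas, path) {
  stopifnot(inherits(betas, "beta_table"))
  df <- data.frame(stimulus_id = rownames(betas$values),
                   stringsAsFactors = FALSE)
  if (!is.null(betas$categories)) df$category <- unname(betas$categories)
  if (!is.null(betas$sessions)) df$session <- as.character(unname(betas$sessions))
  for (j in colnames(betas$values)) df[[j]] <- fmt_num(betas$values[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_beta_table
#' @param subject Subject id to attach on read.
#' @export
read_beta_table <- function(path, subject = "subj_01") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"stimulus_id" %in% names(df))
    stop_invalid("malformed beta table ", path, ": no stimulus_id column")
  dup <- df$stimulus_id[duplicated(df$stimulus_id)]
  if (length(dup) > 0L)
    stop_invalid("duplicate stimulus_id in ", path, ": ",
                 paste(unique(dup), collapse = ", "))
  meta_cols <- intersect(c("stimulus_id", "category", "session"), names(df))
  target_cols <- setdiff(names(df), meta_cols)
  vals <- as.matrix(vapply(df[target_cols], as.numeric,
                           numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L,
                                     dimnames = list(NULL, target_cols))
  rownames(vals) <- df$stimulus_id
  beta_table(vals, subject = subject,
             categories = if ("category" %in% names(df))
               stats::setNames(df$category, df$stimulus_id) else NULL,
             sessions = if ("session" %in% names(df))
               stats::setNames(df$session, df$stimulus_id) else NULL)
}

#' Write / read a stimulus manifest (and images) to disk
#'
#' The manifest is a CSV with columns `stimulus_id`, `category`, `path`,
#' `is_normalizer`; images are written as PNG files next to it.
#'
#' @param stimuli A `stimulus_set`.
#' @param dir Output directory (created if missing).
#' @return `write_stimulus_set` returns the manifest path invisibly;
#'   `read_stimulus_set` returns a `stimulus_set`.
#' @export
write_stimulus_set <- function(stimuli, dir) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  man <- stimuli$manifest
  man$path <- file.path("images", paste0(man$stimulus_id, ".png"))
  for (i in seq_len(nrow(man)))
    png::writePNG(stimuli$images[[man$stimulus_id[i]]],
                  file.path(dir, man$path[i]))
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}

#' @rdname write_stimulus_set
#' @param manifest_path Path to a manifest CSV.
#' @export
read_stimulus_set <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("stimulus_id", "category", "path", "is_normalizer")
  if (!all(need %in% names(man)))
    stop_invalid("malformed manifest: needs columns ",
                 paste(need, collapse = ", "))
  dup <- man$stimulus_id[duplicated(man$stimulus_id)]
  if (length(dup) > 0L)
    stop_invalid("duplicate stimulus_id in manifest: ",
                 paste(unique(dup), collapse = ", "))
  base <- dirname(manifest_path)
  images <- lapply(seq_len(nrow(man)), function(i) {
    img <- png::readPNG(file.path(base, man$path[i]))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  names(images) <- man$stimulus_id
  structure(list(images = images,
                 manifest = man[, c("stimulus_id", "category",
                                    "is_normalizer")],
                 normalizer_ids = man$stimulus_id[man$is_normalizer == 1],
                 image_size = dim(images[[1]])[1:2], seed = NA_integer_),
            class = "stimulus_set")
}

#' Write / read a screening score table as CSV
#'
#' @param scores Score table data frame (from [screen_layers()]).
#' @param path CSV path.
#' @export
write_scores <- function(scores, path) {
  df <- scores
  df$score <- fmt_num(df$score)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$score <- as.numeric(df$score)
  df
}

#' Serialize a ceiling estimate to JSON
#'
#' @param ceiling A `ceiling_estimate`.
#' @param path JSON path.
#' @export
write_ceiling <- function(ceiling, path) {
  stopifnot(inherits(ceiling, "ceiling_estimate"))
  jsonlite::write_json(list(mean = ceiling$mean, sd = ceiling$sd,
                            n_splits = ceiling$n_splits,
                            per_split = ceiling$per_split),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize / restore a fitted mapping
#'
#' Single-file JSON archive holding the parameters, penalties, layer and
#' extractor identifiers, training stimulus ids, seed and convergence flag.
#'
#' @param mapping A `factorized_mapping` or `ridge_mapping`.
#' @param path JSON path.
#' @param layer,extractor_id,training_ids Optional provenance fields.
#' @export
write_mapping <- function(mapping, path, layer = NULL, extractor_id = NULL,
                          training_ids = NULL) {
  if (inherits(mapping, "factorized_mapping")) {
    payload <- list(type = "factorized", m = as.numeric(mapping$m),
                    m_dim = dim(mapping$m), w = mapping$w, b = mapping$b,
                    lambda_s = mapping$lambda_s, lambda_d = mapping$lambda_d,
                    dims = mapping$dims, converged = mapping$converged,
                    seed = mapping$opt$seed)
  } else if (inherits(mapping, "ridge_mapping")) {
    payload <- list(type = "ridge", weights = mapping$weights,
                    intercept = mapping$intercept, lambda = mapping$lambda,
                    dims = mapping$dims)
  } else stop_invalid("unsupported mapping type")
  payload$layer <- layer; payload$extractor_id <- extractor_id
  payload$training_ids <- training_ids
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(p$type, "factorized")) {
    structure(list(m = matrix(p$m, p$m_dim[1], p$m_dim[2]), w = p$w,
                   b = p$b, lambda_s = p$lambda_s, lambda_d = p$lambda_d,
                   dims = as.integer(p$dims), trace = NULL, loss = NA_real_,
                   converged = p$converged,
                   opt = opt_config(seed = p$seed %||% 1L)),
              class = "factorized_mapping")
  } else if (identical(p$type, "ridge")) {
    structure(list(weights = p$weights, intercept = p$intercept,
                   lambda = p$lambda, dims = as.integer(p$dims)),
              class = "ridge_mapping")
  } else stop_invalid("unknown mapping type in ", path)
}

#' Write / read an RDM as square CSV with stimulus-id header row and column
#'
#' @param rdm An `rdm`.
#' @param path CSV path.
#' @export
write_rdm <- function(rdm, path) {
  m <- unclass(rdm)
  df <- data.frame(stimulus_id = rownames(m), stringsAsFactors = FALSE)
  for (j in colnames(m)) df[[j]] <- fmt_num(m[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df$stimulus_id
  m <- as.matrix(vapply(df[setdiff(names(df), "stimulus_id")], as.numeric,
                        numeric(nrow(df))))
  rownames(m) <- ids
  structure(m, class = c("rdm", "matrix"))
}

#' Write / read the locking decisions
#'
#' The lockfile records every free choice frozen before final scoring: the
#' base model, the layer per region, the regularization pair per region,
#' and the seeds used at each locking stage.
#'
#' @param lock Named list with elements `base_model`, `layers`, `lambdas`,
#'   `seeds`.
#' @param path JSON path.
#' @export
write_lockfile <- function(lock, path) {
  need <- c("base_model", "layers", "lambdas", "seeds")
  if (!all(need %in% names(lock)))
    stop_invalid("lockfile needs fields: ", paste(need, collapse = ", "))
  jsonlite::write_json(lock, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lockfile
#' @export
read_lockfile <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
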