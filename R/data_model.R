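#' Keep the highest-variance features
#'
#' Reduces a feature matrix to the `k` columns with the largest sample
#' variance, the standard pre-filter applied to bulk omics matrices before
#' model training. Surviving columns keep their original order; variance ties
#' are broken by first occurrence.
#'
#' @param X numeric matrix, samples in rows, features in columns.
#' @param k number of features to keep (`1 <= k <= ncol(X)`).
#' @return the filtered matrix, same rows, `k` columns.
#' @examples
#' X <- cbind(a = c(1, 1, 1), b = c(0, 1, 2), c = c(0, 2, 4))
#' colnames(select_top_variance_features(X, 2))
#' @export
select_top_variance_features <- function(X, k) {
  check_finite_matrix(X, "X")
  k <- check_count(k, "k")
  if (k > ncol(X)) stop("k (", k, ") exceeds the number of features (", ncol(X), ")")
  v <- apply(X, 2L, stats::var)
  # order(-v) is stable, so equal variances resolve to the earlier column
  keep <- sort(order(-v)[seq_len(k)])
  X[, keep, drop = FALSE]
}

#' Fit a min-max scaler on training data and apply it
#'
#' Per-feature min-max scaling to \[0, 1\] with statistics taken from the
#' training split only, applied unchanged to any further matrices
#' (validation/test values may fall outside \[0, 1\]; there is no clipping).
#' Degenerate features (max == min on training data) map to constant 0.
#'
#' @param train training matrix the statistics are fitted on.
#' @param ... further matrices with the same columns to transform.
#' @return a list with `scaler` (class `minmax_scaler`), `train`, and one
#'   scaled matrix per extra argument (named as passed).
#' @export
fit_apply_scaler <- function(train, ...) {
  check_finite_matrix(train, "train")
  if (nrow(train) == 0L) stop("training matrix is empty")
  scaler <- structure(
    list(min = apply(train, 2L, min), max = apply(train, 2L, max)),
    class = "minmax_scaler"
  )
  others <- list(...)
  out <- c(
    list(scaler = scaler, train = apply_scaler(scaler, train)),
    lapply(others, function(m) apply_scaler(scaler, m))
  )
  out
}

#' Apply or invert a fitted min-max scaler
#'
#' @param scaler a `minmax_scaler` from [fit_apply_scaler()].
#' @param X matrix with the same feature columns as the training data.
#' @return the transformed matrix.
#' @export
apply_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  rng <- scaler$max - scaler$min
  degenerate <- rng == 0
  rng[degenerate] <- 1
  out <- sweep(sweep(X, 2L, scaler$min, "-"), 2L, rng, "/")
  if (any(degenerate)) out[, degenerate] <- 0
  out
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  rng <- scaler$max - scaler$min
  sweep(sweep(X, 2L, rng, "*"), 2L, scaler$min, "+")
}

#' Partition sample indices into minibatches
#'
#' @param n number of samples (or a dataset-sized object's row count).
#' @param bs batch size; the last block may be smaller.
#' @param shuffle permute indices before blocking?
#' @param seed integer seed used only when `shuffle = TRUE`; the global RNG
#'   state is left untouched.
#' @return list of integer index vectors; every index appears exactly once.
#' @export
make_batches <- function(n, bs, shuffle = FALSE, seed = NULL) {
  n <- check_count(n, "n")
  bs <- check_count(bs, "bs")
  idx <- seq_len(n)
  if (shuffle) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    if (!is.null(seed)) set.seed(seed)
    idx <- sample(idx)
  }
  split(idx, ceiling(seq_along(idx) / bs))
}

# ---- delimited I/O ---------------------------------------------------------
# Matrices travel as TSV with a header of feature names and the sample ID in
# the first column; the reader auto-detects tab vs comma.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read / write a feature matrix as delimited text
#'
#' @param X numeric matrix with sample IDs as row names.
#' @param path file path; tab-separated on write, tab or comma on read.
#' @return `read_feature_matrix` returns a numeric matrix with row names.
#' @export
write_feature_matrix <- function(X, path) {
  check_finite_matrix(X, "X")
  df <- data.frame(sample_id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- as.character(df[[1L]])
  check_finite_matrix(X, path)
  X
}

#' Read / write a survival label table
#'
#' Columns: `id`, `time_years`, `event`, `stratum`, `split`.
#'
#' @param labels data.frame with the columns above.
#' @param path file path.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("id", "time_years", "event", "stratum", "split") %in% names(labels)))
  utils::write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  df
}
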