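#' Configuration for the synthetic paired-omics generator
#'
#' Describes a latent-factor model of two paired tabular modalities with
#' right-censored survival outcomes. Both feature matrices are linear in a
#' shared set of `k_latent` standard-normal factors plus modality-specific
#' Gaussian noise; the event hazard is log-linear in the same factors, so the
#' features carry genuine survival signal. A configurable fraction of
#' modality-B rows is removed (train and validation splits only) to emulate
#' cohorts where one modality is incompletely assayed.
#'
#' @param n_samples number of samples.
#' @param d_A,d_B feature counts for modalities A and B.
#' @param k_latent number of shared latent factors.
#' @param loading_scale standard deviation of factor loadings; 0 removes all
#'   shared structure.
#' @param noise_sd_A,noise_sd_B feature noise standard deviations.
#' @param hazard_coefs log-hazard coefficients, one per latent factor.
#' @param baseline_hazard baseline event rate (1/year).
#' @param censor_rate censoring rate (1/year).
#' @param n_strata number of strata (e.g. cancer types); strata only shape
#'   the train/val/test split and per-stratum missingness rounding.
#' @param missing_fraction fraction of modality-B rows removed within
#'   train+val, in \[0, 1).
#' @param test_frac,val_frac test fraction of each stratum, and validation
#'   fraction of the remainder.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 1000, d_A = 200, d_B = 50, k_latent = 4,
                         loading_scale = 1, noise_sd_A = 0.1, noise_sd_B = 0.1,
                         hazard_coefs = rep(0.5, k_latent),
                         baseline_hazard = 0.08, censor_rate = 0.05,
                         n_strata = 3, missing_fraction = 0.04,
                         test_frac = 0.1, val_frac = 0.1, seed = 1) {
  cfg <- list(
    n_samples = check_count(n_samples, "n_samples"),
    d_A = check_count(d_A, "d_A"), d_B = check_count(d_B, "d_B"),
    k_latent = check_count(k_latent, "k_latent"),
    loading_scale = check_fraction(loading_scale, "loading_scale", hi = Inf),
    noise_sd_A = check_fraction(noise_sd_A, "noise_sd_A", hi = Inf),
    noise_sd_B = check_fraction(noise_sd_B, "noise_sd_B", hi = Inf),
    hazard_coefs = as.numeric(hazard_coefs),
    baseline_hazard = check_fraction(baseline_hazard, "baseline_hazard", hi = Inf, lo_open = TRUE),
    censor_rate = check_fraction(censor_rate, "censor_rate", hi = Inf, lo_open = TRUE),
    n_strata = check_count(n_strata, "n_strata"),
    missing_fraction = check_fraction(missing_fraction, "missing_fraction", hi = 1, hi_open = TRUE),
    test_frac = check_fraction(test_frac, "test_frac", lo_open = TRUE, hi_open = TRUE),
    val_frac = check_fraction(val_frac, "val_frac", lo_open = TRUE, hi_open = TRUE),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(cfg$hazard_coefs) != cfg$k_latent)
    stop("hazard_coefs must have length k_latent")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic paired-omics survival dataset
#'
#' Draws the latent-factor model described in [synth_config()]: factors
#' `z ~ N(0, 1)`, features `X = z W + noise` per modality with loadings drawn
#' once from the seed, event times exponential with rate
#' `baseline_hazard * exp(z %*% hazard_coefs)`, censoring times exponential
#' with `censor_rate`. Samples are split into train/val/test by stratified
#' shuffle, modality-B rows are then removed completely at random within
#' train+val only (the test split is always complete), and finally every
#' feature is min-max scaled to \[0, 1\] using training-split statistics.
#'
#' @param config a `synth_config`.
#' @param scale min-max scale the features from training statistics
#'   (default)? `FALSE` returns the raw factor-model features, e.g. to
#'   inspect the unscaled low-rank structure.
#' @return a `paired_omics` object: list with `sample_ids`, `X_A` (n x d_A),
#'   `X_B` (rows only for samples with modality B present), `b_present`
#'   (named logical), `time` (years), `event` (0/1), `stratum`, `split`
#'   (factors), the fitted scalers and the generating `config`.
#' @examples
#' ds <- generate_paired_omics(synth_config(n_samples = 200, seed = 7))
#' ds
#' @export
generate_paired_omics <- function(config, scale = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  n <- config$n_samples
  ids <- sprintf("S%05d", seq_len(n))
  z <- matrix(stats::rnorm(n * config$k_latent), n, config$k_latent)
  W_A <- matrix(stats::rnorm(config$k_latent * config$d_A, sd = config$loading_scale),
                config$k_latent, config$d_A)
  W_B <- matrix(stats::rnorm(config$k_latent * config$d_B, sd = config$loading_scale),
                config$k_latent, config$d_B)
  X_A <- z %*% W_A + matrix(stats::rnorm(n * config$d_A, sd = config$noise_sd_A), n, config$d_A)
  X_B <- z %*% W_B + matrix(stats::rnorm(n * config$d_B, sd = config$noise_sd_B), n, config$d_B)
  dimnames(X_A) <- list(ids, sprintf("A%04d", seq_len(config$d_A)))
  dimnames(X_B) <- list(ids, sprintf("B%04d", seq_len(config$d_B)))

  rate <- config$baseline_hazard * exp(drop(z %*% config$hazard_coefs))
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::rexp(n, config$censor_rate)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  stratum <- factor(sprintf("S%d", sample.int(config$n_strata, n, replace = TRUE)))

  ds <- structure(
    list(sample_ids = ids, X_A = X_A, X_B = X_B,
         b_present = stats::setNames(rep(TRUE, n), ids),
         time = stats::setNames(time, ids), event = stats::setNames(event, ids),
         stratum = stats::setNames(stratum, ids),
         split = NULL, scaler_A = NULL, scaler_B = NULL, config = config),
    class = "paired_omics"
  )
  ds <- split_paired_omics(ds, config$test_frac, config$val_frac,
                           seed = derive_seeds(config$seed, 2L)[1L])
  ds <- apply_b_missingness(ds, config$missing_fraction,
                            seed = derive_seeds(config$seed, 2L)[2L])
  if (scale) scale_paired_omics(ds) else ds
}

#' Assign stratified train/validation/test splits
#'
#' Within each stratum, `test_frac` of the samples go to the test split and
#' `val_frac` of the remainder to validation, by seeded shuffle.
#'
#' @param dataset a `paired_omics` object.
#' @param test_frac,val_frac split fractions in (0, 1).
#' @param seed integer seed for the shuffle.
#' @return the dataset with its `split` factor (re)assigned.
#' @export
split_paired_omics <- function(dataset, test_frac = 0.1, val_frac = 0.1, seed = 1) {
  stopifnot(inherits(dataset, "paired_omics"))
  test_frac <- check_fraction(test_frac, "test_frac", lo_open = TRUE, hi_open = TRUE)
  val_frac <- check_fraction(val_frac, "val_frac", lo_open = TRUE, hi_open = TRUE)
  if (test_frac + val_frac >= 1) stop("test_frac + val_frac must be < 1")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  split <- stats::setNames(rep("train", length(dataset$sample_ids)), dataset$sample_ids)
  for (s in levels(dataset$stratum)) {
    members <- names(dataset$stratum)[dataset$stratum == s]
    if (length(members) < 3L)
      stop("stratum ", s, " has fewer than 3 samples (", length(members), ")")
    members <- sample(members)
    n_test <- round(length(members) * test_frac)
    n_val <- round((length(members) - n_test) * val_frac)
    split[members[seq_len(n_test)]] <- "test"
    if (n_val > 0L)
      split[members[n_test + seq_len(n_val)]] <- "val"
  }
  dataset$split <- factor(split, levels = c("train", "val", "test"))
  names(dataset$split) <- dataset$sample_ids
  dataset
}

#' Remove modality-B rows completely at random
#'
#' Drops `fraction` of the modality-B rows within the train and validation
#' splits, per stratum with rounding; the test split is never reduced.
#'
#' @param dataset a split `paired_omics` object with full modality B.
#' @param fraction fraction to remove, in \[0, 1).
#' @param seed integer seed.
#' @return the dataset with `X_B` reduced and `b_present` updated.
#' @export
apply_b_missingness <- function(dataset, fraction, seed = 1) {
  stopifnot(inherits(dataset, "paired_omics"), !is.null(dataset$split))
  fraction <- check_fraction(fraction, "fraction", hi = 1, hi_open = TRUE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  present <- dataset$b_present
  for (s in levels(dataset$stratum)) {
    pool <- names(dataset$stratum)[dataset$stratum == s &
                                     dataset$split != "test" &
                                     present[names(dataset$stratum)]]
    n_drop <- length(pool) - round((1 - fraction) * length(pool))
    if (n_drop > 0L)
      present[sample(pool, n_drop)] <- FALSE
  }
  dataset$b_present <- present
  dataset$X_B <- dataset$X_B[rownames(dataset$X_B) %in% names(present)[present], , drop = FALSE]
  dataset
}

#' Min-max scale both modalities from training statistics
#'
#' @param dataset a split `paired_omics` object.
#' @return the dataset with scaled `X_A`/`X_B` and `scaler_A`/`scaler_B` set.
#' @export
scale_paired_omics <- function(dataset) {
  stopifnot(inherits(dataset, "paired_omics"), !is.null(dataset$split))
  train_ids <- names(dataset$split)[dataset$split == "train"]
  sa <- fit_apply_scaler(dataset$X_A[train_ids, , drop = FALSE])
  dataset$X_A <- apply_scaler(sa$scaler, dataset$X_A)
  b_train <- intersect(train_ids, rownames(dataset$X_B))
  sb <- fit_apply_scaler(dataset$X_B[b_train, , drop = FALSE])
  dataset$X_B <- apply_scaler(sb$scaler, dataset$X_B)
  dataset$scaler_A <- sa$scaler
  dataset$scaler_B <- sb$scaler
  dataset
}

#' @export
print.paired_omics <- function(x, ...) {
  cat("Paired two-modality omics dataset\n")
  cat(sprintf("  samples: %d (A: %d features, B: %d features)\n",
              length(x$sample_ids), ncol(x$X_A), ncol(x$X_B)))
  cat(sprintf("  modality B present: %d / %d\n", sum(x$b_present), length(x$b_present)))
  if (!is.null(x$split))
    cat("  split: ", paste(sprintf("%s=%d", levels(x$split), table(x$split)), collapse = ", "), "\n")
  cat(sprintf("  events: %d (%.0f%%), median follow-up %.1f years\n",
              sum(x$event), 100 * mean(x$event), stats::median(x$time)))
  invisible(x)
}

# rows of a modality restricted to a split (B additionally to present rows)
dataset_matrix <- function(dataset, modality = c("A", "B"), split = NULL) {
  modality <- match.arg(modality)
  ids <- dataset$sample_ids
  if (!is.null(split)) ids <- ids[dataset$split[ids] %in% split]
  if (modality == "A") dataset$X_A[ids, , drop = FALSE]
  else dataset$X_B[intersect(ids, rownames(dataset$X_B)), , drop = FALSE]
}

#' Write / read a paired-omics dataset as delimited text
#'
#' Writes `modality_A.tsv`, `modality_B.tsv` (feature matrices, sample IDs in
#' the first column) and `labels.tsv` (`id`, `time_years`, `event`, `stratum`,
#' `split`) into a directory.
#'
#' @param dataset a `paired_omics` object.
#' @param dir directory (created if missing).
#' @return `read_paired_omics` returns a `paired_omics` object (scalers and
#'   generating config are not round-tripped).
#' @export
write_paired_omics <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_matrix(dataset$X_A, file.path(dir, "modality_A.tsv"))
  write_feature_matrix(dataset$X_B, file.path(dir, "modality_B.tsv"))
  labels <- data.frame(
    id = dataset$sample_ids,
    time_years = unname(dataset$time),
    event = unname(dataset$event),
    stratum = as.character(unname(dataset$stratum)),
    split = as.character(unname(dataset$split))
  )
  write_labels(labels, file.path(dir, "labels.tsv"))
  invisible(dir)
}

#' @rdname write_paired_omics
#' @export
read_paired_omics <- function(dir) {
  X_A <- read_feature_matrix(file.path(dir, "modality_A.tsv"))
  X_B <- read_feature_matrix(file.path(dir, "modality_B.tsv"))
  labels <- read_labels(file.path(dir, "labels.tsv"))
  stopifnot(all(rownames(X_B) %in% rownames(X_A)),
            setequal(labels$id, rownames(X_A)))
  labels <- labels[match(rownames(X_A), labels$id), ]
  ids <- labels$id
  structure(
    list(sample_ids = ids, X_A = X_A[ids, , drop = FALSE], X_B = X_B,
         b_present = stats::setNames(ids %in% rownames(X_B), ids),
         time = stats::setNames(labels$time_years, ids),
         event = stats::setNames(as.integer(labels$event), ids),
         stratum = stats::setNames(factor(labels$stratum), ids),
         split = stats::setNames(factor(labels$split, levels = c("train", "val", "test")), ids),
         scaler_A = NULL, scaler_B = NULL, config = NULL),
    class = "paired_omics"
  )
}
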