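#' Time-dependent concordance index
#'
#' Fraction of comparable subject pairs whose predicted survival curves order
#' correctly. A pair (i, j) is comparable when `T_i < T_j` and subject i had
#' the event; it is concordant when `S_i(T_i) < S_j(T_i)`, each subject's
#' predicted cumulative survival being evaluated at the interval containing
#' `T_i`. Tied predicted survival counts 0.5; tied event times are not
#' comparable. This is the survival-curve generalisation of Harrell's C: the
#' two coincide when predictions are time-constant risks and censoring is
#' absent.
#'
#' @param cum_surv matrix (subjects x intervals) of predicted cumulative
#'   survival, e.g. `predict(fit, X, type = "cumulative")`.
#' @param time times in years (> 0).
#' @param event event indicators (1 = event, 0 = censored).
#' @return the concordance fraction in \[0, 1\].
#' @export
c_td <- function(cum_surv, time, event) {
  cum_surv <- as.matrix(cum_surv)
  n <- nrow(cum_surv)
  stopifnot(length(time) == n, length(event) == n)
  if (n < 2L) stop("at least 2 subjects are required")
  if (!any(event == 1)) stop("no events: concordance is undefined")
  k <- interval_index(time, ncol(cum_surv))
  S_at <- cum_surv[, k, drop = FALSE]          # S_at[j, i] = S_j(T_i)
  own <- diag(S_at)                            # S_i(T_i)
  comparable <- outer(time, time, "<") & (event == 1)  # rows i, cols j
  A <- matrix(own, n, n)                       # A[i, j] = S_i(T_i)
  B <- t(S_at)                                 # B[i, j] = S_j(T_i)
  n_comp <- sum(comparable)
  if (n_comp == 0L) stop("no comparable pairs")
  conc <- sum((A < B)[comparable]) + 0.5 * sum((A == B)[comparable])
  conc / n_comp
}

#' Cross-modal loss on a test set
#'
#' Evaluates the cross-modal reconstruction loss ([cross_modal_loss()]) on
#' complete test pairs and retains the per-sample losses for paired
#' statistical comparisons between translators.
#'
#' @param X_B_test,X_A_test complete paired test matrices.
#' @param encoder,decoder trained translator halves.
#' @return list with `loss` (scalar) and `per_sample` (named vector).
#' @export
test_cross_modal_loss <- function(X_B_test, X_A_test, encoder, decoder) {
  cross_modal_loss(X_B_test, X_A_test, encoder, decoder, per_sample = TRUE)
}

#' Structural correlation of mean feature profiles
#'
#' `pcc_mean_features` is the Pearson correlation between the length-d_B
#' mean-feature vector of the real test set and that of a reconstruction —
#' a check that imputations reproduce the feature-level structure rather
#' than pointwise values. `pcc_prior_decode` decodes `n_draws` standard
#' normal latent vectors, averages them, and correlates the result with the
#' real mean profile: high values indicate that the decoder produces
#' structurally faithful output even for latent inputs far from any encoded
#' sample (a regularised latent space).
#'
#' @param X_B_test real modality-B test matrix.
#' @param X_hat imputed/reconstructed matrix with the same feature columns.
#' @return Pearson correlation in \[-1, 1\].
#' @export
pcc_mean_features <- function(X_B_test, X_hat) {
  stopifnot(ncol(X_B_test) == ncol(X_hat))
  a <- colMeans(as.matrix(X_B_test))
  b <- colMeans(as.matrix(X_hat))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance mean feature vector")
  stats::cor(a, b)
}

#' @rdname pcc_mean_features
#' @param decoder trained modality-B decoder ([decode_latent()] interface).
#' @param n_draws number of prior draws (default: test-set size, so both
#'   means average comparable sample counts).
#' @param seed integer seed for the prior draws.
#' @export
pcc_prior_decode <- function(X_B_test, decoder, n_draws = nrow(X_B_test), seed = 1) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  latent_dim <- decoder_latent_dim(decoder)
  Z <- matrix(stats::rnorm(n_draws * latent_dim), n_draws, latent_dim)
  pcc_mean_features(X_B_test, decode_latent(decoder, Z))
}

decoder_latent_dim <- function(decoder) {
  if (!is.null(decoder$dec)) decoder$dec$widths[1L]
  else stop("cannot determine the decoder's latent dimension")
}

#' Percentile bootstrap confidence interval
#'
#' Resamples subjects with replacement, recomputes the metric on each
#' replicate, and returns the percentile interval. Replicates on which the
#' metric fails (e.g. a resample without comparable pairs) are redrawn, at
#' most 10 times each.
#'
#' @param metric_fn function of an integer index vector into the test set,
#'   returning a scalar.
#' @param n test-set size.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `estimate` (metric on the full set), `lower`, `upper`,
#'   and `replicates` (all bootstrap values, for paired comparisons).
#' @export
bootstrap_ci <- function(metric_fn, n, n_boot = 1000, level = 0.95, seed = 1) {
  n <- check_count(n, "n", min = 2L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  reps <- numeric(n_boot)
  for (r in seq_len(n_boot)) {
    val <- NULL
    for (try in seq_len(10L)) {
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(metric_fn(idx), error = function(e) NULL)
      if (!is.null(val)) break
    }
    if (is.null(val)) stop("bootstrap replicate failed 10 times")
    reps[r] <- val
  }
  alpha <- (1 - level) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(estimate = metric_fn(seq_len(n)), lower = qs[1L], upper = qs[2L],
       replicates = reps)
}

#' One-sided Wilcoxon signed-rank test on paired values
#'
#' Tests whether `a` systematically exceeds (`alternative = "greater"`) or
#' falls below (`"less"`) `b` on matched pairs. Zero differences are dropped
#' (an error if all are zero). With 25 or fewer non-zero differences the
#' exact sign-flip null distribution is used (the signed-rank distribution
#' when absolute differences are untied, exact enumeration over midranks
#' otherwise); beyond that, the normal approximation with tie and continuity
#' corrections.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param alternative direction of the alternative hypothesis for `a - b`.
#' @return the one-sided p-value.
#' @examples
#' wilcoxon_one_sided(2:6, 1:5, "greater")  # all 5 pairs favour a: 1/32
#' @export
wilcoxon_one_sided <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25L) {
    if (!anyDuplicated(abs(d))) {
      if (alternative == "greater") stats::psignrank(V - 1, n, lower.tail = FALSE)
      else stats::psignrank(V, n)
    } else {
      # exact sign-flip null with midranks: DP over doubled (integer) ranks
      r2 <- as.integer(round(2 * r))
      counts <- c(1, numeric(sum(r2)))        # counts[s + 1] = #assignments with sum s
      for (ri in r2) {
        shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
        counts <- counts + shifted
      }
      V2 <- as.integer(round(2 * V))
      if (alternative == "greater") sum(counts[(V2 + 1):length(counts)]) / 2^n
      else sum(counts[seq_len(V2 + 1)]) / 2^n
    }
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48)
    if (alternative == "greater") stats::pnorm((V - mu - 0.5) / sigma, lower.tail = FALSE)
    else stats::pnorm((V - mu + 0.5) / sigma)
  }
}

#' Evaluate a trained translator on the test split
#'
#' Computes the test cross-modal loss and both structural Pearson
#' correlations for one encoder/decoder pair.
#'
#' @param dataset a `paired_omics` dataset.
#' @param encoder,decoder trained translator halves.
#' @param seed seed for the prior draws.
#' @return list with `l_cm`, `per_sample`, `pcc_imputed`, `pcc_prior`.
#' @export
evaluate_translation <- function(dataset, encoder, decoder, seed = 1) {
  Xa <- dataset_matrix(dataset, "A", "test")
  Xb <- dataset_matrix(dataset, "B", "test")
  Xa <- Xa[rownames(Xb), , drop = FALSE]
  cm <- test_cross_modal_loss(Xb, Xa, encoder, decoder)
  imp <- impute_b_from_a(Xa, encoder, decoder)
  list(l_cm = cm$loss, per_sample = cm$per_sample,
       pcc_imputed = pcc_mean_features(Xb, imp$X_hat),
       pcc_prior = pcc_prior_decode(Xb, decoder, seed = seed))
}

#' Evaluate a survival predictor on the test split
#'
#' Computes the time-dependent concordance with a percentile bootstrap
#' confidence interval.
#'
#' @param fit a trained `surv_net`.
#' @param dataset a `paired_omics` dataset.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed. Evaluations sharing a seed resample identical
#'   test sets, so their replicates are pairable across methods.
#' @return list with `c_td`, `lower`, `upper`, `replicates`.
#' @export
evaluate_predictor <- function(fit, dataset, n_boot = 1000, seed = 1) {
  Xb <- dataset_matrix(dataset, "B", "test")
  time <- dataset$time[rownames(Xb)]
  event <- dataset$event[rownames(Xb)]
  surv <- predict(fit, Xb, type = "cumulative")
  res <- bootstrap_ci(function(idx) c_td(surv[idx, , drop = FALSE], time[idx], event[idx]),
                      n = nrow(Xb), n_boot = n_boot, seed = seed)
  list(c_td = res$estimate, lower = res$lower, upper = res$upper,
       replicates = res$replicates)
}
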