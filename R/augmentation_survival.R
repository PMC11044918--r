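#' Augmentation and prediction-training configuration
#'
#' Hyperparameters for training the discrete-time survival network under one
#' of the augmentation methods:
#' \describe{
#'   \item{multisurv}{no augmentation — real modality-B rows only.}
#'   \item{ov}{oversample rows (default: from the real B training set) with
#'     replacement each epoch; no imputation.}
#'   \item{tdimpute}{statically augment the training pool with deterministic
#'     autoencoder imputations of the missing-B rows; no oversampling.}
#'   \item{tdimpute_ov}{as tdimpute's translator, but used for per-epoch
#'     oversampled imputation.}
#'   \item{cmvae_adv}{statically augment with imputations from the
#'     adversarially aligned cross-modal VAE; no oversampling.}
#'   \item{cmvae_ov, cmvae_adv_ov}{per-epoch oversampled imputation from the
#'     cross-modal VAE (plain or adversarial).}
#' }
#' Methods without oversampling ignore `bsOV`, `t` and `gamma`.
#'
#' @param method one of the methods above.
#' @param bs batch size on real modality-B rows.
#' @param bsOV batch size of the oversampled/imputed batch per epoch.
#' @param t task-loss threshold: imputed rows are kept only when their
#'   per-row loss is strictly below `t` (`Inf` keeps all, 0 keeps none).
#' @param gamma weight in \[0, 1\] on the oversampled batch's loss.
#' @param epochs training epochs (default 400).
#' @param learning_rate Adam learning rate (default 1e-5).
#' @param hidden hidden widths of the prediction network.
#' @param n_intervals number of one-year intervals (default 30).
#' @param ov_pool pool for method `ov`: real B rows (default) or the imputed
#'   rows of missing-B samples.
#' @param seed integer seed.
#' @return a list of class `aug_config`.
#' @export
aug_config <- function(method = c("multisurv", "ov", "tdimpute", "tdimpute_ov",
                                  "cmvae_adv", "cmvae_ov", "cmvae_adv_ov"),
                       bs = 32, bsOV = 32, t = Inf, gamma = 1,
                       epochs = 400, learning_rate = 1e-5,
                       hidden = c(64, 32), n_intervals = 30,
                       ov_pool = c("real", "imputed"), seed = 1) {
  method <- match.arg(method)
  if (!(is.numeric(t) && length(t) == 1L && !is.na(t) && t >= 0))
    stop("t must be a loss threshold >= 0 (Inf keeps all)")
  structure(
    list(method = method, bs = check_count(bs, "bs"),
         bsOV = check_count(bsOV, "bsOV"), t = as.numeric(t),
         gamma = check_fraction(gamma, "gamma"),
         epochs = check_count(epochs, "epochs"),
         learning_rate = check_fraction(learning_rate, "learning_rate", hi = Inf, lo_open = TRUE),
         hidden = as.integer(hidden),
         n_intervals = check_count(n_intervals, "n_intervals"),
         ov_pool = match.arg(ov_pool),
         seed = check_count(seed, "seed", min = 0L)),
    class = "aug_config"
  )
}

uses_oversampling <- function(method) method %in% c("ov", "tdimpute_ov", "cmvae_ov", "cmvae_adv_ov")
uses_imputation <- function(method) method %in% c("tdimpute", "tdimpute_ov", "cmvae_adv",
                                                  "cmvae_ov", "cmvae_adv_ov")
uses_static_augmentation <- function(method) method %in% c("tdimpute", "cmvae_adv")

#' Impute modality-B rows from modality-A samples
#'
#' Computes `X_hat_B = Dec_B(Enc_A(X_A))` with the frozen, trained models,
#' using the posterior mean (deterministic: repeated calls are identical).
#' Survival labels are carried over verbatim from the source modality-A
#' samples — the continuous outcome is never imputed.
#'
#' @param X_A modality-A rows to impute from (row names are sample IDs).
#' @param encoder trained modality-A model supplying [encode_mean()].
#' @param decoder trained modality-B model supplying [decode_latent()].
#' @param time,event optional survival labels of the source samples, carried
#'   onto the imputed rows.
#' @return an object of class `imputed_batch`: list with `X_hat`, `time`,
#'   `event`, `task_loss` (NULL until scored), `keep` (NULL until filtered).
#' @export
impute_b_from_a <- function(X_A, encoder, decoder, time = NULL, event = NULL) {
  if (inherits(encoder, "mlp_vae") && !isTRUE(encoder$trained))
    stop("encoder is untrained")
  if (inherits(decoder, "mlp_vae") && !isTRUE(decoder$trained))
    stop("decoder is untrained")
  X_hat <- decode_latent(decoder, encode_mean(encoder, as.matrix(X_A)))
  rownames(X_hat) <- rownames(X_A)
  structure(list(X_hat = X_hat, time = time, event = event,
                 task_loss = NULL, keep = NULL),
            class = "imputed_batch")
}

#' Filter an imputed batch by its task loss
#'
#' Sets keep flags for rows whose per-row prediction loss is strictly below
#' the threshold `t`; row order is preserved.
#'
#' @param batch an `imputed_batch` whose `task_loss` has been computed.
#' @param t threshold (`Inf` keeps all; 0 keeps none under the strict rule).
#' @return the batch with `keep` set.
#' @export
filter_by_task_loss <- function(batch, t) {
  stopifnot(inherits(batch, "imputed_batch"), !is.null(batch$task_loss))
  batch$keep <- batch$task_loss < t
  batch
}

# ---- discrete-time survival likelihood -------------------------------------

interval_index <- function(time, n_intervals) {
  stopifnot(all(time > 0))
  pmin(ceiling(time), n_intervals)
}

clamp_prob <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)

#' Negative log-likelihood of discrete-time survival
#'
#' For conditional per-interval survival probabilities `p[i, j]` and a
#' subject whose time falls in interval `k` (one-year intervals, times beyond
#' the horizon clamped into the last interval): an event contributes
#' `-(sum_{j<k} log p_j + log(1 - p_k))`; a censored subject contributes
#' `-sum_{j<=k} log p_j`. Probabilities are clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param cond_surv matrix (subjects x intervals) of conditional survival
#'   probabilities.
#' @param time times in years (> 0).
#' @param event event indicators (1 = event, 0 = censored).
#' @param reduce return the batch mean (default) or the per-subject vector?
#' @return scalar mean loss, or per-subject losses.
#' @examples
#' survival_nll(matrix(0.5, 1, 30), time = 0.5, event = 1)  # -log 0.5
#' @export
survival_nll <- function(cond_surv, time, event, reduce = TRUE) {
  cond_surv <- as.matrix(cond_surv)
  n <- nrow(cond_surv); J <- ncol(cond_surv)
  stopifnot(length(time) == n, length(event) == n)
  p <- clamp_prob(cond_surv)
  k <- interval_index(time, J)
  lp <- log(p)
  before <- outer(rep(1, n), seq_len(J))
  lt_k <- sweep(before, 1L, k, "<")        # j < k
  loss <- -rowSums(lp * lt_k)
  at_k <- cbind(seq_len(n), k)
  loss <- loss - ifelse(event == 1, log(1 - p[at_k]), lp[at_k])
  if (reduce) mean(loss) else loss
}

# gradient of the mean NLL w.r.t. cond_surv (clamped region gets zero grad)
survival_nll_grad <- function(cond_surv, time, event, weight = 1) {
  n <- nrow(cond_surv); J <- ncol(cond_surv)
  p <- clamp_prob(cond_surv)
  inside <- (cond_surv > 1e-7) & (cond_surv < 1 - 1e-7)
  k <- interval_index(time, J)
  g <- matrix(0, n, J)
  lt_k <- sweep(outer(rep(1, n), seq_len(J)), 1L, k, "<")
  g[lt_k] <- -1 / p[lt_k]
  at_k <- cbind(seq_len(n), k)
  g[at_k] <- g[at_k] + ifelse(event == 1, 1 / (1 - p[at_k]), -1 / p[at_k])
  weight * (g * inside) / n
}

#' Cumulative survival from conditional interval probabilities
#'
#' `S(t_j) = prod_{i <= j} p_i` per subject; non-increasing in `j`.
#'
#' @param cond_surv matrix (subjects x intervals).
#' @return matrix of the same shape with cumulative survival curves.
#' @export
cumulative_survival <- function(cond_surv) {
  out <- t(apply(as.matrix(cond_surv), 1L, cumprod))
  rownames(out) <- rownames(cond_surv)
  out
}

# ---- deterministic cross-modal translator (TDImpute-style baseline) --------

#' Train a deterministic cross-modal translator
#'
#' A single autoencoder-shaped network mapping modality A directly to
#' modality B, trained to minimise the root-mean-squared error of
#' `Dec_B'(Enc_A'(X_A))` against the paired real B rows — no KL term, no
#' separate modality-A VAE, no adversary. Widths mirror the VAE
#' architecture; the checkpoint minimises validation RMSE. The result
#' implements [encode_mean()] and [decode_latent()], so imputation works
#' identically to the VAE route.
#'
#' @param X_A_train,X_A_val modality-A rows paired (by row name) with the B
#'   rows.
#' @param X_B_train,X_B_val real modality-B rows.
#' @param spec a [vae_spec()] describing the encoder half (input = d_A); the
#'   decoder half mirrors it onto `ncol(X_B_train)` outputs.
#' @return an object of class `translator_ae`.
#' @export
train_tdimpute <- function(X_A_train, X_B_train, X_A_val, X_B_val, spec) {
  paired_tr <- intersect(rownames(X_A_train), rownames(X_B_train))
  paired_va <- intersect(rownames(X_A_val), rownames(X_B_val))
  if (length(paired_tr) == 0L) stop("no ID-paired rows")
  X_A_train <- X_A_train[paired_tr, , drop = FALSE]
  X_B_train <- X_B_train[paired_tr, , drop = FALSE]
  X_A_val <- X_A_val[paired_va, , drop = FALSE]
  X_B_val <- X_B_val[paired_va, , drop = FALSE]

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  d_B <- ncol(X_B_train)
  hid_e <- hidden_widths(spec$input_dim, spec$n_layers_enc)
  enc <- mlp_init(c(spec$input_dim, hid_e, spec$latent_dim),
                  c(rep("relu", length(hid_e)), "linear"))
  hid_d <- rev(hidden_widths(d_B, spec$n_layers_dec))
  dec <- mlp_init(c(spec$latent_dim, hid_d, d_B),
                  c(rep("relu", length(hid_d)), "sigmoid"))
  opt_e <- adam_init(enc); opt_d <- adam_init(dec)
  shuffle_seeds <- derive_seeds(spec$seed + 4L, spec$epochs)

  hist <- vector("list", spec$epochs)
  best <- list(rmse = Inf, epoch = NA_integer_, enc = NULL, dec = NULL)
  for (epoch in seq_len(spec$epochs)) {
    batches <- make_batches(nrow(X_A_train), spec$batch_size, shuffle = TRUE,
                            seed = shuffle_seeds[epoch])
    tl <- 0
    for (b in batches) {
      Xa <- X_A_train[b, , drop = FALSE]
      Xb <- X_B_train[b, , drop = FALSE]
      ec <- mlp_forward(enc, Xa, keep_cache = TRUE)
      dc <- mlp_forward(dec, ec$out, keep_cache = TRUE)
      mse <- mean((Xb - dc$out)^2)
      if (!is.finite(mse)) stop("divergent loss (NaN) at epoch ", epoch)
      bdec <- mlp_backward(dec, dc, 2 * (dc$out - Xb) / (length(b) * d_B))
      benc <- mlp_backward(enc, ec, bdec$dinput)
      sd_ <- adam_step(dec, opt_d, bdec, spec$learning_rate)
      dec <- sd_$net; opt_d <- sd_$state
      se <- adam_step(enc, opt_e, benc, spec$learning_rate)
      enc <- se$net; opt_e <- se$state
      tl <- tl + mse * length(b)
    }
    pred <- mlp_forward(dec, mlp_forward(enc, X_A_val))
    val_rmse <- sqrt(mean((X_B_val - pred)^2))
    hist[[epoch]] <- data.frame(epoch = epoch, train_mse = tl / nrow(X_A_train),
                                val_rmse = val_rmse)
    if (val_rmse < best$rmse)
      best <- list(rmse = val_rmse, epoch = epoch, enc = enc, dec = dec)
  }
  structure(list(enc = best$enc, dec = best$dec, spec = spec,
                 history = do.call(rbind, hist), best_epoch = best$epoch,
                 trained = TRUE),
            class = "translator_ae")
}

#' @export
encode_mean.translator_ae <- function(object, X) mlp_forward(object$enc, as.matrix(X))

#' @export
decode_latent.translator_ae <- function(object, Z) {
  out <- mlp_forward(object$dec, as.matrix(Z))
  rownames(out) <- rownames(Z)
  out
}

#' @export
print.translator_ae <- function(x, ...) {
  cat("Deterministic cross-modal translator\n")
  cat("  encoder widths:", paste(x$enc$widths, collapse = " -> "), "\n")
  cat("  decoder widths:", paste(x$dec$widths, collapse = " -> "), "\n")
  cat(sprintf("  checkpoint epoch %d, validation RMSE %.4f\n", x$best_epoch,
              x$history$val_rmse[x$best_epoch]))
  invisible(x)
}

# ---- prediction-network training -------------------------------------------

#' Train the discrete-time survival network with optional augmentation
#'
#' The predictor is a fully connected network on modality-B features with one
#' sigmoid output per interval (conditional survival probabilities), trained
#' with the discrete-time negative log-likelihood. Per epoch, real B training
#' rows are shuffled into batches of size `bs`; depending on
#' `config$method`, the training pool may be statically augmented with
#' imputed missing-B rows (tdimpute, cmvae_adv), or an extra oversampled
#' batch of `bsOV` rows is drawn with replacement, imputed, scored, filtered
#' by the strict threshold `t`, and contributes `gamma` times its loss
#' (ov, tdimpute_ov, cmvae_ov, cmvae_adv_ov). Oversampling draws use an RNG
#' stream separate from batch shuffling, so `gamma = 0` reproduces the
#' unaugmented trajectory exactly. The checkpoint maximises validation
#' time-dependent concordance.
#'
#' @param dataset a `paired_omics` dataset with train/val splits.
#' @param config an [aug_config()].
#' @param encoder,decoder trained models for imputation (required by every
#'   method except multisurv and ov with the real pool).
#' @return an object of class `surv_net` with `history` (per-epoch training
#'   loss, validation concordance, oversampled rows kept) and `best_epoch`.
#' @export
train_predictor <- function(dataset, config, encoder = NULL, decoder = NULL) {
  stopifnot(inherits(dataset, "paired_omics"), inherits(config, "aug_config"))
  needs_models <- uses_imputation(config$method) ||
    (config$method == "ov" && config$ov_pool == "imputed")
  if (needs_models && (is.null(encoder) || is.null(decoder)))
    stop("method '", config$method, "' requires trained encoder and decoder models")

  train_ids <- names(dataset$split)[dataset$split == "train"]
  val_ids <- names(dataset$split)[dataset$split == "val"]
  Xb_train <- dataset_matrix(dataset, "B", "train")
  Xb_val <- dataset_matrix(dataset, "B", "val")
  if (nrow(Xb_train) == 0L) stop("no modality-B training rows")

  # static pool: real B rows, plus one-shot imputations of missing-B train
  # rows for the non-oversampling imputation methods
  pool_X <- Xb_train
  pool_time <- dataset$time[rownames(Xb_train)]
  pool_event <- dataset$event[rownames(Xb_train)]
  missing_ids <- train_ids[!dataset$b_present[train_ids]]
  if (uses_static_augmentation(config$method) && length(missing_ids)) {
    imp <- impute_b_from_a(dataset$X_A[missing_ids, , drop = FALSE], encoder, decoder,
                           time = dataset$time[missing_ids],
                           event = dataset$event[missing_ids])
    pool_X <- rbind(pool_X, imp$X_hat)
    pool_time <- c(pool_time, imp$time)
    pool_event <- c(pool_event, imp$event)
  }

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  net <- mlp_init(c(ncol(pool_X), config$hidden, config$n_intervals),
                  c(rep("relu", length(config$hidden)), "sigmoid"))
  opt <- adam_init(net)
  shuffle_seeds <- derive_seeds(config$seed + 5L, config$epochs)
  ov_seeds <- derive_seeds(config$seed + 6L, config$epochs)

  val_time <- dataset$time[rownames(Xb_val)]
  val_event <- dataset$event[rownames(Xb_val)]
  oversample <- uses_oversampling(config$method)

  hist <- vector("list", config$epochs)
  best <- list(ctd = -Inf, epoch = NA_integer_, net = NULL)
  for (epoch in seq_len(config$epochs)) {
    batches <- make_batches(nrow(pool_X), config$bs, shuffle = TRUE,
                            seed = shuffle_seeds[epoch])
    tl <- 0
    for (b in batches) {
      fc <- mlp_forward(net, pool_X[b, , drop = FALSE], keep_cache = TRUE)
      nll <- survival_nll(fc$out, pool_time[b], pool_event[b])
      if (!is.finite(nll)) stop("divergent loss (NaN) at epoch ", epoch)
      g <- mlp_backward(net, fc, survival_nll_grad(fc$out, pool_time[b], pool_event[b]))
      st <- adam_step(net, opt, g, config$learning_rate)
      net <- st$net; opt <- st$state
      tl <- tl + nll * length(b)
    }
    n_kept <- NA_integer_
    if (oversample && config$gamma > 0) {
      rng_now <- get_rng_state()
      set.seed(ov_seeds[epoch])
      ov <- draw_oversampled_batch(dataset, config, encoder, decoder, train_ids, Xb_train)
      restore_rng_state(rng_now)
      if (!is.null(ov)) {
        fc <- mlp_forward(net, ov$X, keep_cache = TRUE)
        per_row <- survival_nll(fc$out, ov$time, ov$event, reduce = FALSE)
        keep <- per_row < config$t
        n_kept <- sum(keep)
        if (n_kept > 0L) {
          fck <- mlp_forward(net, ov$X[keep, , drop = FALSE], keep_cache = TRUE)
          g <- mlp_backward(net, fck,
                            survival_nll_grad(fck$out, ov$time[keep], ov$event[keep],
                                              weight = config$gamma))
          st <- adam_step(net, opt, g, config$learning_rate)
          net <- st$net; opt <- st$state
        }
      }
    }
    val_ctd <- NA_real_
    if (nrow(Xb_val) >= 2L && any(val_event == 1)) {
      surv <- cumulative_survival(mlp_forward(net, Xb_val))
      # tiny validation sets can lack comparable pairs altogether
      val_ctd <- tryCatch(c_td(surv, val_time, val_event),
                          error = function(e) NA_real_)
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_nll = tl / nrow(pool_X),
                                val_ctd = val_ctd, n_ov_kept = n_kept)
    if (is.finite(val_ctd) && val_ctd > best$ctd)
      best <- list(ctd = val_ctd, epoch = epoch, net = net)
  }
  if (is.null(best$net)) best <- list(ctd = NA_real_, epoch = config$epochs, net = net)
  structure(list(net = best$net, config = config,
                 history = do.call(rbind, hist), best_epoch = best$epoch,
                 val_ctd = best$ctd, n_features = ncol(pool_X),
                 n_train_rows = nrow(pool_X), n_real_rows = nrow(Xb_train)),
            class = "surv_net")
}

# draw one oversampled batch (uses the ambient RNG stream, seeded by caller)
draw_oversampled_batch <- function(dataset, config, encoder, decoder, train_ids, Xb_train) {
  if (config$method == "ov" && config$ov_pool == "real") {
    if (nrow(Xb_train) == 0L) return(NULL)
    take <- sample.int(nrow(Xb_train), config$bsOV, replace = TRUE)
    ids <- rownames(Xb_train)[take]
    return(list(X = Xb_train[take, , drop = FALSE],
                time = dataset$time[ids], event = dataset$event[ids]))
  }
  take <- sample(train_ids, config$bsOV, replace = TRUE)
  imp <- impute_b_from_a(dataset$X_A[take, , drop = FALSE], encoder, decoder,
                         time = dataset$time[take], event = dataset$event[take])
  list(X = imp$X_hat, time = imp$time, event = imp$event)
}

#' @export
print.surv_net <- function(x, ...) {
  cat("Discrete-time survival network (", x$config$method, ")\n", sep = "")
  cat("  widths:", paste(x$net$widths, collapse = " -> "), "\n")
  cat(sprintf("  checkpoint epoch %d, validation C_td %.3f\n", x$best_epoch, x$val_ctd))
  invisible(x)
}

#' Predict conditional or cumulative survival curves
#'
#' @param object a trained `surv_net`.
#' @param newdata modality-B feature matrix.
#' @param type `"conditional"` for per-interval conditional survival
#'   probabilities, `"cumulative"` for the survival curve.
#' @param ... unused.
#' @return matrix (subjects x intervals).
#' @export
predict.surv_net <- function(object, newdata, type = c("cumulative", "conditional"), ...) {
  type <- match.arg(type)
  p <- mlp_forward(object$net, as.matrix(newdata))
  rownames(p) <- rownames(newdata)
  if (type == "conditional") p else cumulative_survival(p)
}
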