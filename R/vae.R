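#' Specification of a fully connected VAE
#'
#' Architecture and optimisation hyperparameters for one modality's
#' variational autoencoder. Hidden widths halve from the input dimension:
#' with `n_layers_enc = 3` and `input_dim = 1000` the encoder stack is
#' 1000 -> 500 -> 250 -> (mu, logvar) of `latent_dim`; the decoder mirrors it
#' in reverse and ends in a sigmoid, matching features scaled to \[0, 1\].
#'
#' @param input_dim number of input features.
#' @param n_layers_enc,n_layers_dec number of fully connected layers in the
#'   encoder and decoder (default 3 each).
#' @param latent_dim latent dimension (default 32); must stay below the last
#'   hidden width.
#' @param kl_weight plateau weight on the KL term (0.001 is the modality-A
#'   default; use 1e-4 for modality B).
#' @param cm_weight weight on the cross-modal loss in \[0, 1\] (default 0.6,
#'   the middle of the 0.4-0.8 band that preserves reconstruction quality).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs training epochs (default 400).
#' @param batch_size minibatch size (default 64).
#' @param anneal an [anneal_spec()] for cyclic KL annealing.
#' @param seed integer seed controlling initialisation, shuffling and
#'   reparameterisation noise.
#' @return a list of class `vae_spec`.
#' @export
vae_spec <- function(input_dim, n_layers_enc = 3, n_layers_dec = 3,
                     latent_dim = 32, kl_weight = 0.001, cm_weight = 0.6,
                     learning_rate = 1e-4, epochs = 400, batch_size = 64,
                     anneal = anneal_spec(), seed = 1) {
  spec <- list(
    input_dim = check_count(input_dim, "input_dim"),
    n_layers_enc = check_count(n_layers_enc, "n_layers_enc"),
    n_layers_dec = check_count(n_layers_dec, "n_layers_dec"),
    latent_dim = check_count(latent_dim, "latent_dim"),
    kl_weight = check_fraction(kl_weight, "kl_weight", hi = Inf),
    cm_weight = check_fraction(cm_weight, "cm_weight"),
    learning_rate = check_fraction(learning_rate, "learning_rate", hi = Inf, lo_open = TRUE),
    epochs = check_count(epochs, "epochs"),
    batch_size = check_count(batch_size, "batch_size"),
    anneal = anneal,
    seed = check_count(seed, "seed", min = 0L)
  )
  if (spec$latent_dim >= spec$input_dim) stop("latent_dim must be < input_dim")
  stopifnot(inherits(anneal, "anneal_spec"))
  structure(spec, class = "vae_spec")
}

#' Cyclic KL annealing schedule
#'
#' @param n_cycles number of annealing cycles over training (default 4).
#' @param ramp_fraction fraction of each cycle spent ramping linearly from 0
#'   to the plateau weight (default 0.5).
#' @return a list of class `anneal_spec`.
#' @export
anneal_spec <- function(n_cycles = 4, ramp_fraction = 0.5) {
  structure(
    list(n_cycles = check_count(n_cycles, "n_cycles"),
         ramp_fraction = check_fraction(ramp_fraction, "ramp_fraction", lo_open = TRUE)),
    class = "anneal_spec"
  )
}

#' KL weight at a given epoch under cyclic annealing
#'
#' Cycle length is `C = ceiling(total_epochs / n_cycles)`; within a cycle the
#' weight ramps linearly from 0 over the first `ramp_fraction` of the cycle,
#' then plateaus at `kl_weight`.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < total_epochs`.
#' @param total_epochs total number of training epochs.
#' @param anneal an [anneal_spec()].
#' @param kl_weight plateau weight.
#' @return the KL weight (beta) for that epoch.
#' @examples
#' anneal_beta(25, 400, anneal_spec(4, 0.5), 1e-4)  # ramping: 5e-5
#' anneal_beta(60, 400, anneal_spec(4, 0.5), 1e-4)  # plateau: 1e-4
#' @export
anneal_beta <- function(epoch, total_epochs, anneal = anneal_spec(), kl_weight = 1) {
  stopifnot(epoch >= 0, epoch < total_epochs)
  C <- ceiling(total_epochs / anneal$n_cycles)
  tau <- (epoch %% C) / C
  kl_weight * min(1, tau / anneal$ramp_fraction)
}

hidden_widths <- function(input_dim, n_layers) {
  if (n_layers < 2L) return(integer(0))
  as.integer(floor(input_dim / 2^seq_len(n_layers - 1L)))
}

#' Build an untrained fully connected VAE
#'
#' Weights are drawn from the current RNG stream; the training functions seed
#' it from the spec before building.
#'
#' @param spec a [vae_spec()].
#' @return an object of class `mlp_vae` with untrained encoder/decoder.
#' @export
build_mlp_vae <- function(spec) {
  stopifnot(inherits(spec, "vae_spec"))
  hid <- hidden_widths(spec$input_dim, spec$n_layers_enc)
  last <- if (length(hid)) hid[length(hid)] else spec$input_dim
  if (spec$latent_dim >= last)
    stop("latent_dim (", spec$latent_dim, ") must be smaller than the last hidden width (", last, ")")
  enc <- mlp_init(c(spec$input_dim, hid, 2L * spec$latent_dim),
                  c(rep("relu", length(hid)), "linear"))
  hid_d <- rev(hidden_widths(spec$input_dim, spec$n_layers_dec))
  dec <- mlp_init(c(spec$latent_dim, hid_d, spec$input_dim),
                  c(rep("relu", length(hid_d)), "sigmoid"))
  structure(list(enc = enc, dec = dec, spec = spec, history = NULL,
                 best_epoch = NA_integer_, trained = FALSE),
            class = "mlp_vae")
}

#' @export
print.mlp_vae <- function(x, ...) {
  cat("Fully connected VAE (", if (isTRUE(x$trained)) "trained" else "untrained", ")\n", sep = "")
  cat("  encoder widths:", paste(x$enc$widths, collapse = " -> "), "\n")
  cat("  decoder widths:", paste(x$dec$widths, collapse = " -> "), "\n")
  if (!is.null(x$history)) {
    cat(sprintf("  epochs: %d, checkpoint epoch: %d\n", nrow(x$history), x$best_epoch))
  }
  invisible(x)
}

# ---- losses ----------------------------------------------------------------

#' Reconstruction loss (mean squared error)
#'
#' Mean over samples and features of the squared difference.
#'
#' @param X,X_hat matrices of identical shape.
#' @return a scalar `>= 0`.
#' @export
recon_loss <- function(X, X_hat) {
  if (!identical(dim(as.matrix(X)), dim(as.matrix(X_hat))))
    stop("X and X_hat must have the same shape")
  mean((X - X_hat)^2)
}

#' Gaussian KL divergence loss
#'
#' Mean over samples of `-0.5 * sum(1 + logvar - mu^2 - exp(logvar))`, the
#' closed-form KL divergence from the diagonal-Gaussian posterior to the
#' standard-normal prior.
#'
#' @param mu,logvar matrices (samples x latent dims) or vectors (treated as
#'   one dimension per element of a single sample batch).
#' @return a scalar `>= 0`.
#' @examples
#' kl_loss(1, 0)        # 0.5
#' kl_loss(0, log(4))   # 0.5 * (3 - log(4))
#' @export
kl_loss <- function(mu, logvar) {
  mu <- if (is.matrix(mu)) mu else matrix(mu, nrow = 1L)
  logvar <- if (is.matrix(logvar)) logvar else matrix(logvar, nrow = 1L)
  stopifnot(identical(dim(mu), dim(logvar)), all(is.finite(mu)), all(is.finite(logvar)))
  mean(rowSums(-0.5 * (1 + logvar - mu^2 - exp(logvar))))
}

#' Reparameterisation trick
#'
#' Draws `z = mu + exp(0.5 * logvar) * eps` with `eps ~ N(0, 1)`.
#'
#' @param mu,logvar posterior parameters (matrices or vectors).
#' @param seed optional seed for the noise; the global RNG state is restored.
#' @return a draw of the same shape as `mu`.
#' @export
reparameterize <- function(mu, logvar, seed = NULL) {
  stopifnot(all(is.finite(mu)), all(is.finite(logvar)))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  eps <- stats::rnorm(length(mu))
  if (is.matrix(mu)) eps <- matrix(eps, nrow(mu), ncol(mu))
  mu + exp(0.5 * logvar) * eps
}

#' Encode to posterior parameters, or decode latents
#'
#' `vae_encode` maps inputs through the encoder and splits the output into
#' posterior mean and log-variance. `encode_mean` returns the posterior mean
#' only (the deterministic code used for imputation and latent alignment);
#' `decode_latent` maps latent vectors through the decoder. The latter two
#' are generic so that the deterministic translator ([train_tdimpute()])
#' shares the imputation interface.
#'
#' @param object a trained or untrained model.
#' @param X input feature matrix (samples x features).
#' @param Z latent matrix (samples x latent dims).
#' @return `vae_encode`: list with `mu` and `logvar`; `encode_mean`: the mean
#'   matrix; `decode_latent`: the decoded feature matrix.
#' @export
vae_encode <- function(object, X) {
  stopifnot(inherits(object, "mlp_vae"))
  out <- mlp_forward(object$enc, as.matrix(X))
  k <- object$spec$latent_dim
  list(mu = out[, seq_len(k), drop = FALSE],
       logvar = out[, k + seq_len(k), drop = FALSE])
}

#' @rdname vae_encode
#' @export
encode_mean <- function(object, X) UseMethod("encode_mean")

#' @export
encode_mean.mlp_vae <- function(object, X) vae_encode(object, X)$mu

#' @rdname vae_encode
#' @export
decode_latent <- function(object, Z) UseMethod("decode_latent")

#' @export
decode_latent.mlp_vae <- function(object, Z) {
  out <- mlp_forward(object$dec, as.matrix(Z))
  rownames(out) <- rownames(Z)
  out
}

#' @export
predict.mlp_vae <- function(object, newdata, type = c("reconstruction", "latent"), ...) {
  type <- match.arg(type)
  mu <- encode_mean(object, newdata)
  if (type == "latent") return(mu)
  out <- decode_latent(object, mu)
  rownames(out) <- rownames(newdata)
  out
}

#' Cross-modal reconstruction loss
#'
#' Mean squared difference between real modality-B rows and the modality-B
#' reconstruction decoded from the paired modality-A sample's latent code
#' (posterior mean): `mean((X_B - Dec_B(Enc_A(X_A)))^2)`. Rows are matched by
#' row name when both matrices are named, otherwise positionally.
#'
#' @param X_B real modality-B matrix.
#' @param X_A paired modality-A matrix (same samples).
#' @param encoder modality-A model supplying [encode_mean()].
#' @param decoder modality-B model supplying [decode_latent()].
#' @param per_sample also return the per-sample losses?
#' @return scalar loss, or list with `loss` and `per_sample`.
#' @export
cross_modal_loss <- function(X_B, X_A, encoder, decoder, per_sample = FALSE) {
  X_B <- as.matrix(X_B); X_A <- as.matrix(X_A)
  if (!is.null(rownames(X_B)) && !is.null(rownames(X_A))) {
    if (!setequal(rownames(X_B), rownames(X_A)))
      stop("X_A and X_B rows are not ID-paired")
    X_A <- X_A[rownames(X_B), , drop = FALSE]
  } else if (nrow(X_B) != nrow(X_A)) {
    stop("X_A and X_B must have the same number of rows when unnamed")
  }
  X_hat <- decode_latent(decoder, encode_mean(encoder, X_A))
  ps <- rowMeans((X_B - X_hat)^2)
  if (per_sample) list(loss = mean(ps), per_sample = ps) else mean(ps)
}

# ---- training --------------------------------------------------------------

# One VAE gradient step on a minibatch. Z_cm: frozen modality-A posterior
# means paired with the batch (NULL disables the cross-modal term; its
# gradient reaches the decoder only, the A encoder being frozen).
vae_batch_grads <- function(vae, Xb, beta, cm_weight = 0, Z_cm = NULL) {
  nb <- nrow(Xb)
  k <- vae$spec$latent_dim
  ec <- mlp_forward(vae$enc, Xb, keep_cache = TRUE)
  mu <- ec$out[, seq_len(k), drop = FALSE]
  lv <- ec$out[, k + seq_len(k), drop = FALSE]
  lv_mask <- (lv > -10) & (lv < 10)     # guard exp() blow-ups early in training
  lv <- pmin(pmax(lv, -10), 10)
  eps <- matrix(stats::rnorm(nb * k), nb, k)
  sd <- exp(0.5 * lv)
  z <- mu + sd * eps

  dc <- mlp_forward(vae$dec, z, keep_cache = TRUE)
  X_hat <- dc$out
  l_rec <- mean((Xb - X_hat)^2)
  d_xhat <- 2 * (X_hat - Xb) / (nb * ncol(Xb))
  bdec <- mlp_backward(vae$dec, dc, d_xhat)
  dz <- bdec$dinput

  l_kl <- mean(rowSums(-0.5 * (1 + lv - mu^2 - exp(lv))))
  dmu <- dz + beta * mu / nb
  dlv <- (dz * 0.5 * sd * eps + beta * 0.5 * (exp(lv) - 1) / nb) * lv_mask
  benc <- mlp_backward(vae$enc, ec, cbind(dmu, dlv))

  l_cm <- NA_real_
  gdec <- list(W = bdec$W, b = bdec$b)
  if (!is.null(Z_cm)) {
    dc2 <- mlp_forward(vae$dec, Z_cm, keep_cache = TRUE)
    l_cm <- mean((Xb - dc2$out)^2)
    d_cm <- 2 * (dc2$out - Xb) / (nb * ncol(Xb))
    bdec2 <- mlp_backward(vae$dec, dc2, d_cm)
    gdec <- grads_add(gdec, bdec2, weight2 = cm_weight)
  }
  list(g_enc = list(W = benc$W, b = benc$b), g_dec = gdec,
       l_rec = l_rec, l_kl = l_kl, l_cm = l_cm)
}

vae_val_metrics <- function(vae, X_val, X_A_val = NULL, encoder_A = NULL) {
  post <- vae_encode(vae, X_val)
  X_hat <- decode_latent(vae, post$mu)
  out <- list(recon = mean((X_val - X_hat)^2), kl = kl_loss(post$mu, post$logvar))
  if (!is.null(X_A_val))
    out$cm <- cross_modal_loss(X_val, X_A_val, encoder_A, vae)
  out
}

#' Train the modality-A VAE
#'
#' Optimises `L_recon + beta(epoch) * L_KL` with Adam under the cyclic KL
#' annealing schedule. The returned checkpoint is the epoch with the lowest
#' validation reconstruction loss among epochs whose validation KL exceeds
#' 1e-6 — reconstruction minimised while the KL has not vanished (posterior
#' collapse guard). The result is frozen downstream: it supplies the fixed
#' latent space that modality B is aligned to.
#'
#' @param X_train,X_val scaled feature matrices.
#' @param spec a [vae_spec()].
#' @return a trained `mlp_vae` with a per-epoch `history` data frame.
#' @export
train_vae_a <- function(X_train, X_val, spec) {
  check_finite_matrix(X_train, "X_train")
  if (nrow(X_train) == 0L) stop("training matrix is empty")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  vae <- build_mlp_vae(spec)
  opt_e <- adam_init(vae$enc)
  opt_d <- adam_init(vae$dec)
  shuffle_seeds <- derive_seeds(spec$seed + 1L, spec$epochs)

  hist <- vector("list", spec$epochs)
  best <- list(recon = Inf, epoch = NA_integer_, enc = NULL, dec = NULL)
  fallback <- list(recon = Inf, enc = NULL, dec = NULL, epoch = NA_integer_)
  for (epoch in seq_len(spec$epochs)) {
    beta <- anneal_beta(epoch - 1L, spec$epochs, spec$anneal, spec$kl_weight)
    batches <- make_batches(nrow(X_train), spec$batch_size, shuffle = TRUE,
                            seed = shuffle_seeds[epoch])
    tl_rec <- 0; tl_kl <- 0
    for (b in batches) {
      g <- vae_batch_grads(vae, X_train[b, , drop = FALSE], beta)
      if (!all(is.finite(c(g$l_rec, g$l_kl))))
        stop("divergent loss (NaN) at epoch ", epoch)
      se <- adam_step(vae$enc, opt_e, g$g_enc, spec$learning_rate)
      vae$enc <- se$net; opt_e <- se$state
      sd_ <- adam_step(vae$dec, opt_d, g$g_dec, spec$learning_rate)
      vae$dec <- sd_$net; opt_d <- sd_$state
      tl_rec <- tl_rec + g$l_rec * length(b)
      tl_kl <- tl_kl + g$l_kl * length(b)
    }
    vm <- vae_val_metrics(vae, X_val)
    hist[[epoch]] <- data.frame(epoch = epoch, beta = beta,
                                train_recon = tl_rec / nrow(X_train),
                                train_kl = tl_kl / nrow(X_train),
                                val_recon = vm$recon, val_kl = vm$kl)
    if (vm$recon < fallback$recon) {
      fallback <- list(recon = vm$recon, enc = vae$enc, dec = vae$dec, epoch = epoch)
    }
    if (vm$kl > 1e-6 && vm$recon < best$recon) {
      best <- list(recon = vm$recon, epoch = epoch, enc = vae$enc, dec = vae$dec)
    }
  }
  if (is.null(best$enc)) {
    warning("validation KL never exceeded 1e-6; falling back to best reconstruction checkpoint")
    best <- fallback
    best$epoch <- fallback$epoch
  }
  vae$enc <- best$enc
  vae$dec <- best$dec
  vae$history <- do.call(rbind, hist)
  vae$best_epoch <- best$epoch
  vae$trained <- TRUE
  vae
}

#' Train the modality-B VAE aligned to the frozen modality-A latent space
#'
#' Optimises `L_recon + beta(epoch) * L_KL + cm_weight * L_CM`, where the
#' cross-modal loss compares each real B row with the decoding of its paired
#' A sample's (frozen) posterior mean. The checkpoint is the epoch minimising
#' validation `L_CM` — the stopping rule that directly targets imputation
#' quality. With `cm_weight = 0` this reduces exactly to a plain VAE on B.
#'
#' @param X_B_train,X_B_val scaled modality-B matrices (paired rows only).
#' @param X_A_train,X_A_val paired modality-A rows (matched by row name).
#' @param vae_A the trained, frozen modality-A VAE.
#' @param spec a [vae_spec()] for modality B.
#' @return a trained `mlp_vae`.
#' @export
train_vae_b <- function(X_B_train, X_B_val, X_A_train, X_A_val, vae_A, spec) {
  fit_vae_b_engine(X_B_train, X_B_val, X_A_train, X_A_val, vae_A, spec,
                   disc_spec = NULL, sched = NULL)
}

# Shared engine for plain and adversarial modality-B training. When
# disc_spec/sched are supplied, epochs past the warm-up add the discriminator
# and encoder-adversarial steps (see train_adversarial).
fit_vae_b_engine <- function(X_B_train, X_B_val, X_A_train, X_A_val, vae_A, spec,
                             disc_spec = NULL, sched = NULL) {
  stopifnot(inherits(vae_A, "mlp_vae"))
  check_finite_matrix(X_B_train, "X_B_train")
  paired_tr <- intersect(rownames(X_B_train), rownames(X_A_train))
  paired_va <- intersect(rownames(X_B_val), rownames(X_A_val))
  if (length(paired_tr) == 0L) stop("no ID-paired rows between X_B_train and X_A_train")
  X_B_train <- X_B_train[paired_tr, , drop = FALSE]
  X_B_val <- X_B_val[paired_va, , drop = FALSE]
  Z_A_train <- encode_mean(vae_A, X_A_train[paired_tr, , drop = FALSE])
  X_A_val <- X_A_val[paired_va, , drop = FALSE]

  adversarial <- !is.null(disc_spec)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  vae <- build_mlp_vae(spec)
  opt_e <- adam_init(vae$enc)
  opt_d <- adam_init(vae$dec)
  disc <- NULL; opt_disc <- NULL
  if (adversarial) {
    # build from an independent stream so the VAE's noise draws are identical
    # whether or not a discriminator exists (warmup == total must reduce to
    # plain train_vae_b)
    rng_now <- get_rng_state()
    set.seed(derive_seeds(spec$seed + 3L, 1L))
    disc <- build_discriminator(disc_spec, latent_dim = spec$latent_dim)
    restore_rng_state(rng_now)
    opt_disc <- adam_init(disc$net)
  }
  epochs <- if (adversarial) sched$total_epochs else spec$epochs
  warmup <- if (adversarial) sched$warmup_epochs else epochs
  shuffle_seeds <- derive_seeds(spec$seed + 2L, epochs)

  hist <- vector("list", epochs)
  best <- list(cm = Inf, epoch = NA_integer_, enc = NULL, dec = NULL)
  for (epoch in seq_len(epochs)) {
    beta <- anneal_beta(epoch - 1L, epochs, spec$anneal, spec$kl_weight)
    batches <- make_batches(nrow(X_B_train), spec$batch_size, shuffle = TRUE,
                            seed = shuffle_seeds[epoch])
    tl <- c(rec = 0, kl = 0, cm = 0)
    for (b in batches) {
      g <- vae_batch_grads(vae, X_B_train[b, , drop = FALSE], beta,
                           cm_weight = spec$cm_weight,
                           Z_cm = Z_A_train[b, , drop = FALSE])
      if (!all(is.finite(c(g$l_rec, g$l_kl, g$l_cm))))
        stop("divergent loss (NaN) at epoch ", epoch, " (VAE-B step)")
      se <- adam_step(vae$enc, opt_e, g$g_enc, spec$learning_rate)
      vae$enc <- se$net; opt_e <- se$state
      sd_ <- adam_step(vae$dec, opt_d, g$g_dec, spec$learning_rate)
      vae$dec <- sd_$net; opt_d <- sd_$state
      tl <- tl + c(g$l_rec, g$l_kl, g$l_cm) * length(b)
    }
    d_loss <- NA_real_; a_loss <- NA_real_; score_gap <- NA_real_
    if (adversarial && epoch > warmup) {
      # (2) discriminator step, VAE frozen
      z_B <- encode_mean(vae, X_B_train)
      step2 <- disc_grad_step(disc, opt_disc, Z_A_train, z_B, disc_spec$learning_rate)
      disc <- step2$disc; opt_disc <- step2$state; d_loss <- step2$loss
      # (3) encoder-B step on the adversarial loss, discriminator frozen
      step3 <- adv_grad_step(vae, opt_e, disc, X_B_train, spec$learning_rate)
      vae <- step3$vae; opt_e <- step3$state; a_loss <- step3$loss
      if (!all(is.finite(c(d_loss, a_loss))))
        stop("divergent loss (NaN) at epoch ", epoch, " (adversarial step)")
      score_gap <- abs(mean(disc_scores(disc, Z_A_train)) -
                         mean(disc_scores(disc, encode_mean(vae, X_B_train))))
    }
    vm <- vae_val_metrics(vae, X_B_val, X_A_val, vae_A)
    hist[[epoch]] <- data.frame(epoch = epoch, beta = beta,
                                train_recon = tl[["rec"]] / nrow(X_B_train),
                                train_kl = tl[["kl"]] / nrow(X_B_train),
                                train_cm = tl[["cm"]] / nrow(X_B_train),
                                val_recon = vm$recon, val_kl = vm$kl, val_cm = vm$cm,
                                disc_loss = d_loss, adv_loss = a_loss,
                                score_gap = score_gap)
    if (vm$cm < best$cm) {
      best <- list(cm = vm$cm, epoch = epoch, enc = vae$enc, dec = vae$dec)
    }
  }
  vae$enc <- best$enc
  vae$dec <- best$dec
  vae$history <- do.call(rbind, hist)
  vae$best_epoch <- best$epoch
  vae$trained <- TRUE
  if (adversarial) list(vae = vae, discriminator = disc) else vae
}
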