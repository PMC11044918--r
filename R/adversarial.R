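#' Discriminator specification for adversarial latent alignment
#'
#' A small fully connected network scoring latent vectors; trained with the
#' least-squares GAN objective to tell modality-A latents (label 1) from
#' modality-B latents (label 0). Hidden widths halve from the latent
#' dimension, floor-bounded at 8; the output layer is linear (one score).
#'
#' @param n_layers number of fully connected layers (default 4).
#' @param learning_rate Adam learning rate (default 5e-5).
#' @return a list of class `disc_spec`.
#' @export
disc_spec <- function(n_layers = 4, learning_rate = 5e-5) {
  structure(
    list(n_layers = check_count(n_layers, "n_layers"),
         learning_rate = check_fraction(learning_rate, "learning_rate", hi = Inf, lo_open = TRUE)),
    class = "disc_spec"
  )
}

#' Adversarial training schedule
#'
#' The first `warmup_epochs` train only the modality-B VAE so it acquires
#' good reconstructions before the adversarial game starts.
#'
#' @param total_epochs total training epochs (default 400).
#' @param warmup_epochs VAE-only epochs at the start (default 100).
#' @return a list of class `adv_schedule`.
#' @export
adv_schedule <- function(total_epochs = 400, warmup_epochs = 100) {
  total_epochs <- check_count(total_epochs, "total_epochs")
  warmup_epochs <- check_count(warmup_epochs, "warmup_epochs", min = 0L)
  if (warmup_epochs > total_epochs) stop("warmup_epochs must be <= total_epochs")
  structure(list(total_epochs = total_epochs, warmup_epochs = warmup_epochs),
            class = "adv_schedule")
}

build_discriminator <- function(spec, latent_dim) {
  hid <- pmax(as.integer(floor(latent_dim / 2^seq_len(spec$n_layers - 1L))), 8L)
  net <- mlp_init(c(latent_dim, hid, 1L), c(rep("relu", length(hid)), "linear"))
  structure(list(net = net, spec = spec, latent_dim = latent_dim),
            class = "latent_discriminator")
}

disc_scores <- function(disc, Z) drop(mlp_forward(disc$net, as.matrix(Z)))

#' Least-squares GAN losses
#'
#' `disc_loss` is the discriminator objective
#' `mean((scores_A - 1)^2) + mean((scores_B - 0)^2)`: modality-A latents are
#' pushed toward label 1 and modality-B latents toward 0. `adv_loss` is the
#' generator-side objective `mean((scores_B - 1)^2)` with the labels swapped;
#' during training its gradient flows only through the modality-B encoder.
#'
#' @param scores_A,scores_B discriminator scores on latents from the two
#'   modalities.
#' @return a scalar loss.
#' @examples
#' disc_loss(rep(1, 4), rep(0, 4))  # perfect discrimination: 0
#' adv_loss(rep(0.5, 4))            # 0.25
#' @export
disc_loss <- function(scores_A, scores_B) {
  if (length(scores_A) == 0L || length(scores_B) == 0L) stop("empty score vector")
  stopifnot(all(is.finite(scores_A)), all(is.finite(scores_B)))
  mean((scores_A - 1)^2) + mean(scores_B^2)
}

#' @rdname disc_loss
#' @export
adv_loss <- function(scores_B) {
  stopifnot(all(is.finite(scores_B)))
  mean((scores_B - 1)^2)
}

# one discriminator update on frozen latents
disc_grad_step <- function(disc, state, Z_A, Z_B, lr) {
  ca <- mlp_forward(disc$net, Z_A, keep_cache = TRUE)
  cb <- mlp_forward(disc$net, Z_B, keep_cache = TRUE)
  loss <- disc_loss(drop(ca$out), drop(cb$out))
  ga <- mlp_backward(disc$net, ca, 2 * (ca$out - 1) / nrow(Z_A))
  gb <- mlp_backward(disc$net, cb, 2 * cb$out / nrow(Z_B))
  g <- grads_add(ga, gb)
  st <- adam_step(disc$net, state, g, lr)
  disc$net <- st$net
  list(disc = disc, state = st$state, loss = loss)
}

# one encoder-B update on the adversarial loss; discriminator and decoder
# stay untouched
adv_grad_step <- function(vae, state, disc, X_B, lr) {
  k <- vae$spec$latent_dim
  ec <- mlp_forward(vae$enc, X_B, keep_cache = TRUE)
  mu <- ec$out[, seq_len(k), drop = FALSE]
  dc <- mlp_forward(disc$net, mu, keep_cache = TRUE)
  loss <- adv_loss(drop(dc$out))
  bd <- mlp_backward(disc$net, dc, 2 * (dc$out - 1) / nrow(X_B))
  dmu <- bd$dinput
  be <- mlp_backward(vae$enc, ec, cbind(dmu, matrix(0, nrow(X_B), k)))
  st <- adam_step(vae$enc, state, list(W = be$W, b = be$b), lr)
  vae$enc <- st$net
  list(vae = vae, state = st$state, loss = loss)
}

#' Train the modality-B VAE with adversarial latent alignment
#'
#' Identical to [train_vae_b()] for the first `warmup_epochs`; afterwards
#' each epoch runs three steps in order: (1) the usual VAE-B step
#' (`L_recon + beta * L_KL + cm_weight * L_CM`); (2) a discriminator step on
#' the least-squares GAN loss with the VAE frozen; (3) a modality-B encoder
#' step on the swapped-label adversarial loss with the discriminator frozen.
#' Latents shown to the discriminator are posterior means. The checkpoint is
#' still the epoch minimising validation `L_CM`. With
#' `warmup_epochs = total_epochs` (and `spec$epochs` equal to
#' `total_epochs`) the adversarial path never runs and the result is
#' identical to plain [train_vae_b()].
#'
#' @inheritParams train_vae_b
#' @param d_spec a [disc_spec()].
#' @param sched an [adv_schedule()].
#' @return list with `vae` (trained `mlp_vae`) and `discriminator`.
#' @export
train_adversarial <- function(X_B_train, X_B_val, X_A_train, X_A_val, vae_A,
                              spec, d_spec = disc_spec(), sched = adv_schedule()) {
  stopifnot(inherits(d_spec, "disc_spec"), inherits(sched, "adv_schedule"))
  fit_vae_b_engine(X_B_train, X_B_val, X_A_train, X_A_val, vae_A, spec,
                   disc_spec = d_spec, sched = sched)
}
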