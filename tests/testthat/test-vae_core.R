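test_that("reconstruction loss is the mean squared error with its scaling laws", {
  X <- matrix(runif(12), 3, 4)
  expect_equal(recon_loss(X, X), 0)
  Y <- X; Y[1, 1] <- Y[1, 1] + 0.5
  expect_equal(recon_loss(X, Y), 0.25 / 12)
  expect_equal(recon_loss(matrix(0.5), matrix(0)), 0.25)
  R <- matrix(rnorm(12), 3, 4)
  expect_equal(recon_loss(X, X + 2 * R), 4 * recon_loss(X, X + R))
  expect_error(recon_loss(X, X[, 1:2]), "same shape")
})

test_that("KL loss matches the closed form and a quadrature oracle", {
  expect_equal(kl_loss(0, 0), 0)
  expect_equal(kl_loss(1, 0), 0.5)
  expect_equal(kl_loss(0, log(4)), 0.5 * (3 - log(4)))

  # oracle: numerically integrate KL(q || N(0,1)) per dimension
  kl_quad <- function(mu, lv) {
    sd <- exp(0.5 * lv)
    integrand <- function(x) {
      q <- dnorm(x, mu, sd)
      ifelse(q > 0, q * (dnorm(x, mu, sd, log = TRUE) - dnorm(x, log = TRUE)), 0)
    }
    integrate(integrand, mu - 12 * sd, mu + 12 * sd, rel.tol = 1e-10)$value
  }
  set.seed(31)
  mu <- matrix(rnorm(1000, sd = 1.5), 250, 4)
  lv <- matrix(rnorm(1000, sd = 0.8), 250, 4)
  oracle <- mean(vapply(seq_len(250), function(i)
    sum(vapply(1:4, function(j) kl_quad(mu[i, j], lv[i, j]), numeric(1))), numeric(1)))
  expect_equal(kl_loss(mu, lv), oracle, tolerance = 1e-6)
})

test_that("cyclic KL annealing follows the ramp/plateau formula with periodicity", {
  an <- anneal_spec(4, 0.5)
  expect_equal(anneal_beta(0, 400, an, 1e-4), 0)
  expect_equal(anneal_beta(25, 400, an, 1e-4), 5e-5)
  expect_equal(anneal_beta(60, 400, an, 1e-4), 1e-4)

  configs <- list(list(total = 400, an = anneal_spec(4, 0.5), w = 1e-4),
                  list(total = 400, an = anneal_spec(2, 0.25), w = 1e-3),
                  list(total = 313, an = anneal_spec(5, 1), w = 0.01))
  for (cf in configs) {
    C <- ceiling(cf$total / cf$an$n_cycles)
    beta <- vapply(0:(cf$total - 1), anneal_beta, numeric(1),
                   total_epochs = cf$total, anneal = cf$an, kl_weight = cf$w)
    ref <- vapply(0:(cf$total - 1), function(e) {
      tau <- (e %% C) / C
      cf$w * min(1, tau / cf$an$ramp_fraction)
    }, numeric(1))
    expect_equal(beta, ref)
    # periodic with period C
    idx <- seq_len(cf$total - C)
    expect_equal(beta[idx], beta[idx + C])
    # non-decreasing within each ramp
    for (start in seq(1, cf$total, by = C)) {
      ramp <- beta[start:min(start + ceiling(C * cf$an$ramp_fraction) - 1, cf$total)]
      expect_true(all(diff(ramp) >= 0))
    }
  }
})

test_that("reparameterisation is a seeded Gaussian perturbation of the mean", {
  mu <- matrix(1:6 / 2, 2, 3)
  expect_equal(reparameterize(mu, matrix(-60, 2, 3), seed = 1), mu, tolerance = 1e-9)
  z1 <- reparameterize(mu, matrix(0, 2, 3), seed = 7)
  z2 <- reparameterize(mu, matrix(0, 2, 3), seed = 7)
  expect_identical(z1, z2)
  z <- reparameterize(matrix(0, 1e4, 1), matrix(log(4), 1e4, 1), seed = 3)
  expect_equal(var(drop(z)), 4, tolerance = 0.4)
})

test_that("encoder and decoder widths halve from the input dimension", {
  v <- build_mlp_vae(vae_spec(1000, 3, 3, latent_dim = 32))
  expect_equal(v$enc$widths, c(1000L, 500L, 250L, 64L))
  expect_equal(v$dec$widths, c(32L, 250L, 500L, 1000L))
  v2 <- build_mlp_vae(vae_spec(64, 2, 2, latent_dim = 8))
  expect_equal(v2$enc$widths, c(64L, 32L, 16L))
  expect_error(build_mlp_vae(vae_spec(64, 4, 4, latent_dim = 8)), "hidden width")
})

test_that("cross-modal loss measures the decode-from-A error on paired rows", {
  pr <- trained_pair()
  Xb <- pr$m$Xb_va
  Xa <- pr$m$Xa_va[rownames(Xb), ]
  # single source of truth: identical from training and evaluation surfaces
  l1 <- cross_modal_loss(Xb, Xa, pr$vae_A, pr$vae_B)
  l2 <- test_cross_modal_loss(Xb, Xa, pr$vae_A, pr$vae_B)
  expect_equal(l1, l2$loss, tolerance = 1e-12)
  expect_equal(mean(l2$per_sample), l2$loss, tolerance = 1e-12)
  # invariant under joint row permutation
  p <- sample(nrow(Xb))
  expect_equal(cross_modal_loss(Xb[p, ], Xa[p, ], pr$vae_A, pr$vae_B), l1)
  # hand value: one pair, one feature, prediction off by 0.1 -> 0.01
  enc <- survaug:::mlp_init(c(1, 1), "linear"); enc$W[[1]][] <- 0
  dec <- survaug:::mlp_init(c(1, 1), "linear"); dec$W[[1]][] <- 0; dec$b[[1]] <- 0.6
  fake <- structure(list(enc = enc, dec = dec, trained = TRUE), class = "translator_ae")
  expect_equal(cross_modal_loss(matrix(0.5), matrix(0.3), fake, fake), 0.01)
  expect_error(cross_modal_loss(matrix(1, 2, 1, dimnames = list(c("a", "b"), NULL)),
                                matrix(1, 2, 1, dimnames = list(c("a", "x"), NULL)),
                                pr$vae_A, pr$vae_B),
               "ID-paired")
})

test_that("modality-A VAE training minimises reconstruction without posterior collapse", {
  ds <- generate_paired_omics(synth_config(n_samples = 250, d_A = 40, d_B = 16,
                                           noise_sd_A = 0, noise_sd_B = 0, seed = 21))
  m <- split_mats(ds)
  spec <- vae_spec(40, latent_dim = 6, kl_weight = 1e-3, learning_rate = 1e-3,
                   epochs = 250, seed = 13)
  fit <- train_vae_a(m$Xa_tr, m$Xa_va, spec)
  expect_lt(fit$history$val_recon[fit$best_epoch], 0.01)
  expect_gt(fit$history$val_kl[fit$best_epoch], 1e-6)
  fit2 <- train_vae_a(m$Xa_tr, m$Xa_va, spec)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$enc$W, fit2$enc$W)
})

test_that("modality-B training checkpoints at minimum validation cross-modal loss", {
  pr <- trained_pair()
  expect_equal(pr$vae_B$best_epoch, which.min(pr$vae_B$history$val_cm))
  # beats an untrained model's cross-modal loss by a wide margin
  set.seed(99)
  untrained <- build_mlp_vae(pr$sp$B)
  Xb <- pr$m$Xb_va; Xa <- pr$m$Xa_va[rownames(Xb), ]
  expect_lt(cross_modal_loss(Xb, Xa, pr$vae_A, pr$vae_B),
            cross_modal_loss(Xb, Xa, pr$vae_A, untrained))
})

test_that("zero cross-modal weight removes the term from the gradient", {
  pr <- trained_pair()
  set.seed(2)
  Xb <- pr$m$Xb_tr[1:8, ]
  Za <- encode_mean(pr$vae_A, pr$m$Xa_tr[rownames(Xb), ])
  vae <- build_mlp_vae(pr$sp$B)
  set.seed(5)
  g0 <- survaug:::vae_batch_grads(vae, Xb, beta = 1e-4)
  set.seed(5)
  g1 <- survaug:::vae_batch_grads(vae, Xb, beta = 1e-4, cm_weight = 0, Z_cm = Za)
  expect_equal(g0$g_enc, g1$g_enc)
  expect_equal(g0$g_dec$W, g1$g_dec$W)
})

test_that("the frozen modality-A VAE is bit-identical after downstream training", {
  pr <- trained_pair()
  before <- pr$vae_A
  m <- pr$m
  invisible(train_vae_b(m$Xb_tr, m$Xb_va, m$Xa_tr, m$Xa_va, before,
                        tiny_vae_specs(epochs = 5)$B))
  invisible(train_adversarial(m$Xb_tr, m$Xb_va, m$Xa_tr, m$Xa_va, before,
                              tiny_vae_specs(epochs = 6)$B,
                              sched = adv_schedule(6, 2)))
  expect_identical(before$enc$W, pr$vae_A$enc$W)
  expect_identical(before$dec$W, pr$vae_A$dec$W)
})

test_that("network gradients agree with finite differences", {
  # validates the hand-derived backpropagation the whole package rests on
  set.seed(17)
  X <- matrix(runif(5 * 6), 5, 6)
  vae <- build_mlp_vae(vae_spec(6, 2, 2, latent_dim = 2, seed = 1))
  seed_grad <- 77
  loss_at <- function(vae) {
    set.seed(seed_grad)
    g <- survaug:::vae_batch_grads(vae, X, beta = 0.01)
    g$l_rec + 0.01 * g$l_kl
  }
  set.seed(seed_grad)
  g <- survaug:::vae_batch_grads(vae, X, beta = 0.01)
  h <- 1e-6
  for (probe in list(c(1, 1, 1), c(2, 3, 1))) {
    l <- probe[1]
    vp <- vae; vp$enc$W[[l]][probe[2], probe[3]] <- vp$enc$W[[l]][probe[2], probe[3]] + h
    vm <- vae; vm$enc$W[[l]][probe[2], probe[3]] <- vm$enc$W[[l]][probe[2], probe[3]] - h
    fd <- (loss_at(vp) - loss_at(vm)) / (2 * h)
    expect_equal(g$g_enc$W[[l]][probe[2], probe[3]], fd, tolerance = 1e-4)
  }
  for (probe in list(c(1, 2, 2), c(2, 1, 4))) {
    l <- probe[1]
    vp <- vae; vp$dec$W[[l]][probe[2], probe[3]] <- vp$dec$W[[l]][probe[2], probe[3]] + h
    vm <- vae; vm$dec$W[[l]][probe[2], probe[3]] <- vm$dec$W[[l]][probe[2], probe[3]] - h
    fd <- (loss_at(vp) - loss_at(vm)) / (2 * h)
    expect_equal(g$g_dec$W[[l]][probe[2], probe[3]], fd, tolerance = 1e-4)
  }
})
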