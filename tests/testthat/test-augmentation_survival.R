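test_that("discrete-time survival likelihood matches hand values", {
  expect_equal(survival_nll(matrix(0.5, 1, 30), 0.5, 1), -log(0.5))
  expect_lt(survival_nll(matrix(1 - 1e-7, 1, 30), 0.9, 0), 1e-6)
  p <- matrix(c(0.8, 0.4, rep(0.9, 28)), 1, 30)
  expect_equal(survival_nll(p, 1.5, 1), -(log(0.8) + log(0.6)))
  # censored in interval 2: survived both observed intervals
  expect_equal(survival_nll(p, 1.5, 0), -(log(0.8) + log(0.4)))
})

test_that("survival likelihood agrees with an enumeration oracle on random subjects", {
  # oracle: form each subject's discrete likelihood term by term
  oracle <- function(p, time, event, J = ncol(p)) {
    mean(vapply(seq_len(nrow(p)), function(i) {
      k <- min(ceiling(time[i]), J)
      pr <- pmin(pmax(p[i, ], 1e-7), 1 - 1e-7)
      ll <- 0
      for (j in seq_len(k - 1)) ll <- ll + log(pr[j])
      ll <- ll + if (event[i] == 1) log(1 - pr[k]) else log(pr[k])
      -ll
    }, numeric(1)))
  }
  inst <- random_surv_instance(500, seed = 44)
  expect_equal(survival_nll(inst$cond, inst$time, inst$event),
               oracle(inst$cond, inst$time, inst$event), tolerance = 1e-9)
  # events past the horizon clamp into the last interval
  expect_equal(survival_nll(inst$cond[1:3, ], c(45, 33, 31), c(1, 0, 1)),
               oracle(inst$cond[1:3, ], c(45, 33, 31), c(1, 0, 1)), tolerance = 1e-9)
})

test_that("likelihood gradient matches finite differences", {
  inst <- random_surv_instance(6, J = 5, seed = 8)
  g <- survaug:::survival_nll_grad(inst$cond, inst$time, inst$event)
  h <- 1e-6
  for (probe in list(c(1, 1), c(3, 2), c(5, 5))) {
    pp <- inst$cond; pp[probe[1], probe[2]] <- pp[probe[1], probe[2]] + h
    pm <- inst$cond; pm[probe[1], probe[2]] <- pm[probe[1], probe[2]] - h
    fd <- (survival_nll(pp, inst$time, inst$event) -
             survival_nll(pm, inst$time, inst$event)) / (2 * h)
    expect_equal(g[probe[1], probe[2]], fd, tolerance = 1e-5)
  }
})

test_that("cumulative survival is the running product and never increases", {
  inst <- random_surv_instance(50, seed = 12)
  S <- cumulative_survival(inst$cond)
  expect_equal(S[, 1], inst$cond[, 1])
  expect_equal(S[7, 4], prod(inst$cond[7, 1:4]))
  expect_true(all(S[, -1] <= S[, -ncol(S)] + 1e-15))
})

test_that("task-loss filtering is strict and order-preserving", {
  b <- structure(list(X_hat = diag(3), time = 1:3, event = c(1, 0, 1),
                      task_loss = c(0.1, 0.5, 0.9), keep = NULL),
                 class = "imputed_batch")
  expect_equal(filter_by_task_loss(b, 0.6)$keep, c(TRUE, TRUE, FALSE))
  expect_true(all(filter_by_task_loss(b, Inf)$keep))
  expect_false(any(filter_by_task_loss(b, 0)$keep))
  expect_equal(filter_by_task_loss(b, 0.5)$keep, c(TRUE, FALSE, FALSE))
})

test_that("imputation carries labels over verbatim and is deterministic", {
  pr <- trained_pair()
  ds <- pr$ds
  ids <- names(ds$split)[ds$split == "train"][1:15]
  i1 <- impute_b_from_a(ds$X_A[ids, ], pr$vae_A, pr$vae_B,
                        time = ds$time[ids], event = ds$event[ids])
  i2 <- impute_b_from_a(ds$X_A[ids, ], pr$vae_A, pr$vae_B,
                        time = ds$time[ids], event = ds$event[ids])
  expect_identical(i1$X_hat, i2$X_hat)
  expect_identical(i1$time, ds$time[ids])
  expect_identical(i1$event, ds$event[ids])
  expect_equal(ncol(i1$X_hat), ncol(ds$X_B))
  expect_error(impute_b_from_a(ds$X_A[ids, ], build_mlp_vae(pr$sp$A), pr$vae_B),
               "untrained")
})

test_that("a translator trained on identical modalities approximates the identity", {
  set.seed(61)
  z <- matrix(rnorm(300 * 3), 300, 3)
  X <- z %*% matrix(rnorm(3 * 12), 3, 12)
  X <- apply(X, 2, function(c) (c - min(c)) / (max(c) - min(c)))
  rownames(X) <- sprintf("S%03d", 1:300)
  tr <- X[1:240, ]; va <- X[241:300, ]
  spec <- vae_spec(12, 2, 2, latent_dim = 4, learning_rate = 5e-3,
                   epochs = 300, seed = 3)
  fit <- train_tdimpute(tr, tr, va, va, spec)
  imp <- impute_b_from_a(va, fit, fit)
  expect_lt(sqrt(mean((imp$X_hat - va)^2)), 0.08)
  expect_lt(fit$history$val_rmse[fit$best_epoch], 0.08)
  expect_equal(fit$best_epoch, which.min(fit$history$val_rmse))
})

test_that("deterministic translator reaches low RMSE on noiseless shared factors", {
  ds <- generate_paired_omics(synth_config(n_samples = 300, d_A = 40, d_B = 16,
                                           noise_sd_A = 0, noise_sd_B = 0, seed = 19))
  m <- split_mats(ds)
  spec <- vae_spec(40, 3, 2, latent_dim = 6, learning_rate = 2e-3,
                   epochs = 400, seed = 7)
  f1 <- train_tdimpute(m$Xa_tr, m$Xb_tr, m$Xa_va, m$Xb_va, spec)
  expect_lt(f1$history$val_rmse[f1$best_epoch], 0.02)
  f2 <- train_tdimpute(m$Xa_tr, m$Xb_tr, m$Xa_va, m$Xb_va, spec)
  expect_identical(f1$history, f2$history)
})

test_that("methods without augmentation depend only on real modality-B rows", {
  ds <- tiny_dataset(seed = 14, missing_fraction = 0.5)
  cfg <- aug_config("multisurv", epochs = 6, learning_rate = 1e-3, seed = 9)
  Xb_before <- ds$X_B
  fit <- train_predictor(ds, cfg)
  expect_identical(ds$X_B, Xb_before)       # real rows never mutated
  expect_equal(fit$n_features, ncol(ds$X_B))
  expect_equal(nrow(fit$history), 6)
})

test_that("zero oversampling weight reproduces the unaugmented trajectory", {
  pr <- trained_pair()
  ds <- pr$ds
  cfg0 <- aug_config("multisurv", epochs = 8, learning_rate = 1e-3, seed = 33)
  cfg1 <- aug_config("cmvae_ov", epochs = 8, learning_rate = 1e-3, seed = 33,
                     gamma = 0, bsOV = 16)
  f0 <- train_predictor(ds, cfg0)
  f1 <- train_predictor(ds, cfg1, encoder = pr$vae_A, decoder = pr$vae_B)
  expect_identical(f0$net$W, f1$net$W)
  expect_equal(f0$history$train_nll, f1$history$train_nll)
})

test_that("static augmentation enlarges the pool; oversampling leaves it unchanged", {
  pr <- trained_pair()
  ds <- apply_b_missingness(pr$ds, 0.5, seed = 77)
  n_real <- sum(ds$b_present[names(ds$split)[ds$split == "train"]])
  n_missing <- sum(!ds$b_present[names(ds$split)[ds$split == "train"]])
  f_td <- train_predictor(ds, aug_config("cmvae_adv", epochs = 4, seed = 2),
                          encoder = pr$vae_A, decoder = pr$vae_B)
  f_ms <- train_predictor(ds, aug_config("multisurv", epochs = 4, seed = 2))
  expect_equal(f_ms$n_train_rows, n_real)
  expect_equal(f_td$n_train_rows, n_real + n_missing)
  f_ov <- train_predictor(ds, aug_config("cmvae_ov", epochs = 4, seed = 2, bsOV = 8),
                          encoder = pr$vae_A, decoder = pr$vae_B)
  expect_false(is.null(f_ov$history$n_ov_kept))
  expect_true(any(f_ov$history$n_ov_kept > 0, na.rm = TRUE))
  expect_error(train_predictor(ds, aug_config("cmvae_ov", epochs = 2)),
               "requires trained encoder")
})

test_that("a trained predictor finds real survival signal on informative latents", {
  ds <- generate_paired_omics(synth_config(n_samples = 600, d_A = 20, d_B = 16,
                                           missing_fraction = 0.04, seed = 55))
  fit <- train_predictor(ds, aug_config("multisurv", epochs = 60,
                                        learning_rate = 1e-3, seed = 5))
  Xb <- survaug:::dataset_matrix(ds, "B", "test")
  ctd <- c_td(predict(fit, Xb), ds$time[rownames(Xb)], ds$event[rownames(Xb)])
  # null concordance is 0.5 with SE ~ 1/sqrt(comparable pairs); 3 SE above it
  n_pairs <- sum(outer(ds$time[rownames(Xb)], ds$time[rownames(Xb)], "<") &
                   ds$event[rownames(Xb)] == 1)
  expect_gt(ctd, 0.5 + 3 / (2 * sqrt(n_pairs)))
  # predictions satisfy the probability contract
  p <- predict(fit, Xb, type = "conditional")
  expect_true(all(p > 0 & p < 1))
})
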