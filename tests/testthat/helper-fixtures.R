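# small shared fixtures, built in code

tiny_dataset <- function(seed = 3, n = 300, d_A = 40, d_B = 16,
                         missing_fraction = 0.04, noise = 0.1) {
  generate_paired_omics(synth_config(
    n_samples = n, d_A = d_A, d_B = d_B, k_latent = 4,
    noise_sd_A = noise, noise_sd_B = noise,
    missing_fraction = missing_fraction, seed = seed
  ))
}

tiny_vae_specs <- function(d_A = 40, d_B = 16, epochs = 40, seed = 11) {
  list(
    A = vae_spec(d_A, latent_dim = 6, kl_weight = 1e-3, learning_rate = 1e-3,
                 epochs = epochs, seed = seed),
    B = vae_spec(d_B, n_layers_enc = 2, n_layers_dec = 2, latent_dim = 6,
                 kl_weight = 1e-4, learning_rate = 1e-3, epochs = epochs,
                 seed = seed + 1L)
  )
}

split_mats <- function(ds) {
  list(
    Xa_tr = survaug:::dataset_matrix(ds, "A", "train"),
    Xa_va = survaug:::dataset_matrix(ds, "A", "val"),
    Xb_tr = survaug:::dataset_matrix(ds, "B", "train"),
    Xb_va = survaug:::dataset_matrix(ds, "B", "val")
  )
}

# random conditional-survival matrices for likelihood/concordance tests
random_surv_instance <- function(n, J = 30, seed = 1) {
  set.seed(seed)
  list(
    cond = matrix(stats::runif(n * J, 0.05, 0.95), n, J),
    time = stats::runif(n, 0.1, J + 5),
    event = stats::rbinom(n, 1, 0.6)
  )
}

# memoised fixture: one trained translator pair on an easy dataset
trained_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- tiny_dataset(seed = 5)
      m <- split_mats(ds)
      sp <- tiny_vae_specs()
      vae_A <- train_vae_a(m$Xa_tr, m$Xa_va, sp$A)
      vae_B <- train_vae_b(m$Xb_tr, m$Xb_va, m$Xa_tr, m$Xa_va, vae_A, sp$B)
      cache <<- list(ds = ds, m = m, sp = sp, vae_A = vae_A, vae_B = vae_B)
    }
    cache
  }
})
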