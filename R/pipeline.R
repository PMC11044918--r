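#' Run the full augmentation experiment grid
#'
#' For each missing fraction: generates (or reuses) a synthetic paired-omics
#' dataset, trains the modality-A VAE, the modality-B translators required by
#' the requested methods (cross-modal VAE, adversarial variant, deterministic
#' translator), then trains one survival predictor per method and evaluates
#' test concordance (with bootstrap confidence intervals), test cross-modal
#' loss and the structural correlations. Methods are compared to a reference
#' method with a one-sided Wilcoxon signed-rank test on bootstrap replicates
#' paired by replicate index (each replicate resamples the same test subjects
#' for every method).
#'
#' @param methods character vector of method names (see [aug_config()]).
#' @param missing_fractions fractions of modality-B rows removed from
#'   train+val (defaults 0.04, 0.90, 0.95).
#' @param synth a [synth_config()] template; its `missing_fraction` and
#'   `seed` are overridden per run.
#' @param vae_a_spec,vae_b_spec [vae_spec()] templates for the two VAEs
#'   (input dims are overridden to match the data).
#' @param d_spec,sched discriminator spec and adversarial schedule, used by
#'   the adversarial methods.
#' @param aug template [aug_config()]; `method` and `seed` are overridden.
#' @param reference method name the Wilcoxon comparison is made against.
#' @param n_boot bootstrap replicates per method.
#' @param seed global seed; every stage derives its own stream from it.
#' @return list with `table` (one row per method x missing fraction:
#'   `c_td`, CI bounds, `l_cm`, `pcc_imputed`, `pcc_prior`, `wilcoxon_p`)
#'   and `details` (fitted models and datasets, keyed by missing fraction).
#' @export
run_experiment <- function(methods = c("multisurv", "cmvae_ov"),
                           missing_fractions = c(0.04, 0.90, 0.95),
                           synth = synth_config(),
                           vae_a_spec = NULL, vae_b_spec = NULL,
                           d_spec = disc_spec(), sched = adv_schedule(),
                           aug = aug_config(), reference = methods[1L],
                           n_boot = 1000, seed = 1) {
  stopifnot(all(methods %in% c("multisurv", "ov", "tdimpute", "tdimpute_ov",
                               "cmvae_adv", "cmvae_ov", "cmvae_adv_ov")),
            reference %in% methods)
  seeds <- derive_seeds(seed, 4L)
  rows <- list()
  details <- list()
  for (mf in missing_fractions) {
    cfg <- synth
    cfg$missing_fraction <- check_fraction(mf, "missing_fraction", hi = 1, hi_open = TRUE)
    cfg$seed <- seeds[1L]
    ds <- generate_paired_omics(cfg)
    stage <- train_experiment_models(ds, methods, vae_a_spec, vae_b_spec,
                                     d_spec, sched, seed = seeds[2L])
    evals <- list()
    for (m in methods) {
      acfg <- aug
      acfg$method <- m
      acfg$seed <- seeds[3L]
      trans <- translator_for_method(m, stage)
      fit <- train_predictor(ds, acfg, encoder = trans$encoder, decoder = trans$decoder)
      pe <- evaluate_predictor(fit, ds, n_boot = n_boot, seed = seeds[4L])
      te <- if (!is.null(trans$encoder))
        evaluate_translation(ds, trans$encoder, trans$decoder, seed = seeds[4L])
      else list(l_cm = NA_real_, pcc_imputed = NA_real_, pcc_prior = NA_real_)
      evals[[m]] <- list(pred = pe, trans = te, fit = fit)
    }
    for (m in methods) {
      p <- if (m == reference) NA_real_ else
        wilcoxon_one_sided(evals[[m]]$pred$replicates,
                           evals[[reference]]$pred$replicates, "greater")
      rows[[length(rows) + 1L]] <- data.frame(
        missing_fraction = mf, method = m,
        c_td = evals[[m]]$pred$c_td,
        c_td_lower = evals[[m]]$pred$lower, c_td_upper = evals[[m]]$pred$upper,
        l_cm = evals[[m]]$trans$l_cm,
        pcc_imputed = evals[[m]]$trans$pcc_imputed,
        pcc_prior = evals[[m]]$trans$pcc_prior,
        wilcoxon_p_vs_ref = p
      )
    }
    details[[sprintf("mf_%g", mf)]] <- list(dataset = ds, stage = stage, evals = evals)
  }
  list(table = do.call(rbind, rows), details = details)
}

# train the shared upstream models a method set needs
train_experiment_models <- function(ds, methods, vae_a_spec, vae_b_spec,
                                    d_spec, sched, seed) {
  Xa_tr <- dataset_matrix(ds, "A", "train"); Xa_va <- dataset_matrix(ds, "A", "val")
  Xb_tr <- dataset_matrix(ds, "B", "train"); Xb_va <- dataset_matrix(ds, "B", "val")
  need_vae <- any(methods %in% c("cmvae_ov", "cmvae_adv", "cmvae_adv_ov"))
  need_adv <- any(methods %in% c("cmvae_adv", "cmvae_adv_ov"))
  need_td <- any(methods %in% c("tdimpute", "tdimpute_ov"))
  out <- list()
  if (need_vae || need_adv) {
    sa <- vae_a_spec %||% vae_spec(ncol(Xa_tr), latent_dim = default_latent(ncol(Xa_tr)),
                                   kl_weight = 0.001, epochs = 100)
    sa$input_dim <- ncol(Xa_tr); sa$seed <- seed
    out$vae_A <- train_vae_a(Xa_tr, Xa_va, sa)
    sb <- vae_b_spec %||% vae_spec(ncol(Xb_tr), latent_dim = sa$latent_dim,
                                   kl_weight = 1e-4, epochs = 100)
    sb$input_dim <- ncol(Xb_tr); sb$latent_dim <- sa$latent_dim; sb$seed <- seed + 1L
    if (any(methods %in% c("cmvae_ov", "cmvae_adv_ov")) ||
        !need_adv)  # plain cross-modal VAE
      out$vae_B <- train_vae_b(Xb_tr, Xb_va, Xa_tr, Xa_va, out$vae_A, sb)
    if (need_adv) {
      adv <- train_adversarial(Xb_tr, Xb_va, Xa_tr, Xa_va, out$vae_A, sb,
                               d_spec = d_spec, sched = sched)
      out$vae_B_adv <- adv$vae
      out$discriminator <- adv$discriminator
    }
  }
  if (need_td) {
    st <- vae_a_spec %||% vae_spec(ncol(Xa_tr), latent_dim = default_latent(ncol(Xa_tr)),
                                   epochs = 100)
    st$input_dim <- ncol(Xa_tr); st$seed <- seed + 2L
    out$tdimpute <- train_tdimpute(Xa_tr, Xb_tr, Xa_va, Xb_va, st)
  }
  out
}

translator_for_method <- function(method, stage) {
  switch(method,
    multisurv = , ov = list(encoder = NULL, decoder = NULL),
    tdimpute = , tdimpute_ov = list(encoder = stage$tdimpute, decoder = stage$tdimpute),
    cmvae_ov = list(encoder = stage$vae_A, decoder = stage$vae_B),
    cmvae_adv = , cmvae_adv_ov = list(encoder = stage$vae_A, decoder = stage$vae_B_adv)
  )
}

default_latent <- function(d) max(4L, min(32L, as.integer(floor(d / 8))))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an evaluation report as JSON
#'
#' @param report a named list (e.g. one row of [run_experiment()]'s output
#'   or any metric list).
#' @param path output file.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
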