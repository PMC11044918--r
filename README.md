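# survaug

Cross-modal variational-autoencoder data augmentation for discrete-time
survival prediction on paired tabular omics.

## The problem

Multi-omics survival cohorts are rarely complete: one modality (say DNA
methylation, "modality A") is assayed for almost every sample, while another
(say gene expression, "modality B") is missing for many — sometimes most —
of them. A survival model trained on modality B alone must discard every
sample without it, which is exactly what hurts in low-data regimes. `survaug`
recovers those samples by *cross-modal imputation with label carry-over*:

1. Train a VAE on modality A; freeze it. Its latent space is the fixed
   target that modality B is aligned to.
2. Train a VAE on modality B with an extra **cross-modal loss**
   `L_CM = mean (X_B − Dec_B(Enc_A(X_A)))²` on ID-paired rows, optionally
   plus a least-squares-GAN discriminator on the latent codes
   (`L_Disc = mean(D(z_A)−1)² + mean(D(z_B))²`, encoder trained with labels
   swapped). A cyclic KL annealing schedule keeps the posterior from
   collapsing; the checkpoint minimises validation `L_CM`.
3. Impute missing rows as `X̂_B = Dec_B(Enc_A(X_A))` (posterior mean) and
   carry `(time, event)` over from the source sample.
4. Train a 30-interval discrete-time survival network on modality B,
   augmented per epoch with an oversampled batch of `bsOV` imputations,
   filtered by a strict task-loss threshold `t` and weighted by `γ`.
   Checkpoint maximises validation time-dependent concordance `C_td`.

Evaluation covers test `L_CM`, Pearson correlations of mean feature profiles
(real vs imputed, and real vs prior-decoded), `C_td` with percentile
bootstrap CIs, and one-sided Wilcoxon signed-rank comparisons. A synthetic
paired-omics generator (shared latent factors, log-linear exponential
hazards, right censoring, configurable modality-B missingness) makes every
stage testable without any external data.

## Worked example

```r
library(survaug)

ds <- generate_paired_omics(synth_config(
  n_samples = 1000, d_A = 200, d_B = 50, missing_fraction = 0.9, seed = 301
))
ds
#> Paired two-modality omics dataset
#>   samples: 1000 (A: 200 features, B: 50 features)
#>   modality B present: 189 / 1000
#>   split:  train=811, val=90, test=99
#>   events: 562 (56%), median follow-up 5.1 years

bm <- benchmark_seed(301, missing_fraction = 0.9, n_samples = 1000)
round(unlist(bm[c("l_cm_vae", "l_cm_untrained", "pcc_imputed_vae",
                  "pcc_prior_vae", "pcc_prior_td",
                  "ctd_multisurv", "ctd_cmvae_ov")]), 4)
#>        l_cm_vae  l_cm_untrained pcc_imputed_vae   pcc_prior_vae
#>          0.0362          0.0981          0.8154          0.6444
#>    pcc_prior_td   ctd_multisurv    ctd_cmvae_ov
#>          0.1392          0.6958          0.7080
```

Reading those numbers: with only 99 paired modality-B training rows (90% of
them were removed), the trained cross-modal VAE reconstructs held-out
modality-B profiles with a test cross-modal loss of 0.036 on [0,1]-scaled
features, about a third of an untrained decoder's 0.098; the imputed mean
feature profile correlates at 0.82 with the real one (0.999 when modality B
is near-complete); decoding pure prior noise still correlates at 0.64 for
the VAE against 0.14 for a deterministic translator (the pay-off of a
regularised latent space); and oversampled imputation lifts test concordance
over the no-augmentation baseline (0.708 vs 0.696).

The full experiment grid (methods × missing fractions, bootstrap CIs,
Wilcoxon columns) is `run_experiment()`; a thin CLI over the same functions
lives at `inst/cli/survaug.R` (`simulate | run-all | evaluate`).

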