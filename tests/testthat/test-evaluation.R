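ctd_oracle <- function(S, time, event, J = ncol(S)) {
  # exhaustive pair enumeration, independent of the vectorised implementation
  n <- length(time)
  k <- pmin(ceiling(time), J)
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      si <- S[i, k[i]]; sj <- S[j, k[i]]
      if (si < sj) num <- num + 1 else if (si == sj) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

test_that("time-dependent concordance orders hand-built survival curves", {
  S <- cumulative_survival(rbind(rep(0.3, 30), rep(0.6, 30), rep(0.9, 30)))
  expect_equal(c_td(S, c(1, 2, 3), c(1, 1, 1)), 1.0)
  expect_equal(c_td(S[3:1, ], c(1, 2, 3), c(1, 1, 1)), 0.0)
  # a censored subject only enters as the later member of a pair
  S4 <- cumulative_survival(rbind(rep(0.2, 30), rep(0.5, 30), rep(0.7, 30), rep(0.9, 30)))
  t4 <- c(0.5, 1.5, 2.5, 3.5); e4 <- c(1, 0, 1, 1)
  expect_equal(c_td(S4, t4, e4), ctd_oracle(S4, t4, e4))
  expect_error(c_td(S[1, , drop = FALSE], 1, 1), "at least")
  expect_error(c_td(S, c(1, 2, 3), c(0, 0, 0)), "no events")
})

test_that("concordance equals exhaustive enumeration on random censored instances", {
  for (s in 1:50) {
    n <- sample(5:50, 1)
    inst <- random_surv_instance(n, seed = 400 + s)
    S <- cumulative_survival(inst$cond)
    if (!any(inst$event == 1)) next
    expect_identical(c_td(S, inst$time, inst$event),
                     ctd_oracle(S, inst$time, inst$event))
  }
})

test_that("concordance reduces to Harrell's C for time-constant risk without censoring", {
  skip_if_not_installed("survival")
  for (s in 1:20) {
    set.seed(700 + s)
    n <- 30
    risk <- runif(n, 0.1, 0.9)
    time <- runif(n, 0.5, 25)
    # time-constant survival: S_i(t) = (1 - risk_i)^t, same ordering each t
    S <- t(sapply(risk, function(r) (1 - r)^(1:30)))
    ours <- c_td(S, time, rep(1, n))
    ref <- survival::concordance(survival::Surv(time, rep(1, n)) ~ risk,
                                 reverse = TRUE)$concordance
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("concordance concentrates at one half under label permutation", {
  inst <- random_surv_instance(200, seed = 90)
  S <- cumulative_survival(inst$cond)
  set.seed(17)
  vals <- replicate(100, {
    p <- sample(200)
    c_td(S[p, ], inst$time, inst$event)
  })
  expect_lt(abs(mean(vals) - 0.5), 0.05)
})

test_that("mean-feature correlation matches hand values and affine invariance", {
  X <- matrix(rep(c(1, 2, 3), each = 2), 2, 3)
  Y <- matrix(rep(c(2, 4, 7), each = 2), 2, 3)
  expect_equal(pcc_mean_features(X, X), 1.0)
  expect_equal(pcc_mean_features(X, Y), cor(c(1, 2, 3), c(2, 4, 7)))
  expect_equal(pcc_mean_features(X, Y), 0.9934, tolerance = 1e-4)
  # negated affine map of the mean profile -> -1
  expect_equal(pcc_mean_features(X, 5 - X), -1.0)
  # joint positive affine rescaling changes nothing
  expect_equal(pcc_mean_features(3 * X + 1, 3 * Y + 1), pcc_mean_features(X, Y))
  expect_error(pcc_mean_features(matrix(1, 2, 3), matrix(1, 2, 3)), "zero-variance")
})

test_that("prior-decode correlation is seeded and exact for a constant decoder", {
  pr <- trained_pair()
  Xb <- pr$m$Xb_va
  v1 <- pcc_prior_decode(Xb, pr$vae_B, seed = 4)
  v2 <- pcc_prior_decode(Xb, pr$vae_B, seed = 4)
  expect_identical(v1, v2)
  expect_true(abs(v1) <= 1)
  # decoder that always outputs the test-set mean profile -> exactly 1
  means <- colMeans(Xb)
  dec <- survaug:::mlp_init(c(4, length(means)), "linear")
  dec$W[[1]][] <- 0; dec$b[[1]] <- means
  enc <- survaug:::mlp_init(c(length(means), 4), "linear")
  const <- structure(list(enc = enc, dec = dec, trained = TRUE), class = "translator_ae")
  expect_equal(pcc_prior_decode(Xb, const, seed = 1), 1.0)
})

test_that("percentile bootstrap brackets the estimate and covers the mean", {
  const <- bootstrap_ci(function(idx) 42, n = 30, n_boot = 50, seed = 1)
  expect_equal(const$lower, 42)
  expect_equal(const$upper, 42)

  set.seed(10)
  x <- rnorm(100)
  ci <- bootstrap_ci(function(idx) mean(x[idx]), n = 100, n_boot = 400, seed = 2)
  expect_lte(ci$lower, ci$estimate)
  expect_gte(ci$upper, ci$estimate)
  expect_length(ci$replicates, 400)

  # coverage of the true mean over repeated draws, nominal 95%
  hits <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    y <- rnorm(100)
    ci <- bootstrap_ci(function(idx) mean(y[idx]), n = 100, n_boot = 200, seed = s)
    ci$lower <= 0 && 0 <= ci$upper
  }, logical(1))
  expect_gt(mean(hits), 0.88)
  expect_lt(mean(hits), 0.99)
})

test_that("one-sided signed-rank p-values are exact for small samples", {
  expect_equal(wilcoxon_one_sided(2:6, 1:5, "greater"), 1 / 32)
  expect_error(wilcoxon_one_sided(1:4, 1:4), "all paired differences are zero")

  # brute force over all 2^n sign assignments
  enum_p <- function(d, alternative) {
    d <- d[d != 0]; n <- length(d)
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    signs <- expand.grid(rep(list(c(0, 1)), n))
    Vs <- as.matrix(signs) %*% r
    if (alternative == "greater") mean(Vs >= V) else mean(Vs <= V)
  }
  set.seed(5)
  for (rep in 1:5) {
    d <- round(rnorm(12, 0.3, 1), 6)     # continuous: no ties, no zeros
    a <- rnorm(12); b <- a - d
    expect_equal(wilcoxon_one_sided(a, b, "greater"), enum_p(d, "greater"))
    expect_equal(wilcoxon_one_sided(a, b, "less"), enum_p(d, "less"))
  }
  # tied absolute differences still follow the exact sign-flip null
  for (rep in 1:5) {
    d <- sample(c(-2, -1, 1, 2, 3), 10, replace = TRUE)
    b <- sample(0:9, 10, replace = TRUE); a <- b + d
    expect_equal(wilcoxon_one_sided(a, b, "greater"), enum_p(d, "greater"))
    expect_equal(wilcoxon_one_sided(a, b, "less"), enum_p(d, "less"))
  }
})

test_that("large-sample signed-rank matches the reference implementation", {
  set.seed(6)
  a <- rnorm(60, 0.2); b <- rnorm(60)
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             alternative = "greater",
                                             exact = FALSE, correct = TRUE))
  expect_equal(wilcoxon_one_sided(a, b, "greater"), ref$p.value, tolerance = 1e-12)
  # tied data fall back to the corrected normal approximation
  at <- round(rnorm(30, 0.3), 1); bt <- round(rnorm(30), 1)
  at <- at + (at == bt) * 0.05
  reft <- suppressWarnings(stats::wilcox.test(at, bt, paired = TRUE,
                                              alternative = "greater",
                                              exact = FALSE, correct = TRUE))
  expect_equal(wilcoxon_one_sided(at, bt, "greater"), reft$p.value, tolerance = 1e-12)
})

test_that("signed-rank p never increases when every difference improves", {
  set.seed(11)
  b <- rnorm(15)
  a <- b + runif(15, -0.5, 0.5)
  p1 <- wilcoxon_one_sided(a, b, "greater")
  p2 <- wilcoxon_one_sided(a + 0.3, b, "greater")
  p3 <- wilcoxon_one_sided(a + 1.0, b, "greater")
  expect_lte(p2, p1)
  expect_lte(p3, p2)
})
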