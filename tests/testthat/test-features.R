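pair_labels <- c("0X", "0Y", "0XY", "XY", "XXY", "YXY")

test_that("the feature vector has the fixed 19-column schema", {
  f <- extract_features(add_noise(c(0, 0, 0, 3), 4, seed = 1))
  expect_equal(ncol(f), 19L)
  expect_equal(colnames(f),
               c("m_e0", "m_eX", "m_eY", "m_eXY",
                 paste0("p_", pair_labels), paste0("t_", pair_labels),
                 "delta_hat", "omnibus_p", "pooled_var"))
  expect_true(all(as.matrix(f[, paste0("p_", pair_labels)]) >= 0 &
                    as.matrix(f[, paste0("p_", pair_labels)]) <= 1))
  expect_gte(f$delta_hat, 0)
  expect_error(extract_features(matrix(0, 4, 1)), ".")
})

test_that("well-separated groups give vanishing contrast p-values", {
  reps <- add_noise(c(0, 0, 0, 10), delta_over_sigma = 100, seed = 2)
  f <- extract_features(reps)
  expect_lt(f$p_0XY, 1e-6)
  expect_lt(f$p_XXY, 1e-6)
  expect_lt(f$p_YXY, 1e-6)
  expect_lt(f$omnibus_p, 1e-6)
  expect_equal(f$delta_hat, 10, tolerance = 0.3)
})

test_that("contrast p-values are calibrated and uniform under the null", {
  set.seed(3)
  n_sim <- 10000
  Y <- matrix(stats::rnorm(n_sim * 16), n_sim)
  cond <- rep(c("CTRL", "X", "Y", "COMBO"), each = 4)
  f <- features_from_matrix(Y, cond)
  P <- as.matrix(f[, paste0("p_", pair_labels)])
  # per-contrast type-I control at nominal alpha = 0.05
  retention <- colMeans(P > 0.05)
  expect_true(all(retention >= 0.94))
  # approximate uniformity of each contrast p-value
  for (k in seq_len(6)) {
    expect_gt(stats::ks.test(P[, k], "punif")$p.value, 0.01)
  }
  # a pure-null batch mostly reports no signal
  expect_gt(mean(f$delta_hat == 0), 0.9)
})

test_that("increasing a group separation never increases its contrast p", {
  base <- add_noise(c(0, 0, 0, 0), 4, sigma = 1, seed = 4)
  base["COMBO", ] <- base["CTRL", ]  # zero separation, variance fixed
  shifts <- seq(0, 6, by = 0.5)
  p <- vapply(shifts, function(s) {
    reps <- base
    reps["COMBO", ] <- reps["COMBO", ] + s
    extract_features(reps)$p_0XY
  }, 0)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("training and application feature routes agree exactly", {
  tax <- test_taxonomy()
  ts <- build_training_set(tax, instances_per_profile = 2, seed = 5,
                           profile_ids = c(1, 2, 3, 40, 80))
  fi <- features_from_instances(ts)
  rep_cols <- grep("^(CTRL|X|Y|COMBO)_\\d+$", colnames(ts), value = TRUE)
  for (rg in unique(ts$regime)) {
    i <- ts$regime == rg
    Y <- as.matrix(ts[i, rep_cols])
    rownames(Y) <- as.character(ts$instance[i])
    fm <- features_from_matrix(Y, sub("_\\d+$", "", rep_cols),
                               moderate = sum(i) >= 100)
    expect_equal(
      as.data.frame(fi[fi$regime == rg, colnames(fm)[-1]]),
      as.data.frame(fm[, -1]),
      ignore_attr = TRUE
    )
  }
})

test_that("variance shrinkage recovers a known scaled inverse-chi-square prior", {
  set.seed(6)
  d0 <- 8; s02 <- 0.5; df <- 12
  sig2 <- s02 * d0 / stats::rchisq(5000, d0)
  s2 <- sig2 * stats::rchisq(5000, df) / df
  fit <- shrink_variances(s2, df)
  expect_equal(fit$prior_variance, s02, tolerance = 0.15 * s02)
  expect_equal(fit$prior_df, d0, tolerance = 0.15 * d0)
  expect_true(all(fit$moderated > 0))
  # shrinkage pulls extremes toward the prior
  expect_true(max(fit$moderated) < max(s2))

  # degenerate ensemble: infinite prior df, moderated = the common value
  fit2 <- shrink_variances(rep(0.25, 50), df = 12)
  expect_true(fit2$degenerate)
  expect_identical(fit2$prior_df, Inf)
  expect_equal(fit2$moderated, rep(0.25, 50))
})

test_that("ensemble moderation of a single gene shifts its statistics", {
  reps <- add_noise(c(0, 0, 0, 2), 4, seed = 7)
  plain <- extract_features(reps)
  mod <- extract_features(reps, ensemble_variances = list(
    prior_variance = plain$pooled_var * 4, prior_df = 20
  ))
  expect_gt(mod$pooled_var, plain$pooled_var)
  expect_lt(abs(mod$t_0XY), abs(plain$t_0XY))
  # infinite prior df pins the variance at the prior
  pin <- extract_features(reps, ensemble_variances = list(
    prior_variance = 0.5, prior_df = Inf
  ))
  expect_equal(pin$pooled_var, 0.5)
})

test_that("the noise-regime estimator certifies low-noise datasets", {
  tax <- test_taxonomy()
  est <- vapply(c(4, 2), function(rg) {
    ds <- generate_synthetic_dataset(
      tax, 400, c("constant" = 0.5, "additive" = 0.3,
                  "emergent synergy" = 0.2),
      delta_over_sigma = rg, seed = 600 + rg
    )
    f <- features_from_matrix(ds$expression, ds$design$condition)
    estimate_noise_regime(f[stats::p.adjust(f$omnibus_p, "BH") < 0.05, ])
  }, 0)
  expect_gt(est[1], 3.5)
  expect_lt(est[1], 5)
  expect_lt(est[2], est[1])
  expect_error(estimate_noise_regime(tibble::tibble(delta_hat = 0,
                                                    pooled_var = 1)),
               "no responding genes")
})

test_that("zero within-group variance with unequal means is flagged", {
  reps <- matrix(rep(c(0, 0, 0, 5), each = 4), nrow = 4, byrow = TRUE)
  expect_warning(f <- extract_features(reps), "zero pooled variance")
  expect_equal(f$p_0XY, 0)
})
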