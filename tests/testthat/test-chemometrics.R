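test_that("PLS1 with a single predictor is the least-squares line", {
  set.seed(1)
  x <- matrix(rnorm(30), 30, 1)
  y <- 2 - 1.5 * x[, 1] + rnorm(30, 0, 0.1)
  fit <- pls_fit(x, y, 1)
  ols <- lm(y ~ x)
  expect_equal(unname(coef(fit)[1]), unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(fitted(fit), unname(fitted(ols)), tolerance = 1e-10)
})

test_that("full-complexity PLS1 reaches the normal-equations solution", {
  set.seed(2)
  X <- matrix(rnorm(100), 20, 5)
  y <- rnorm(20)
  fit <- pls_fit(X, y, 5)
  Xc <- scale(X, scale = FALSE)
  b_ols <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  expect_lt(max(abs(fit$b - b_ols)) / max(abs(b_ols)), 1e-6)
})

test_that("scores are mutually orthogonal and b reproduces the training fit", {
  samples <- full_samples()
  Xp <- apply_pipeline(samples$spectra, samples$wavelengths,
                       preproc_config())
  fit <- pls_fit(Xp, samples$info$psi_mpa, 8)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(diag(G)))
  manual <- drop(sweep(Xp, 2, fit$x_mean) %*% fit$b) + fit$y_mean
  expect_equal(manual, fit$fitted.values, tolerance = 1e-10)
  ## predicting the training set reproduces fitted values
  expect_equal(predict(fit, Xp), fit$fitted.values, tolerance = 1e-12)
  ## the mean spectrum predicts the mean response
  expect_equal(predict(fit, matrix(fit$x_mean, 1)), fit$y_mean)
})

test_that("a constant response collapses to the null model", {
  X <- matrix(rnorm(60), 12, 5)
  expect_warning(fit <- pls_fit(X, rep(-1.2, 12), 3), "exhausted")
  expect_equal(fit$b, rep(0, 5))
  expect_equal(fit$fitted.values, rep(-1.2, 12))
})

test_that("venetian blinds interleave samples in dataset order", {
  f10 <- venetian_folds(10, 10)
  expect_equal(f10, 1:10)
  f23 <- venetian_folds(23, 10)
  expect_equal(as.integer(table(f23)[1:3]), rep(3L, 3))
  expect_equal(as.integer(table(f23)[4:10]), rep(2L, 7))
  expect_equal(f23[11], 1L)  # wraps: sample 11 joins fold 1
  expect_error(venetian_folds(9, 10), "cannot split")
  expect_error(venetian_folds(10, 1), "at least 2")
})

test_that("the first-local-minimum rule picks the smallest complexity before the error rises", {
  flm <- vinespec:::first_local_min
  expect_equal(flm(c(0.30, 0.20, 0.25, 0.10)), 2)
  expect_equal(flm(c(0.5, 0.4, 0.3, 0.2)), 4)      # monotone: a_max
  expect_equal(flm(c(0.3, 0.2, 0.2, 0.25)), 3)     # tie advances
  expect_equal(flm(c(0.1, 0.3, 0.05)), 1)
})

test_that("cross-validation recovers a low-rank noiseless structure", {
  set.seed(4)
  n <- 40; p <- 60
  wl <- seq_len(p)
  loadings <- rbind(exp(-(wl - 15)^2 / 40), exp(-(wl - 35)^2 / 60),
                    exp(-(wl - 50)^2 / 30))
  scores <- matrix(rnorm(n * 3), n, 3)
  X <- scores %*% loadings
  y <- drop(scores %*% c(0.5, -0.3, 0.2))
  cv <- cross_validate(X, y, k = 10, a_max = 8)
  expect_lte(cv$chosen_lv, 4)
  expect_lt(cv$rmsecv_by_lv[cv$chosen_lv], 0.02)
  expect_gt(cv$r2cv, 0.99)
})

test_that("cross-validation has no train/test leakage", {
  samples <- full_samples()
  y <- samples$info$psi_mpa
  set.seed(9)
  y_shuffled <- sample(y)
  cv <- cross_validate(samples$spectra, y_shuffled, k = 10, a_max = 10,
                       preproc = preproc_config(),
                       wavelengths = samples$wavelengths)
  expect_lt(cv$r2cv, 0.2)  # shuffling the response destroys the model
})

test_that("VIP scores are normalized and localize a single active band", {
  m <- full_model()
  expect_equal(mean(m$vip$scores^2), 1, tolerance = 1e-8)
  ## p = 1 forces VIP = 1
  one <- pls_fit(matrix(rnorm(20), 20, 1), rnorm(20), 1)
  expect_equal(unname(vip_scores(one)$scores), 1)
  ## single active water band at 1454 nm: importance maxima stay in-band
  s2 <- sensor2()
  one_band <- vinespec:::LEAF_BANDS[2, ]
  set.seed(12)
  psi <- runif(80, -2.2, -0.3)
  X <- t(vapply(psi, function(p)
    make_leaf_reflectance(p, s2, noise_sd = 0.002, bands = one_band)$values,
    numeric(118)))
  Xp <- apply_pipeline(X, s2$wavelengths, preproc_config())
  vip <- vip_scores(pls_fit(Xp, psi, 3, wavelengths = s2$wavelengths))
  peak_wl <- s2$wavelengths[which.max(vip$scores)]
  expect_gte(peak_wl, 1404)
  expect_lte(peak_wl, 1504)
  ## channels far from the band are uninfluential (the first and last
  ## grid channels are excluded: truncated-window derivative edge effects)
  interior <- seq(2, 117)
  far <- interior[s2$wavelengths[interior] < 1250 |
                    s2$wavelengths[interior] > 1700]
  expect_true(all(vip$scores[far] < 1))
})

test_that("the external split reserves seven in-range samples per date, reproducibly", {
  samples <- full_samples()
  sp <- external_split(samples, per_date = 7, rng_seed = 3)
  expect_equal(nrow(sp$validation$spectra), 42)  # 6 dates x 7 = ~20% of 216
  expect_equal(nrow(sp$train$spectra), 174)
  for (d in unique(samples$info$date)) {
    val_psi <- sp$validation$info$psi_mpa[sp$validation$info$date == d]
    all_psi <- samples$info$psi_mpa[samples$info$date == d]
    expect_length(val_psi, 7)
    expect_gt(min(val_psi), min(all_psi))
    expect_lt(max(val_psi), max(all_psi))
  }
  sp2 <- external_split(samples, per_date = 7, rng_seed = 3)
  expect_identical(sp$val_idx, sp2$val_idx)
  expect_false(identical(sp$val_idx,
                         external_split(samples, rng_seed = 4)$val_idx))
  tiny <- samples[1:8]
  expect_error(external_split(tiny, per_date = 7), "eligible")
})

test_that("evaluation metrics match hand-computed values", {
  m <- regression_metrics(c(-1, -1.5, -2), c(-1.1, -1.4, -2.1))
  expect_equal(m$rmse, 0.1, tolerance = 1e-12)
  perfect <- regression_metrics(1:5, 1:5)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  mean_pred <- regression_metrics(1:5, rep(3, 5))
  expect_equal(mean_pred$r2, 0)
  expect_error(regression_metrics(1, 1), "at least two")
})

test_that("the calibrated model recovers potentials of fresh leaf spectra", {
  m <- full_model()
  s2 <- sensor2()
  set.seed(21)
  psi <- runif(30, -2.0, -0.4)
  X <- t(vapply(psi, function(p)
    make_leaf_reflectance(p, s2, noise_sd = 0.002)$values, numeric(118)))
  pred <- predict(m, X, wavelengths = s2$wavelengths)
  expect_lt(mean(abs(pred - psi)), 0.1)
  expect_error(predict(m, X[, 1:50], wavelengths = s2$wavelengths[1:50]),
               "grid mismatch")
})
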