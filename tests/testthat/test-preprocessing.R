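test_that("SNV centers and scales each spectrum with the sample sd", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  x <- runif(50)
  expect_equal(mean(snv(x)), 0, tolerance = 1e-12)
  expect_equal(sd(snv(x)), 1, tolerance = 1e-12)
  ## idempotence and affine invariance
  expect_equal(snv(snv(x)), snv(x))
  expect_equal(snv(2.5 * x + 0.3), snv(x))
  expect_error(snv(rep(1, 10)), "zero-variance")
})

test_that("SNV on a matrix matches row-wise application", {
  X <- matrix(runif(60), 6, 10)
  expect_equal(snv(X), t(apply(X, 1, snv)))
})

test_that("Savitzky-Golay derivative is exact for polynomials and scaled per nm", {
  wl <- seq(900, 1860, by = 8.2)
  ## linear ramp: derivative is the slope everywhere (edges included,
  ## since a line is fit exactly on any truncated window)
  ramp <- 0.004 * wl
  d <- savgol_derivative(ramp, wl, window = 7, polyorder = 2, deriv = 1)
  expect_equal(d, rep(0.004, length(wl)), tolerance = 1e-10)
  ## constant: zero derivative
  expect_equal(savgol_derivative(rep(2, length(wl)), wl, window = 7),
               rep(0, length(wl)), tolerance = 1e-10)
  ## quadratic with polyorder 2: interior derivative analytic
  q <- 1e-5 * (wl - 1300)^2
  dq <- savgol_derivative(q, wl, window = 7, polyorder = 2, deriv = 1)
  interior <- 4:(length(wl) - 3)
  expect_equal(dq[interior], (2e-5 * (wl - 1300))[interior],
               tolerance = 1e-8)
})

test_that("Savitzky-Golay with deriv 0 and saturated polyorder reproduces the input", {
  wl <- seq(1100, 2100, by = 2)
  x <- sin(wl / 90) + rnorm(length(wl), 0, 0.1)
  out <- savgol_derivative(x, wl, window = 5, polyorder = 4, deriv = 0)
  expect_equal(out, x, tolerance = 1e-8)
})

test_that("interior channels agree with an independent Savitzky-Golay implementation", {
  skip_if_not_installed("signal")
  wl <- seq(900, 1860, by = 8.2)
  set.seed(3)
  x <- make_leaf_reflectance(-1.3, sensor2())$values
  ours <- savgol_derivative(x, wl, window = 7, polyorder = 2, deriv = 1)
  ## signal::sgolayfilt returns the unscaled per-channel derivative
  theirs <- signal::sgolayfilt(x, p = 2, n = 7, m = 1) / 8.2
  interior <- 4:(length(wl) - 3)
  expect_equal(ours[interior], theirs[interior], tolerance = 1e-8)
})

test_that("configuration is validated and serializes round-trip", {
  expect_error(preproc_config(window = 6), "odd")
  expect_error(preproc_config(window = 7, polyorder = 2, deriv = 3),
               "deriv")
  expect_error(preproc_config(steps = "msc"), "snv")
  cfg <- preproc_config(steps = c("savgol", "snv"), window = 9,
                        polyorder = 3, deriv = 2)
  json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null")
  back <- jsonlite::fromJSON(json)
  cfg2 <- preproc_config(steps = back$steps, window = back$savgol$window,
                         polyorder = back$savgol$polyorder,
                         deriv = back$savgol$deriv)
  expect_equal(cfg, cfg2)
})

test_that("the pipeline applies steps in order and an empty recipe is the identity", {
  wl <- sensor2()$wavelengths
  X <- rbind(make_leaf_reflectance(-1, sensor2(), rng_seed = 1)$values,
             make_leaf_reflectance(-2, sensor2(), rng_seed = 2)$values)
  expect_equal(apply_pipeline(X, wl, preproc_config(steps = character(0))), X)
  manual <- savgol_derivative(snv(X), wl, window = 7, polyorder = 2,
                              deriv = 1)
  expect_equal(apply_pipeline(X, wl, preproc_config(window = 7)), manual)
  reversed <- snv(savgol_derivative(X, wl, window = 7, polyorder = 2,
                                    deriv = 1))
  expect_equal(apply_pipeline(X, wl,
                              preproc_config(steps = c("savgol", "snv"),
                                             window = 7)), reversed)
})

test_that("default preprocessing removes scatter variance between replicates", {
  s2 <- sensor2()
  set.seed(8)
  reps <- t(vapply(1:20, function(i)
    make_leaf_reflectance(-1.2, s2, noise_sd = 0.001)$values, numeric(118)))
  pp <- apply_pipeline(reps, s2$wavelengths, preproc_config())
  ## scatter is replicate-to-replicate variance; SNV rescales, so compare
  ## it relative to the spectral signal (variance of the mean profile)
  rel_noise <- function(X) mean(apply(X, 2, var)) / var(colMeans(X))
  expect_lt(rel_noise(pp), rel_noise(reps))
})
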