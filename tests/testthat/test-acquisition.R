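make_refs <- function(n = 10) {
  wl <- seq(900, 900 + 8.2 * (n - 1), by = 8.2)
  list(wl = wl,
       dark = spectrum(wl, rep(100, n), "dark"),
       white = spectrum(wl, rep(1100, n), "white"))
}

test_that("two-point calibration satisfies its identities", {
  r <- make_refs()
  expect_equal(compute_reflectance(
    spectrum(r$wl, r$white$values, "raw"), r$dark, r$white)$values,
    rep(1, 10))
  expect_equal(compute_reflectance(
    spectrum(r$wl, r$dark$values, "raw"), r$dark, r$white)$values,
    rep(0, 10))
  mid <- spectrum(r$wl, (r$dark$values + r$white$values) / 2, "raw")
  expect_equal(compute_reflectance(mid, r$dark, r$white)$values,
               rep(0.5, 10))
})

test_that("calibration errors name degenerate channels and grid mismatches", {
  r <- make_refs()
  bad_white <- spectrum(r$wl, c(100, r$white$values[-1]), "white")
  expect_error(compute_reflectance(spectrum(r$wl, rep(500, 10), "raw"),
                                   r$dark, bad_white),
               "coincide at 1 channel")
  other <- spectrum(r$wl + 1, rep(500, 10), "raw")
  expect_error(compute_reflectance(other, r$dark, r$white),
               "wavelength grid")
})

test_that("top-5 sanity statistic is the mean of the five largest values", {
  expect_equal(top5_mean(c(1, 2, 3, 4, 5, 6)), 4)
  expect_equal(top5_mean(rep(3.5, 8)), 3.5)
  expect_equal(top5_mean(c(5, 5, 5, 5, 5, 1)), 5)
  expect_error(top5_mean(1:4), "at least 5")
})

test_that("the acquisition state machine enforces dark -> white -> signature -> measure", {
  r <- make_refs()
  s <- acquisition_session()
  expect_error(acq_white(s, r$white), "dark reference not captured")
  expect_error(acq_measure(s, matrix(1, 1, 10), 0), "dark reference")
  s <- acq_dark(s, r$dark)
  expect_error(acq_signature(s, r$white), "white reference not captured")
  s <- acq_white(s, r$white)
  expect_error(acq_measure(s, matrix(1, 1, 10), 0),
               "signature reference not captured")
})

test_that("a session accepts signature-like frames and rejects interference", {
  s2 <- sensor2()
  sig <- make_leaf_reflectance(-1.1, s2, noise_sd = 0, scatter = FALSE)
  dark <- spectrum(s2$wavelengths, rep(120, 118), "dark")
  white <- spectrum(s2$wavelengths, rep(4000, 118), "white")
  to_counts <- function(v) 120 + v * (4000 - 120)
  counts <- rbind(to_counts(sig$values), to_counts(sig$values),
                  to_counts(sig$values))
  ses <- run_session(counts, c(0, 0.08, 0.16), dark, white, sig)
  expect_equal(nrow(ses$accepted), 3)
  expect_equal(ses$rejected_count, 0)
  ## pure interference stream: nothing passes at the default threshold
  intf <- t(vapply(1:6, function(i)
    to_counts(make_interference("sky_gap", s2, rng_seed = i)$values),
    numeric(118)))
  ses2 <- run_session(intf, (0:5) * 0.08, dark, white, sig)
  expect_equal(nrow(ses2$accepted), 0)
  expect_equal(ses2$rejected_count, 6)
})

test_that("accepted and rejected frames partition the stream", {
  camp <- small_campaign()
  pass <- camp$passes[[1]]
  ses <- run_session(pass$spectra, pass$frames$timestamp, pass$dark,
                     pass$white, pass$signature, gps = pass$gps)
  expect_equal(nrow(ses$accepted) + ses$rejected_count, nrow(pass$spectra))
  ## the cosine filter recovers exactly the generator's leaf frames
  expect_equal(nrow(ses$accepted), sum(pass$frames$is_leaf))
})

test_that("GPS pairing respects the time tolerance and flags unlocated frames", {
  r <- make_refs()
  s <- acquisition_session(threshold = 1e-6)
  s <- acq_dark(s, r$dark)
  s <- acq_white(s, r$white)
  s <- acq_signature(s, spectrum(r$wl, rep(0.5, 10), "reflectance"))
  counts <- matrix(600, 3, 10)
  gps <- data.frame(timestamp = c(0.02, 0.1), lon = c(1, 2), lat = c(3, 4))
  s <- acq_measure(s, counts, c(0, 0.11, 5), gps)
  expect_equal(s$accepted_meta$located, c(TRUE, TRUE, FALSE))
  expect_equal(s$accepted_meta$lon, c(1, 2, NA))
  ## nearest fix wins
  expect_equal(s$accepted_meta$lat[2], 4)
})

test_that("session replay writes the per-step files", {
  camp <- small_campaign()
  pass <- camp$passes[[1]]
  dir <- tempfile()
  run_session(pass$spectra[1:50, ], pass$frames$timestamp[1:50],
              pass$dark, pass$white, pass$signature, gps = pass$gps,
              out_dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("dark.txt", "white.txt", "signature.txt", "session_log.txt")))))
  expect_length(list.files(dir, pattern = "^accepted_"), 1)
  log <- readLines(file.path(dir, "session_log.txt"))
  expect_true(any(grepl("^threshold=0.985$", log)))
  expect_true(any(grepl("^n_frames=50$", log)))
})
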