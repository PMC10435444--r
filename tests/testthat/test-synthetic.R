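test_that("sensor grids follow range and resolution", {
  s1 <- sensor1()
  expect_equal(s1$n_channels, 501L)
  expect_equal(range(s1$wavelengths), c(1100, 2100))
  s2 <- sensor2()
  expect_equal(s2$n_channels, 118L)  # floor((1860-900)/8.2) + 1
  expect_equal(s2$wavelengths[1], 900)
  expect_lte(max(s2$wavelengths), 1860)
})

test_that("leaf water band deepens monotonically with water content", {
  s2 <- sensor2()
  i1454 <- which.min(abs(s2$wavelengths - 1454))
  psi_grid <- seq(-2.2, -0.3, by = 0.1)
  depth <- vapply(psi_grid, function(p) {
    sp <- make_leaf_reflectance(p, s2, noise_sd = 0, scatter = FALSE)
    sp$values[i1454]
  }, 0)
  ## wetter leaf (less negative psi) absorbs more at 1454 nm
  expect_true(all(diff(depth) < 0))
  wet <- make_leaf_reflectance(-0.5, s2, noise_sd = 0, scatter = FALSE)
  dry <- make_leaf_reflectance(-2.0, s2, noise_sd = 0, scatter = FALSE)
  expect_lt(wet$values[i1454], dry$values[i1454])
})

test_that("leaf spectra are deterministic under a seed, valid reflectance, and respect psi domain", {
  s2 <- sensor2()
  a <- make_leaf_reflectance(-1.2, s2, rng_seed = 7)
  b <- make_leaf_reflectance(-1.2, s2, rng_seed = 7)
  expect_identical(a$values, b$values)
  expect_error(make_leaf_reflectance(0.1, s2), "outside valid range")
  expect_error(make_leaf_reflectance(-3, s2), "outside valid range")
  clean <- make_leaf_reflectance(-1.13, sensor1(), noise_sd = 0,
                                 scatter = FALSE)
  expect_length(clean$values, 501)
  expect_true(all(clean$values > 0 & clean$values <= 1))
})

test_that("bands outside the sensor range are skipped and recorded", {
  sp2 <- make_leaf_reflectance(-1, sensor2(), noise_sd = 0, scatter = FALSE)
  expect_true(all(c(1935, 2100) %in% sp2$meta$skipped_bands))
  sp1 <- make_leaf_reflectance(-1, sensor1(), noise_sd = 0, scatter = FALSE)
  expect_equal(sp1$meta$skipped_bands, 978)  # below 1100 nm
})

test_that("interference classes are certified dissimilar to leaf spectra", {
  s2 <- sensor2()
  leaf <- make_leaf_reflectance(-1.0, s2, noise_sd = 0, scatter = FALSE)
  for (k in c("sky_gap", "wood", "wire", "pipe", "berry")) {
    intf <- make_interference(k, s2, rng_seed = 3)
    expect_lt(cosine_similarity(intf, leaf), 0.985)
  }
  ## sky gap is the bright class and carries no 1454 nm leaf dip
  sky <- make_interference("sky_gap", s2, rng_seed = 3)
  expect_gt(mean(sky$values), mean(leaf$values))
  i1454 <- which.min(abs(s2$wavelengths - 1454))
  near <- abs(s2$wavelengths - 1454) < 20
  expect_gt(min(sky$values[!near]) - 0, 0)
  expect_error(make_interference("fence", s2), "arg")
})

test_that("leaf and interference cosine ranges straddle the 0.985 threshold", {
  s2 <- sensor2()
  sig <- make_leaf_reflectance(-1.1, s2, noise_sd = 0.002, scatter = FALSE)
  set.seed(5)
  leaf_sims <- replicate(60, cosine_similarity(
    make_leaf_reflectance(runif(1, -2.2, -0.3), s2), sig))
  intf_sims <- unlist(lapply(c("sky_gap", "wood", "wire", "pipe", "berry"),
    function(k) replicate(12, cosine_similarity(
      make_interference(k, s2), sig))))
  expect_gt(min(leaf_sims), 0.985)
  expect_lt(max(intf_sims), 0.985)
})

test_that("a pass matches the trial geometry and stays georeferenced in-block", {
  camp <- small_campaign()
  pass <- camp$passes[[1]]
  expect_equal(nrow(pass$references), 3 * 3)  # 3 blocks x 3 vine groups
  expect_true(all(pass$references$psi_mpa <= 0))
  ## every frame's GPS position lies inside its block polygon
  layout <- camp$layout
  for (blk in layout$blocks) {
    sel <- pass$frames$block_id == blk$block_id
    expect_true(all(point_in_polygon_wrapper(
      pass$frames$lon[sel], pass$frames$lat[sel], blk$polygon)))
  }
  ## frame count per block follows row length / speed / rate
  speed_ms <- 3 / 3.6
  expected <- floor((layout$row_length - 1) / speed_ms * sensor2()$rate_hz)
  expect_equal(sum(pass$frames$block_id == "B01"), expected)
})

test_that("campaigns hit the reference-count design and are reproducible", {
  camp <- full_campaign()
  expect_equal(nrow(camp$references), 216)  # 6 dates x 12 blocks x 3 refs
  expect_equal(sum(camp$references$date == camp$model$dates[1]), 36)
  nine <- simulate_pass(field_layout(n_blocks = 9), water_status_model(),
                        scene_mix(), sensor2(),
                        water_status_model()$dates[1], rng_seed = 2)
  expect_equal(nrow(nine$references), 27)
  ## unirrigated vines end the season drier than they start it
  refs <- camp$references
  t2 <- refs[refs$treatment == "T2", ]
  first <- mean(t2$psi_mpa[t2$date == camp$model$dates[1]])
  last <- mean(t2$psi_mpa[t2$date == camp$model$dates[6]])
  expect_lt(last, first)
  ## clamp coverage, no positive potentials
  expect_true(all(refs$psi_mpa >= -2.2 & refs$psi_mpa <= -0.05))
  ## identical seed reproduces the campaign bit for bit
  camp2 <- simulate_campaign(field_layout(), water_status_model(),
                             scene_mix(), sensor2(), rng_seed = 42L)
  expect_identical(camp$references, camp2$references)
  expect_identical(camp$passes[[3]]$spectra, camp2$passes[[3]]$spectra)
})

test_that("stream files round-trip with their metadata header", {
  camp <- small_campaign()
  path <- tempfile(fileext = ".txt")
  write_stream(camp$passes[[2]], path)
  hdr <- readLines(path, n = 3)
  expect_match(hdr[1], "^# sensor=")
  expect_match(hdr[2], "^# date=d2")
  back <- read_stream(path)
  expect_equal(back$wavelengths, sensor2()$wavelengths)
  expect_equal(back$spectra, unname(camp$passes[[2]]$spectra),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$date, "d2")
})

test_that("campaign directories carry manifest, streams and references", {
  dir <- tempfile()
  camp <- simulate_campaign(field_layout(n_blocks = 3),
                            water_status_model(dates = c("d1", "d2")),
                            scene_mix(), sensor2(), rng_seed = 9,
                            out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  expect_true(file.exists(file.path(dir, "references.csv")))
  expect_length(list.files(dir, pattern = "^stream_"), 2)
  man <- readLines(file.path(dir, "manifest.txt"))
  expect_true(any(grepl("^rng_seed=9$", man)))
  expect_true(any(grepl("^p_leaf=", man)))
})

test_that("degenerate generator inputs error clearly", {
  expect_error(water_status_model(dates = "one"), "two")
  expect_error(simulate_pass(field_layout(), water_status_model(),
                             scene_mix(), sensor2(), "1999-01-01"),
               "not part of the water-status model")
  expect_error(simulate_pass(field_layout(), water_status_model(),
                             scene_mix(), sensor2(),
                             water_status_model()$dates[1],
                             speed_kmh = 0), "speed")
  expect_error(scene_mix(p_leaf = 1.4), "p_leaf")
})
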