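## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

## Full-size campaign under the study conditions: 6 dates x 12 blocks x
## 3 marked vines on the sensor #2 grid (n = 216 reference samples).
full_campaign <- function() {
  if (is.null(.fixtures$camp)) {
    .fixtures$camp <- simulate_campaign(field_layout(), water_status_model(),
                                        scene_mix(), sensor2(),
                                        rng_seed = 42L)
  }
  .fixtures$camp
}

full_samples <- function() {
  if (is.null(.fixtures$samples)) {
    .fixtures$samples <- build_samples(full_campaign())
  }
  .fixtures$samples
}

full_model <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- psi_model(full_samples())
  }
  .fixtures$model
}

## Small campaign for structural tests: 3 blocks, 3 dates.
small_campaign <- function(seed = 7L) {
  simulate_campaign(field_layout(n_blocks = 3),
                    water_status_model(dates = c("d1", "d2", "d3")),
                    scene_mix(), sensor2(), rng_seed = seed)
}

point_in_polygon_wrapper <- function(px, py, poly) {
  vinespec:::point_in_polygon(px, py, poly)
}

## Independent cosine oracle, written apart from the package's code path.
cosine_oracle <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

## Mixed leaf/interference frame set with known labels.
mixed_frames <- function(n, sensor = sensor2(), p_leaf = 0.7, seed = 11L) {
  set.seed(seed)
  is_leaf <- runif(n) < p_leaf
  mat <- matrix(NA_real_, n, sensor$n_channels)
  for (i in seq_len(n)) {
    mat[i, ] <- if (is_leaf[i]) {
      make_leaf_reflectance(runif(1, -2.2, -0.3), sensor)$values
    } else {
      make_interference(sample(c("sky_gap", "wood", "wire", "pipe", "berry"),
                               1), sensor)$values
    }
  }
  list(spectra = mat, is_leaf = is_leaf)
}
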