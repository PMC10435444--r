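## Synthetic on-the-go NIR campaign generator.
##
## Leaf optics are a Beer-Lambert-style stack of Gaussian absorption bands on
## a smooth baseline: water bands at 978, 1454 and 1935 nm whose strength
## grows with leaf water content, plus fixed dry-matter bands at 1720 and
## 2100 nm. Leaf water content W is linked linearly to stem water potential.
## This is deliberately not a radiative-transfer model: the pipeline only
## needs a monotone, band-localized water signal plus the multiplicative /
## additive scatter artifacts that SNV and derivative preprocessing remove.

## Water absorption dominates the fresh-leaf NIR; dry-matter bands are an
## order of magnitude weaker.
LEAF_BANDS <- data.frame(
  center = c(978, 1454, 1935, 1720, 2100),
  sigma  = c(30, 25, 70, 45, 60),
  amp    = c(0.30, 0.90, 1.60, 0.10, 0.08),
  water  = c(TRUE, TRUE, TRUE, FALSE, FALSE)
)

leaf_baseline <- function(wl) 0.58 - 8e-5 * (wl - 900)

#' Water-status model for a simulated irrigation trial
#'
#' Defines, per measurement date and irrigation treatment, the distribution
#' of stem water potential (MPa, negative; more negative = more stressed),
#' together with the clamp range and the linear link from potential to leaf
#' water content used by the optical model.
#'
#' Defaults reproduce a rain-fed Tempranillo plot drying down over six dates
#' (date means -1.13 to -1.82 MPa, per-date SD 0.15 MPa), with irrigation
#' treatments offset around the date mean: T0 fully irrigated (wetter),
#' T1 deficit, T2 unirrigated (drier).
#'
#' @param dates character vector of measurement dates (ISO strings). At
#'   least two.
#' @param date_means mean potential per date, MPa. Defaults to the six-date
#'   dry-down above; for other date counts a linear trend over the same
#'   range is used.
#' @param treatment_offsets named numeric, MPa added to the date mean per
#'   treatment.
#' @param sd within-(date, treatment) standard deviation, MPa.
#' @param psi_floor,psi_ceil clamp range for generated potentials, MPa.
#' @param water_link numeric `c(w0, w1)`: leaf water content
#'   `W = w0 + w1 * psi`, with `w1 > 0` so wetter vines (less negative psi)
#'   have higher W.
#' @return A `"water_status_model"` object.
#' @export
water_status_model <- function(dates = paste0("2021-", c("07-07", "07-20",
                                 "07-27", "08-11", "08-25", "09-15")),
                               date_means = NULL,
                               treatment_offsets = c(T0 = 0.15, T1 = 0,
                                                     T2 = -0.15),
                               sd = 0.15,
                               psi_floor = -2.2, psi_ceil = -0.05,
                               water_link = c(w0 = 0.85, w1 = 0.25)) {
  if (length(dates) < 2L) stop("need at least two measurement dates")
  if (is.null(date_means)) {
    date_means <- if (length(dates) == 6L) {
      c(-1.13, -1.23, -1.26, -1.51, -1.68, -1.82)
    } else {
      seq(-1.13, -1.82, length.out = length(dates))
    }
  }
  if (length(date_means) != length(dates)) {
    stop("date_means must match dates in length")
  }
  if (psi_ceil > 0 || psi_floor >= psi_ceil) {
    stop("clamp range must satisfy psi_floor < psi_ceil <= 0")
  }
  if (water_link[2] <= 0) stop("water_link slope w1 must be positive")
  structure(list(dates = as.character(dates),
                 date_means = stats::setNames(date_means, dates),
                 treatment_offsets = treatment_offsets,
                 sd = sd, psi_floor = psi_floor, psi_ceil = psi_ceil,
                 water_link = water_link),
            class = "water_status_model")
}

psi_mean <- function(model, date, treatment) {
  if (!date %in% model$dates) {
    stop(sprintf("date %s is not part of the water-status model", date))
  }
  unname(model$date_means[date] + model$treatment_offsets[treatment])
}

clamp_psi <- function(psi, model) {
  pmin(pmax(psi, model$psi_floor), model$psi_ceil)
}

leaf_water_content <- function(psi, water_link = c(0.85, 0.25)) {
  unname(water_link[1] + water_link[2] * psi)
}

#' Simulate a leaf reflectance spectrum
#'
#' Reflectance is `baseline(wl) * exp(-sum_k A_k * G(wl; mu_k, sigma_k))`
#' with Gaussian water bands at 978, 1454 and 1935 nm whose amplitude grows
#' linearly with leaf water content, and fixed dry-matter bands at 1720 and
#' 2100 nm. Band centers outside the sensor range are skipped (recorded in
#' `meta$skipped_bands`). Multiplicative/additive scatter
#' (`a*R + b`, `a ~ U[0.9, 1.1]`, `b ~ U[-0.02, 0.02]`) is applied after
#' absorption and i.i.d. Gaussian channel noise last.
#'
#' @param psi stem water potential, MPa; must lie in `[psi_floor, 0]`.
#' @param sensor a [sensor_spec()].
#' @param noise_sd channel noise standard deviation (reflectance units).
#' @param rng_seed optional integer; identical seeds give bit-identical
#'   spectra. `NULL` draws from the ambient RNG stream.
#' @param scatter if `FALSE`, scatter is fixed at `a = 1, b = 0` (useful
#'   for noiseless references and monotonicity checks).
#' @param water_link linear psi-to-water-content link, see
#'   [water_status_model()].
#' @param psi_floor lower bound of valid psi, MPa.
#' @param bands absorption band table (`center`, `sigma`, `amp`, `water`);
#'   override to generate spectra with a reduced or shifted band set.
#' @return A reflectance [spectrum()].
#' @examples
#' wet <- make_leaf_reflectance(-0.5, sensor2(), noise_sd = 0, scatter = FALSE)
#' dry <- make_leaf_reflectance(-2.0, sensor2(), noise_sd = 0, scatter = FALSE)
#' i1454 <- which.min(abs(wet$wavelengths - 1454))
#' wet$values[i1454] < dry$values[i1454]  # wetter leaf absorbs more
#' @export
make_leaf_reflectance <- function(psi, sensor, noise_sd = 0.005,
                                  rng_seed = NULL, scatter = TRUE,
                                  water_link = c(w0 = 0.85, w1 = 0.25),
                                  psi_floor = -2.2, bands = LEAF_BANDS) {
  if (psi > 0 || psi < psi_floor) {
    stop(sprintf("psi = %.3f MPa outside valid range [%.2f, 0]",
                 psi, psi_floor))
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  wl <- sensor$wavelengths
  W <- leaf_water_content(psi, water_link)
  keep <- bands$center >= sensor$wl_min & bands$center <= sensor$wl_max
  skipped <- bands$center[!keep]
  absorb <- rep(0, length(wl))
  for (k in which(keep)) {
    A <- if (bands$water[k]) bands$amp[k] * W else bands$amp[k]
    absorb <- absorb +
      A * exp(-(wl - bands$center[k])^2 / (2 * bands$sigma[k]^2))
  }
  r <- leaf_baseline(wl) * exp(-absorb)
  r <- with_seed(rng_seed, {
    if (scatter) {
      a <- stats::runif(1, 0.9, 1.1)
      b <- stats::runif(1, -0.02, 0.02)
      r <- a * r + b
    }
    if (noise_sd > 0) r <- r + stats::rnorm(length(r), 0, noise_sd)
    r
  })
  spectrum(wl, r, kind = "reflectance",
           meta = list(sensor = sensor$name, psi = psi, W = W,
                       skipped_bands = skipped))
}

## Stylized non-leaf templates. Shapes are chosen so that none shares the
## leaf's joint 978/1454 nm water-dip structure; each is validated against
## the cosine threshold at generation time rather than trusted a priori.
INTERFERENCE_CLASSES <- c("sky_gap", "wood", "wire", "pipe", "berry")

interference_template <- function(kind, wl) {
  t <- (wl - 900) / 1200
  g <- function(ctr, sig) exp(-(wl - ctr)^2 / (2 * sig^2))
  switch(kind,
    ## open path: bright, but carved by atmospheric water vapour bands
    sky_gap = 0.95 - 0.55 * g(1380, 30) - 0.50 * g(1870, 45) -
      0.30 * g(1130, 28) - 0.25 * g(940, 25),
    ## dry bark: strong red-edge-less upslope, broad lignin/cellulose dip
    wood    = 0.30 + 0.40 * t - 0.20 * g(1720, 55),
    ## galvanized wire: weak specular return peaking short, little beyond
    wire    = 0.12 + 0.30 * g(1050, 170),
    ## polyethylene pipe: sharp C-H first-overtone and combination bands
    pipe    = 0.62 - 0.40 * g(1730, 40) - 0.36 * g(1215, 32) -
      0.25 * g(1395, 25),
    berry   = 0.22 + 0.38 * t - 0.10 * g(1935, 80),
    stop(sprintf("unknown interference class '%s'", kind))
  )
}

## Leaf spectra spanning the default psi range, used to certify that a
## generated interference frame would be rejected by the cosine filter.
reference_leaves <- function(sensor) {
  lapply(c(-2.0, -1.2, -0.5), function(p) {
    make_leaf_reflectance(p, sensor, noise_sd = 0, scatter = FALSE)$values
  })
}

#' Simulate a non-leaf interference spectrum
#'
#' Generates a stylized spectrum for material the sensor sees between
#' canopy gaps: sky, wood, trellis wire, irrigation pipe, grape berries.
#' Every generated frame is verified to have cosine similarity below
#' `threshold` against default-parameter leaf spectra spanning the psi
#' range; if random jitter pushes it above, it is regenerated (up to five
#' attempts) before erroring.
#'
#' @param kind one of `"sky_gap"`, `"wood"`, `"wire"`, `"pipe"`, `"berry"`.
#' @param sensor a [sensor_spec()].
#' @param rng_seed optional integer seed.
#' @param threshold dissimilarity certification threshold (the filter
#'   default, 0.985).
#' @return A reflectance [spectrum()].
#' @export
make_interference <- function(kind, sensor, rng_seed = NULL,
                              threshold = 0.985) {
  kind <- match.arg(kind, INTERFERENCE_CLASSES)
  wl <- sensor$wavelengths
  base <- interference_template(kind, wl)
  leaves <- reference_leaves(sensor)
  with_seed(rng_seed, {
    for (attempt in 1:5) {
      jitter_scale <- stats::runif(1, 0.9, 1.1)
      jitter_tilt <- stats::runif(1, -0.03, 0.03) * (wl - 900) / 1200
      r <- pmax(base * jitter_scale + jitter_tilt +
                  stats::rnorm(length(wl), 0, 0.004), 1e-4)
      sims <- vapply(leaves, function(lv) cosine_similarity(r, lv), 0)
      if (all(sims < threshold)) {
        return(spectrum(wl, r, kind = "reflectance",
                        meta = list(sensor = sensor$name, class = kind)))
      }
    }
    stop(sprintf(
      "could not generate '%s' interference dissimilar to leaf (cosine >= %g after 5 attempts)",
      kind, threshold))
  })
}

#' Scene composition of an on-the-go pass
#'
#' @param p_leaf probability that a stream frame views leaf canopy.
#' @param weights named non-negative weights over interference classes;
#'   normalized internally.
#' @return A `"scene_mix"` object; `p_leaf` plus the normalized class
#'   probabilities sum to 1.
#' @export
scene_mix <- function(p_leaf = 0.7,
                      weights = stats::setNames(rep(1, 5),
                                                INTERFERENCE_CLASSES)) {
  if (p_leaf < 0 || p_leaf > 1) stop("p_leaf must be in [0, 1]")
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("interference weights must be non-negative and not all zero")
  }
  weights <- weights / sum(weights)
  structure(list(p_leaf = p_leaf, weights = weights), class = "scene_mix")
}

#' Lay out a blocked irrigation trial
#'
#' Rectangular replication blocks arranged in a grid, one traversed row
#' segment per block, with irrigation treatments T0/T1/T2 cycled across
#' blocks so every treatment is replicated. Coordinates are lon/lat about
#' `origin`; internal geometry is metric.
#'
#' @param n_blocks number of replication blocks (default 12, the larger of
#'   the two trial plots; 9 gives the smaller one).
#' @param vines_per_block vines along the traversed row (15: three 5-vine
#'   groups, one marked vine per group).
#' @param vine_spacing,row_spacing planting geometry, m.
#' @param rows_per_block block width in rows.
#' @param origin lon/lat of the plot's southwest corner.
#' @return A `"field_layout"` object: `$blocks` is a list with `block_id`,
#'   `treatment`, `polygon` (lon/lat ring), `centerline` (row traversal
#'   endpoints, lon/lat).
#' @export
field_layout <- function(n_blocks = 12, vines_per_block = 15,
                         vine_spacing = 1.2, row_spacing = 2.6,
                         rows_per_block = 3,
                         origin = c(lon = -2.1206, lat = 42.3051)) {
  if (n_blocks < 1) stop("layout must contain at least one block")
  treatments <- c("T0", "T1", "T2")
  row_length <- vines_per_block * vine_spacing
  width <- rows_per_block * row_spacing
  n_cols <- max(1L, ceiling(sqrt(n_blocks)))
  gap <- 2
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    col <- (b - 1L) %% n_cols
    row <- (b - 1L) %/% n_cols
    x0 <- col * (row_length + gap)
    y0 <- row * (width + gap)
    poly_xy <- cbind(c(x0, x0 + row_length, x0 + row_length, x0, x0),
                     c(y0, y0, y0 + width, y0 + width, y0))
    center_y <- y0 + width / 2
    line_xy <- cbind(c(x0 + 0.5, x0 + row_length - 0.5),
                     c(center_y, center_y))
    blocks[[b]] <- list(
      block_id = sprintf("B%02d", b),
      treatment = treatments[(b - 1L) %% 3L + 1L],
      polygon = xy_to_lonlat(poly_xy[, 1], poly_xy[, 2], origin),
      centerline = xy_to_lonlat(line_xy[, 1], line_xy[, 2], origin)
    )
  }
  structure(list(blocks = blocks, vine_spacing = vine_spacing,
                 row_spacing = row_spacing, row_length = row_length,
                 origin = origin),
            class = "field_layout")
}

#' @export
print.field_layout <- function(x, ...) {
  tr <- table(vapply(x$blocks, `[[`, "", "treatment"))
  cat(sprintf("<field layout: %d blocks (%s), rows %.1f m, spacing %.2f x %.2f m>\n",
              length(x$blocks),
              paste(names(tr), tr, sep = "=", collapse = " "),
              x$row_length, x$vine_spacing, x$row_spacing))
  invisible(x)
}

## Instrument response used to turn reflectance into raw detector counts;
## the acquisition module inverts this exactly via dark/white calibration.
sensor_white_counts <- function(sensor) {
  wl <- sensor$wavelengths
  3000 + 15000 * exp(-((wl - 1500) / 700)^2)
}

sensor_dark_counts <- function(sensor) {
  200 + 0.01 * (sensor$wavelengths - 900)
}

reflectance_to_counts <- function(r, sensor) {
  d <- sensor_dark_counts(sensor)
  w <- sensor_white_counts(sensor)
  if (is.matrix(r)) {
    sweep(sweep(r, 2, w - d, "*"), 2, d, "+")
  } else {
    d + r * (w - d)
  }
}

#' Simulate one on-the-go pass through the plot
#'
#' Drives the virtual vehicle along each block's row at constant speed,
#' emitting raw-count frames at the sensor rate. Each frame views leaf with
#' probability `mix$p_leaf`, otherwise a random interference class. Per
#' block, one potential is drawn from the (date, treatment) distribution
#' and three marked-vine references (one per 5-vine group) are recorded
#' around it. A 20 Hz GPS track along the traversal is returned alongside.
#'
#' @param layout a [field_layout()].
#' @param model a [water_status_model()]; `date` must be one of its dates.
#' @param mix a [scene_mix()].
#' @param sensor a [sensor_spec()].
#' @param date measurement date (must exist in `model`).
#' @param speed_kmh vehicle speed, km/h (field campaigns used 3).
#' @param noise_sd leaf spectral noise, reflectance units.
#' @param rng_seed integer seed; identical seeds give identical passes.
#' @return A `"field_pass"` list: `spectra` (frames x channels raw counts),
#'   `frames` (timestamp, lon, lat, block_id plus generator truth columns
#'   `is_leaf`, `psi_true`, `class`), `gps` (20 Hz track), `references`
#'   (date, block_id, treatment, vine_group, psi_mpa, lon, lat), the
#'   calibration spectra `dark`/`white`, and a leaf `signature` reflectance.
#' @export
simulate_pass <- function(layout, model, mix, sensor, date,
                          speed_kmh = 3, noise_sd = 0.005, rng_seed = 1L) {
  if (!inherits(layout, "field_layout") || length(layout$blocks) == 0) {
    stop("layout must be a non-empty field_layout")
  }
  if (!date %in% model$dates) {
    stop(sprintf("date %s is not part of the water-status model", date))
  }
  if (speed_kmh <= 0) stop("speed_kmh must be positive")
  speed_ms <- speed_kmh / 3.6
  frame_dt <- 1 / sensor$rate_hz
  with_seed(rng_seed, {
    ## static single-leaf signature captured before the pass
    sig_psi <- clamp_psi(psi_mean(model, date, "T1") + stats::rnorm(1, 0, 0.05),
                         model)
    signature <- make_leaf_reflectance(sig_psi, sensor, noise_sd = 0.002,
                                       scatter = FALSE,
                                       water_link = model$water_link,
                                       psi_floor = model$psi_floor)
    spectra <- list(); frames <- list(); refs <- list(); gps <- list()
    t0 <- 0
    for (blk in layout$blocks) {
      mu <- psi_mean(model, date, blk$treatment)
      psi_block <- clamp_psi(stats::rnorm(1, mu, model$sd), model)
      line <- lonlat_to_xy(blk$centerline[, 1], blk$centerline[, 2],
                           layout$origin)
      seg_len <- sqrt(sum((line[2, ] - line[1, ])^2))
      n_frames <- max(1L, floor(seg_len / speed_ms * sensor$rate_hz))
      frac <- (seq_len(n_frames) - 0.5) / n_frames
      pos <- cbind(line[1, 1] + frac * (line[2, 1] - line[1, 1]),
                   line[1, 2] + frac * (line[2, 2] - line[1, 2]))
      ll <- xy_to_lonlat(pos[, 1], pos[, 2], layout$origin)
      ts <- t0 + (seq_len(n_frames) - 1) * frame_dt
      is_leaf <- stats::runif(n_frames) < mix$p_leaf
      cls <- rep(NA_character_, n_frames)
      mat <- matrix(NA_real_, n_frames, sensor$n_channels)
      for (i in seq_len(n_frames)) {
        if (is_leaf[i]) {
          psi_i <- clamp_psi(psi_block + stats::rnorm(1, 0, 0.03), model)
          sp <- make_leaf_reflectance(psi_i, sensor, noise_sd = noise_sd,
                                      water_link = model$water_link,
                                      psi_floor = model$psi_floor)
          mat[i, ] <- sp$values
        } else {
          cls[i] <- sample(names(mix$weights), 1, prob = mix$weights)
          mat[i, ] <- make_interference(cls[i], sensor)$values
        }
      }
      psi_true <- ifelse(is_leaf, psi_block, NA_real_)
      spectra[[blk$block_id]] <- reflectance_to_counts(mat, sensor)
      frames[[blk$block_id]] <- data.frame(
        timestamp = ts, lon = ll[, 1], lat = ll[, 2],
        block_id = blk$block_id, is_leaf = is_leaf, psi_true = psi_true,
        class = cls, stringsAsFactors = FALSE)
      ## 20 Hz RTK GPS track over the same traversal
      gt <- seq(t0, max(ts), by = 0.05)
      gfrac <- pmin((gt - t0) * speed_ms / seg_len + 0.5 / n_frames, 1)
      gpos <- cbind(line[1, 1] + gfrac * (line[2, 1] - line[1, 1]),
                    line[1, 2] + gfrac * (line[2, 2] - line[1, 2]))
      gll <- xy_to_lonlat(gpos[, 1], gpos[, 2], layout$origin)
      gps[[blk$block_id]] <- data.frame(timestamp = gt, lon = gll[, 1],
                                        lat = gll[, 2],
                                        fix_quality = "rtk_fixed",
                                        stringsAsFactors = FALSE)
      ## three marked vines, one per 5-vine group, at 1/6, 1/2, 5/6 of row
      gfr <- c(1, 3, 5) / 6
      rx <- line[1, 1] + gfr * (line[2, 1] - line[1, 1])
      ry <- line[1, 2] + gfr * (line[2, 2] - line[1, 2])
      rll <- xy_to_lonlat(rx, ry, layout$origin)
      refs[[blk$block_id]] <- data.frame(
        date = date, block_id = blk$block_id, treatment = blk$treatment,
        vine_group = 1:3,
        psi_mpa = clamp_psi(psi_block + stats::rnorm(3, 0, 0.05), model),
        lon = rll[, 1], lat = rll[, 2], stringsAsFactors = FALSE)
      t0 <- max(ts) + 5  # turning headland between rows
    }
    structure(list(
      sensor = sensor, date = date, seed = rng_seed,
      spectra = do.call(rbind, spectra),
      frames = do.call(rbind, c(frames, list(make.row.names = FALSE))),
      gps = do.call(rbind, c(gps, list(make.row.names = FALSE))),
      references = do.call(rbind, c(refs, list(make.row.names = FALSE))),
      dark = spectrum(sensor$wavelengths, sensor_dark_counts(sensor), "dark",
                      meta = list(sensor = sensor$name)),
      white = spectrum(sensor$wavelengths, sensor_white_counts(sensor),
                       "white", meta = list(sensor = sensor$name)),
      signature = signature
    ), class = "field_pass")
  })
}

#' @export
print.field_pass <- function(x, ...) {
  cat(sprintf("<field pass %s: %d frames, %d blocks, %d psi references>\n",
              x$date, nrow(x$spectra),
              length(unique(x$frames$block_id)), nrow(x$references)))
  invisible(x)
}

#' Simulate a whole measurement campaign
#'
#' One pass per date; per-date potentials follow the configured dry-down
#' trend (unirrigated vines end the season more stressed than they start).
#' With the default layout (12 blocks, 3 marked vines each) and 6 dates the
#' campaign yields 216 reference measurements.
#'
#' @inheritParams simulate_pass
#' @param dates dates to simulate; default, all dates of `model`.
#' @param out_dir optional directory: writes one stream file per pass, a
#'   reference CSV and a key=value manifest recording every parameter.
#' @return A `"campaign"` list of passes plus the pooled `references`
#'   table and the `manifest` character vector.
#' @export
simulate_campaign <- function(layout, model, mix, sensor,
                              dates = model$dates, speed_kmh = 3,
                              noise_sd = 0.005, rng_seed = 1L,
                              out_dir = NULL) {
  if (length(dates) < 2L) stop("a campaign needs at least two dates")
  passes <- vector("list", length(dates))
  names(passes) <- dates
  for (i in seq_along(dates)) {
    passes[[i]] <- simulate_pass(layout, model, mix, sensor, dates[i],
                                 speed_kmh = speed_kmh, noise_sd = noise_sd,
                                 rng_seed = rng_seed + 1000L * i)
  }
  references <- do.call(rbind, c(lapply(passes, `[[`, "references"),
                                 list(make.row.names = FALSE)))
  manifest <- c(
    sensor = sensor$name, n_channels = sensor$n_channels,
    wl_min = sensor$wl_min, wl_max = sensor$wl_max, step = sensor$step,
    rate_hz = sensor$rate_hz, n_blocks = length(layout$blocks),
    vine_spacing = layout$vine_spacing, row_spacing = layout$row_spacing,
    dates = paste(dates, collapse = ";"),
    date_means = paste(signif(model$date_means[dates], 6), collapse = ";"),
    treatment_offsets = paste(names(model$treatment_offsets),
                              model$treatment_offsets, sep = "=",
                              collapse = ";"),
    psi_sd = model$sd, psi_floor = model$psi_floor,
    psi_ceil = model$psi_ceil,
    water_link = paste(model$water_link, collapse = ";"),
    p_leaf = mix$p_leaf, speed_kmh = speed_kmh, noise_sd = noise_sd,
    rng_seed = rng_seed)
  manifest <- paste(names(manifest), manifest, sep = "=")
  out <- structure(list(passes = passes, references = references,
                        layout = layout, model = model, mix = mix,
                        sensor = sensor, manifest = manifest),
                   class = "campaign")
  if (!is.null(out_dir)) write_campaign(out, out_dir)
  out
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf("<campaign: %d dates x %d blocks, %d psi references>\n",
              length(x$passes), length(x$layout$blocks),
              nrow(x$references)))
  invisible(x)
}

## ---- plain-text persistence ------------------------------------------------

#' Write a pass stream to a plain-text table
#'
#' Header lines `# sensor=`, `# date=`, `# seed=`; columns timestamp, lon,
#' lat, then one column per wavelength (nm to 0.01).
#'
#' @param pass a `"field_pass"`.
#' @param path output file.
#' @export
write_stream <- function(pass, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sensor=%s", pass$sensor$name),
               sprintf("# date=%s", pass$date),
               sprintf("# seed=%d", pass$seed)), con)
  tab <- cbind(pass$frames[, c("timestamp", "lon", "lat")],
               as.data.frame(pass$spectra))
  names(tab) <- c("timestamp", "lon", "lat",
                  sprintf("%.2f", pass$sensor$wavelengths))
  utils::write.table(format(tab, digits = 9, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pass stream written by [write_stream()]
#'
#' @param path stream file.
#' @return list with `spectra` matrix, `frames` data frame (timestamp, lon,
#'   lat), `wavelengths`, and the header fields.
#' @export
read_stream <- function(path) {
  hdr <- readLines(path, n = 3)
  kv <- sub("^# ", "", hdr)
  fields <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 3,
                           check.names = FALSE)
  list(spectra = as.matrix(tab[, -(1:3), drop = FALSE]),
       frames = tab[, 1:3],
       wavelengths = as.numeric(names(tab)[-(1:3)]),
       sensor = fields[["sensor"]], date = fields[["date"]],
       seed = as.integer(fields[["seed"]]))
}

write_campaign <- function(campaign, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in names(campaign$passes)) {
    write_stream(campaign$passes[[d]],
                 file.path(out_dir, sprintf("stream_%s.txt", d)))
  }
  utils::write.csv(campaign$references,
                   file.path(out_dir, "references.csv"), row.names = FALSE)
  writeLines(campaign$manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
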