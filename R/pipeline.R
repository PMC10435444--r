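#' Run the full water-status workflow end to end
#'
#' Chains every stage on a simulated campaign: spectral stream generation,
#' acquisition replay with cosine filtering, block allocation and
#' averaging, external validation split, PLS calibration with
#' venetian-blind cross-validation and VIP, external validation, and
#' per-date predicted and reference water-status maps with their agreement
#' report. Every stage's artifacts can be written to `out_dir` (stream
#' files, reference CSV, manifest, model JSON, prediction CSV, GeoJSON
#' maps, run log).
#'
#' @param seed integer master seed; every random stage derives from it,
#'   so reruns are bit-identical.
#' @param out_dir optional artifact directory.
#' @param sensor a [sensor_spec()] (default [sensor2()], the automated
#'   workflow's device).
#' @param layout a [field_layout()].
#' @param model a [water_status_model()].
#' @param mix a [scene_mix()].
#' @param threshold cosine filter threshold (default 0.985).
#' @param preproc a [preproc_config()].
#' @param per_date external validation samples per date (default 7).
#' @param map_date date to map (default, the last campaign date).
#' @param n_classes,scheme,cell_size map classification and grid
#'   settings, see [classify_map()] and [tps_interpolate()].
#' @param noise_sd leaf spectral noise level.
#' @return list with `campaign`, `samples`, `split`, `model`
#'   (a [psi_model()]), `validation` (external metrics), `maps`
#'   (`predicted`, `reference`, `agreement`), and `log` (per-stage
#'   counts).
#' @export
run_pipeline <- function(seed = 1L, out_dir = NULL,
                         sensor = sensor2(),
                         layout = field_layout(),
                         model = water_status_model(),
                         mix = scene_mix(),
                         threshold = 0.985,
                         preproc = preproc_config(),
                         per_date = 7L,
                         map_date = NULL,
                         n_classes = 5, scheme = "quantile",
                         cell_size = 2,
                         noise_sd = 0.005) {
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log <<- c(log, line)
  }
  campaign <- simulate_campaign(layout, model, mix, sensor,
                                noise_sd = noise_sd, rng_seed = seed,
                                out_dir = if (!is.null(out_dir))
                                  file.path(out_dir, "streams"))
  say("simulate: %d dates, %d frames, %d psi references",
      length(campaign$passes),
      sum(vapply(campaign$passes, function(p) nrow(p$spectra), 0)),
      nrow(campaign$references))
  samples <- build_samples(campaign, cfg = filter_config(threshold))
  say("filter: %d samples from %d block-date means (threshold %.3f)",
      nrow(samples$spectra), nrow(unique(samples$info[c("date", "block_id")])),
      threshold)
  split <- external_split(samples, per_date = per_date,
                          rng_seed = seed + 7L)
  say("split: %d calibration / %d external validation samples",
      length(split$train_idx), length(split$val_idx))
  fit <- psi_model(split$train, preproc = preproc)
  say("train: LV = %d, R2c = %.3f, RMSEC = %.3f, R2cv = %.3f, RMSECV = %.3f",
      fit$metrics$n_lv, fit$metrics$r2c, fit$metrics$rmsec,
      fit$metrics$r2cv, fit$metrics$rmsecv)
  val <- evaluate_model(fit, split$validation)
  say("validate: R2p = %.3f, RMSEP = %.3f MPa (n = %d)", val$r2p,
      val$rmsep, val$n)
  if (is.null(map_date)) map_date <- utils::tail(model$dates, 1)
  maps <- map_campaign_date(fit, samples, map_date, n_classes = n_classes,
                            scheme = scheme, cell_size = cell_size)
  say("map: %s, class agreement %.2f, r = %.2f, RMSD = %.3f MPa",
      map_date, maps$agreement$class_agreement, maps$agreement$r,
      maps$agreement$rmsd)
  out <- list(campaign = campaign, samples = samples, split = split,
              model = fit, validation = val, maps = maps, log = log,
              seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_model_json(fit, file.path(out_dir, "model.json"),
                     seed = seed)
    utils::write.csv(cbind(samples$info,
                           predicted = predict(fit, samples)),
                     file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    map_to_geojson(maps$predicted, file.path(out_dir, "map_predicted.geojson"))
    map_to_geojson(maps$reference, file.path(out_dir, "map_reference.geojson"))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  invisible(out)
}

#' Predicted and reference maps for one date
#'
#' Builds the two maps the decision workflow compares: the surface
#' interpolated from model predictions at the reference vine locations,
#' and the surface interpolated from the pressure-chamber references
#' themselves, classified identically.
#'
#' @param model a [psi_model()].
#' @param samples the [psi_samples()] the campaign produced.
#' @param date campaign date to map.
#' @param n_classes,scheme,cell_size see [classify_map()] /
#'   [tps_interpolate()].
#' @return list with classified `predicted` and `reference` grids and
#'   their [compare_maps()] `agreement`.
#' @export
map_campaign_date <- function(model, samples, date, n_classes = 5,
                              scheme = "quantile", cell_size = 2) {
  sel <- samples$info$date == date
  if (!any(sel)) stop(sprintf("no samples for date %s", date))
  sub <- samples[which(sel)]
  pred <- predict(model, sub)
  origin <- c(mean(sub$info$lon), mean(sub$info$lat))
  ref_pts <- data.frame(lon = sub$info$lon, lat = sub$info$lat,
                        psi_mpa = sub$info$psi_mpa)
  prd_pts <- data.frame(lon = sub$info$lon, lat = sub$info$lat,
                        psi_mpa = pred)
  gref <- classify_map(tps_interpolate(ref_pts, cell_size = cell_size,
                                       origin = origin),
                       n_classes, scheme)
  gprd <- classify_map(tps_interpolate(prd_pts, cell_size = cell_size,
                                       origin = origin),
                       n_classes, scheme)
  list(predicted = gprd, reference = gref,
       agreement = compare_maps(gprd, gref))
}

#' Serialize a fitted model to JSON
#'
#' Writes the wavelength grid, preprocessing recipe, centering vectors,
#' NIPALS weights/loadings and regression vector, chosen complexity,
#' metrics and provenance, so a saved model can be reloaded and applied
#' to new sessions.
#'
#' @param model a [psi_model()].
#' @param path output file.
#' @param seed optional provenance seed recorded in the file.
#' @export
write_model_json <- function(model, path, seed = NULL) {
  obj <- list(
    wavelengths = model$wavelengths,
    preproc = unclass(model$preproc),
    n_lv = model$pls$ncomp,
    x_mean = model$pls$x_mean, y_mean = model$pls$y_mean,
    weights = model$pls$weights, loadings = model$pls$loadings,
    yloadings = model$pls$yloadings, b = model$pls$b,
    metrics = model$metrics,
    vip = unname(model$vip$scores),
    provenance = list(seed = seed, n = model$metrics$n,
                      package = "vinespec"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a model written by [write_model_json()]
#'
#' @param path model JSON file.
#' @return A `"psi_model"`-compatible object supporting
#'   [predict.psi_model()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  win <- obj$preproc$savgol$window
  if (length(win) == 0) win <- NULL  # auto window serializes as empty
  preproc <- preproc_config(steps = obj$preproc$steps,
                            window = win,
                            polyorder = obj$preproc$savgol$polyorder,
                            deriv = obj$preproc$savgol$deriv)
  pls <- structure(list(weights = as.matrix(obj$weights),
                        loadings = as.matrix(obj$loadings),
                        yloadings = obj$yloadings,
                        b = obj$b, x_mean = obj$x_mean,
                        y_mean = obj$y_mean, ncomp = obj$n_lv,
                        wavelengths = obj$wavelengths),
                   class = "pls1")
  structure(list(pls = pls, preproc = preproc,
                 wavelengths = obj$wavelengths, metrics = obj$metrics,
                 vip = structure(list(scores = obj$vip,
                                      influential = which(obj$vip > 1),
                                      wavelengths = obj$wavelengths),
                                 class = "vip_scores")),
            class = "psi_model")
}
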