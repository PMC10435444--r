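#' Calibrate a stem-water-potential model from block-averaged spectra
#'
#' The package's central fitting function. Given calibration samples
#' (block-mean reflectance spectra paired with pressure-chamber stem water
#' potential), it
#' \enumerate{
#'   \item runs ten-fold venetian-blind cross-validation over the latent
#'     variable range, with preprocessing and centering recomputed inside
#'     each training fold,
#'   \item retains the first-local-minimum RMSECV complexity,
#'   \item refits the PLS1/NIPALS model on all samples at that complexity,
#'   \item computes VIP wavelength importance.
#' }
#' The preprocessing recipe is stored in the model and re-applied verbatim
#' by [predict.psi_model()].
#'
#' @param samples a [psi_samples()] object.
#' @param preproc a [preproc_config()] (default: SNV then Savitzky-Golay
#'   first derivative).
#' @param k venetian-blind folds, default 10.
#' @param a_max maximum latent variables scanned, default 20.
#' @param n_lv optional fixed number of latent variables, bypassing the
#'   first-local-minimum rule (cross-validation still runs for the error
#'   curve).
#' @return An object of class `"psi_model"`: the inner `"pls1"` fit,
#'   `cv` (a `"pls_cv"`), `vip`, `preproc`, `wavelengths`, and `metrics`
#'   (`r2c`, `rmsec`, `r2cv`, `rmsecv`, `n_lv`).
#' @examples
#' \donttest{
#' camp <- simulate_campaign(field_layout(), water_status_model(),
#'                           scene_mix(), sensor2(), rng_seed = 42)
#' samples <- build_samples(camp)
#' m <- psi_model(samples)
#' summary(m)
#' }
#' @export
psi_model <- function(samples, preproc = preproc_config(), k = 10L,
                      a_max = 20L, n_lv = NULL) {
  stopifnot(inherits(samples, "psi_samples"))
  X <- samples$spectra
  y <- samples$info$psi_mpa
  cv <- cross_validate(X, y, k = k, a_max = a_max, preproc = preproc,
                       wavelengths = samples$wavelengths)
  A <- if (is.null(n_lv)) cv$chosen_lv else n_lv
  Xp <- apply_pipeline(X, samples$wavelengths, preproc)
  fit <- pls_fit(Xp, y, A, wavelengths = samples$wavelengths)
  cal <- regression_metrics(y, fit$fitted.values)
  structure(list(
    pls = fit, cv = cv, vip = vip_scores(fit), preproc = preproc,
    wavelengths = samples$wavelengths, info = samples$info,
    metrics = list(r2c = cal$r2, rmsec = cal$rmse,
                   r2cv = cv$r2cv,
                   rmsecv = cv$rmsecv_by_lv[min(A, cv$a_max)],
                   n_lv = fit$ncomp, n = nrow(X)),
    call = match.call()
  ), class = "psi_model")
}

#' @export
print.psi_model <- function(x, ...) {
  m <- x$metrics
  cat("Stem water potential calibration (PLS1, venetian-blind CV)\n")
  cat(sprintf("  n = %d samples, %d channels, %d latent variable(s)\n",
              m$n, length(x$wavelengths), m$n_lv))
  cat(sprintf("  R2c  = %.3f   RMSEC  = %.3f MPa\n", m$r2c, m$rmsec))
  cat(sprintf("  R2cv = %.3f   RMSECV = %.3f MPa\n", m$r2cv, m$rmsecv))
  invisible(x)
}

#' @export
summary.psi_model <- function(object, ...) {
  out <- list(metrics = object$metrics,
              preproc = object$preproc,
              n_influential = length(object$vip$influential),
              top_wavelengths = if (!is.null(object$vip$wavelengths)) {
                ord <- order(object$vip$scores, decreasing = TRUE)
                utils::head(data.frame(
                  wavelength_nm = object$vip$wavelengths[ord],
                  vip = unname(object$vip$scores[ord])), 5)
              },
              rmsecv_by_lv = object$cv$rmsecv_by_lv)
  class(out) <- "summary.psi_model"
  out
}

#' @export
print.summary.psi_model <- function(x, ...) {
  m <- x$metrics
  cat("Stem water potential calibration\n")
  print(x$preproc)
  cat(sprintf("  n = %d, LV = %d (first local RMSECV minimum)\n", m$n, m$n_lv))
  cat(sprintf("  R2c  = %.3f   RMSEC  = %.3f MPa\n", m$r2c, m$rmsec))
  cat(sprintf("  R2cv = %.3f   RMSECV = %.3f MPa\n", m$r2cv, m$rmsecv))
  cat(sprintf("  influential wavelengths (VIP > 1): %d\n", x$n_influential))
  if (!is.null(x$top_wavelengths)) {
    cat("  top VIP wavelengths:\n")
    print(format(x$top_wavelengths, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Predict stem water potential from new spectra
#'
#' Applies the model's stored preprocessing recipe and regression vector.
#' The wavelength grid of the new spectra must match the training grid.
#'
#' @param object a [psi_model()].
#' @param newdata a [psi_samples()] object, a numeric matrix
#'   (samples x channels), or a single [spectrum()].
#' @param wavelengths grid of `newdata` when it is a bare matrix; checked
#'   against the training grid.
#' @param ... unused.
#' @return Numeric vector of predicted potentials, MPa.
#' @export
predict.psi_model <- function(object, newdata, wavelengths = NULL, ...) {
  if (inherits(newdata, "psi_samples")) {
    wavelengths <- newdata$wavelengths
    newdata <- newdata$spectra
  } else if (is_spectrum(newdata)) {
    wavelengths <- newdata$wavelengths
    newdata <- matrix(newdata$values, 1)
  }
  newdata <- as.matrix(newdata)
  if (!is.null(wavelengths)) {
    if (length(wavelengths) != length(object$wavelengths) ||
        max(abs(wavelengths - object$wavelengths)) > 1e-6) {
      stop(sprintf("wavelength grid mismatch: model expects %d channels %.2f-%.2f nm",
                   length(object$wavelengths), min(object$wavelengths),
                   max(object$wavelengths)))
    }
  } else if (ncol(newdata) != length(object$wavelengths)) {
    stop(sprintf("wavelength grid mismatch: model expects %d channels %.2f-%.2f nm",
                 length(object$wavelengths), min(object$wavelengths),
                 max(object$wavelengths)))
  }
  Xp <- apply_pipeline(newdata, object$wavelengths, object$preproc)
  predict(object$pls, Xp)
}

#' @export
coef.psi_model <- function(object, ...) coef(object$pls)

#' @export
fitted.psi_model <- function(object, ...) fitted(object$pls)

#' @export
residuals.psi_model <- function(object, ...) residuals(object$pls)

#' Externally validate a fitted model
#'
#' Computes the prediction metrics (R2p, RMSEP, bias) on a held-out sample
#' set, e.g. the validation part of [external_split()].
#'
#' @param model a [psi_model()].
#' @param samples a [psi_samples()] object not used in calibration.
#' @return list with `r2p`, `rmsep`, `bias`, `n`, and the predictions.
#' @export
evaluate_model <- function(model, samples) {
  pred <- predict(model, samples)
  m <- regression_metrics(samples$info$psi_mpa, pred)
  list(r2p = m$r2, rmsep = m$rmse, bias = m$bias, n = m$n,
       predicted = pred, observed = samples$info$psi_mpa)
}

#' Diagnostic plots for a water-status calibration
#'
#' `which = 1`: measured vs cross-validated predictions; `which = 2`:
#' RMSECV against the number of latent variables with the retained
#' complexity marked; `which = 3`: VIP profile with the VIP = 1 influence
#' threshold and the water absorption bands (978, 1454, 1935 nm) shaded.
#'
#' @param x a [psi_model()].
#' @param which subset of `1:3`.
#' @param ... passed to the underlying plot calls.
#' @export
plot.psi_model <- function(x, which = 1:3, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    y <- x$pls$y
    pred <- x$cv$cv_pred[, min(x$metrics$n_lv, x$cv$a_max)]
    graphics::plot(y, pred, xlab = "measured psi (MPa)",
                   ylab = "CV-predicted psi (MPa)",
                   main = sprintf("R2cv = %.2f", x$metrics$r2cv), ...)
    graphics::abline(0, 1, lty = 2)
  }
  if (2 %in% which) {
    graphics::plot(seq_along(x$cv$rmsecv_by_lv), x$cv$rmsecv_by_lv,
                   type = "b", xlab = "latent variables",
                   ylab = "RMSECV (MPa)", main = "complexity selection", ...)
    graphics::abline(v = x$metrics$n_lv, lty = 3)
  }
  if (3 %in% which) {
    wl <- x$wavelengths
    graphics::plot(wl, x$vip$scores, type = "l", xlab = "wavelength (nm)",
                   ylab = "VIP score", main = "wavelength importance", ...)
    graphics::abline(h = 1, lty = 2)
    for (ctr in c(978, 1454, 1935)) {
      if (ctr >= min(wl) && ctr <= max(wl)) {
        graphics::rect(ctr - 30, graphics::par("usr")[3], ctr + 30,
                       graphics::par("usr")[4],
                       col = grDevices::adjustcolor("steelblue", 0.15),
                       border = NA)
      }
    }
  }
  invisible(x)
}
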