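## Scatter correction and derivative spectroscopy, applied identically at
## calibration and prediction time (the configuration is serialized into
## fitted models).

#' Standard normal variate transform
#'
#' Per-spectrum centering and scaling, `(x - mean(x)) / sd(x)` with the
#' sample (n-1) standard deviation: removes additive offsets and
#' multiplicative scatter. Output has mean 0 and sd 1; the transform is
#' idempotent and invariant to `a*x + b` for `a > 0`.
#'
#' @param x numeric vector, [spectrum()], or samples-by-channels matrix
#'   (rows transformed independently).
#' @return Same shape as the input.
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
#' @export
snv <- function(x) {
  if (is_spectrum(x)) {
    return(spectrum(x$wavelengths, snv(x$values), kind = x$kind,
                    meta = x$meta))
  }
  if (is.matrix(x)) {
    m <- rowMeans(x)
    s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1))
    if (any(s == 0)) stop("zero-variance spectrum: SNV undefined")
    return((x - m) / s)
  }
  if (length(x) < 2L) stop("SNV needs at least two channels")
  s <- stats::sd(x)
  if (s == 0) stop("zero-variance spectrum: SNV undefined")
  (x - mean(x)) / s
}

## Local polynomial least-squares (Savitzky-Golay) operator as an n x n
## band matrix. Interior rows share one centered stencil; edge rows refit
## the polynomial on the truncated window and evaluate at the edge channel,
## so output length equals input length. `step` scales derivatives to
## per-nm units.
savgol_matrix <- function(n, window, polyorder, deriv, step = 1) {
  if (window %% 2 == 0 || window <= polyorder) {
    stop("Savitzky-Golay window must be odd and larger than polyorder")
  }
  if (deriv > polyorder) stop("derivative order cannot exceed polyorder")
  if (n < window) stop("spectrum has fewer channels than the window")
  h <- (window - 1L) %/% 2L
  stencil <- function(offsets) {
    ## least-squares polynomial fit on a scaled abscissa (QR keeps the
    ## Vandermonde system well conditioned up to high polyorder)
    z <- offsets * step
    s <- max(abs(z), 1)
    A <- outer(z / s, 0:polyorder, `^`)
    coef <- qr.solve(A, diag(length(offsets)))[deriv + 1L, ]
    coef * factorial(deriv) / s^deriv
  }
  interior <- stencil(-h:h)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    D[i, lo:hi] <- if (lo == i - h && hi == i + h) interior else
      stencil((lo:hi) - i)
  }
  D
}

#' Savitzky-Golay smoothing / derivative
#'
#' Least-squares local polynomial convolution. Derivatives are scaled by
#' the channel spacing, so a first derivative is in units per nm. Edge
#' channels are handled by refitting the polynomial on the truncated
#' window (output keeps the full channel grid, which keeps wavelength
#' indexing stable for the regression and VIP stages).
#'
#' Default windows: 15 channels for dense grids (>= 300 channels, ~30 nm
#' at 2 nm spacing) and 7 otherwise (~57 nm at 8.2 nm spacing).
#'
#' @param x numeric vector, [spectrum()], or samples-by-channels matrix.
#' @param wavelengths channel grid, nm; required (to scale the abscissa)
#'   unless `x` is a spectrum. Must be uniformly spaced.
#' @param window odd window length in channels; `NULL` picks the default
#'   for the grid density.
#' @param polyorder local polynomial degree (default 2).
#' @param deriv derivative order (default 1; 0 = smoothing only).
#' @return Same shape as the input.
#' @export
savgol_derivative <- function(x, wavelengths = NULL, window = NULL,
                              polyorder = 2, deriv = 1) {
  if (is_spectrum(x)) {
    return(spectrum(x$wavelengths,
                    savgol_derivative(x$values, x$wavelengths, window,
                                      polyorder, deriv),
                    kind = x$kind, meta = x$meta))
  }
  if (is.null(wavelengths)) stop("wavelengths are required to scale the derivative")
  n <- length(wavelengths)
  dw <- diff(wavelengths)
  if (max(dw) - min(dw) > 1e-6 * mean(dw)) {
    stop("Savitzky-Golay requires a uniform wavelength grid")
  }
  if (is.null(window)) window <- if (n >= 300) 15L else 7L
  D <- savgol_matrix(n, window, polyorder, deriv, step = mean(dw))
  if (is.matrix(x)) x %*% t(D) else as.numeric(D %*% x)
}

#' Preprocessing configuration
#'
#' An ordered recipe over `{"snv", "savgol"}`. The default — SNV first,
#' then the Savitzky-Golay first derivative — is the combination that
#' produced the best water-status models; the reverse order is selectable.
#'
#' @param steps character vector, applied in order; may be empty
#'   (identity).
#' @param window,polyorder,deriv Savitzky-Golay settings, see
#'   [savgol_derivative()].
#' @return A `"preproc_config"` object (serializable to/from JSON with
#'   [jsonlite::toJSON()]).
#' @export
preproc_config <- function(steps = c("snv", "savgol"), window = NULL,
                           polyorder = 2, deriv = 1) {
  if (!all(steps %in% c("snv", "savgol"))) {
    stop("steps must be drawn from {snv, savgol}")
  }
  if (!is.null(window)) {
    if (window %% 2 == 0 || window <= polyorder) {
      stop("window must be odd and larger than polyorder")
    }
  }
  if (deriv > polyorder) stop("deriv must not exceed polyorder")
  structure(list(steps = as.character(steps),
                 savgol = list(window = window, polyorder = polyorder,
                               deriv = deriv)),
            class = "preproc_config")
}

#' @export
print.preproc_config <- function(x, ...) {
  sg <- sprintf("window=%s, polyorder=%d, deriv=%d",
                ifelse(is.null(x$savgol$window), "auto", x$savgol$window),
                x$savgol$polyorder, x$savgol$deriv)
  cat(sprintf("<preprocessing: %s (%s)>\n",
              if (length(x$steps)) paste(x$steps, collapse = " -> ")
              else "identity", sg))
  invisible(x)
}

#' Apply a preprocessing recipe to a batch of spectra
#'
#' Steps are applied in configured order. All operations are per-spectrum
#' (no training statistics), so the same call is used on calibration and
#' prediction data.
#'
#' @param X samples-by-channels matrix (or [psi_samples()], whose spectra
#'   are transformed).
#' @param wavelengths channel grid, nm.
#' @param config a [preproc_config()].
#' @return The transformed matrix.
#' @export
apply_pipeline <- function(X, wavelengths, config = preproc_config()) {
  if (inherits(X, "psi_samples")) {
    return(apply_pipeline(X$spectra, X$wavelengths, config))
  }
  X <- as.matrix(X)
  if (ncol(X) != length(wavelengths)) {
    stop("spectra and wavelength grid differ in channel count")
  }
  for (step in config$steps) {
    X <- switch(step,
      snv = snv(X),
      savgol = savgol_derivative(X, wavelengths,
                                 window = config$savgol$window,
                                 polyorder = config$savgol$polyorder,
                                 deriv = config$savgol$deriv))
  }
  X
}
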