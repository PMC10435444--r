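#' Construct a spectrum
#'
#' A spectrum couples a strictly increasing wavelength grid (nm) with a
#' value vector of the same length. `kind` records the processing state:
#' raw detector counts, dark/white references, or calibrated reflectance.
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param values numeric vector of the same length (counts or reflectance).
#' @param kind one of `"raw"`, `"dark"`, `"white"`, `"reflectance"`.
#' @param meta named list of acquisition metadata (sensor name, timestamp,
#'   lon/lat, ...). Free-form.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavelengths, values,
                     kind = c("raw", "dark", "white", "reflectance"),
                     meta = list()) {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have the same length")
  }
  if (length(wavelengths) < 2L || any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (kind == "reflectance" && any(!is.finite(values))) {
    stop("reflectance spectra must be finite at every channel")
  }
  structure(list(wavelengths = wavelengths, values = values,
                 kind = kind, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  rng <- range(x$wavelengths)
  cat(sprintf("<spectrum: %s, %d channels, %.1f-%.1f nm>\n",
              x$kind, length(x$values), rng[1], rng[2]))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

## shared-grid check used by calibration, filtering and prediction
check_same_grid <- function(a, b, what = "spectra") {
  wa <- if (is_spectrum(a)) a$wavelengths else a
  wb <- if (is_spectrum(b)) b$wavelengths else b
  if (length(wa) != length(wb) || max(abs(wa - wb)) > 1e-6) {
    stop(sprintf("%s are not on the same wavelength grid", what))
  }
  invisible(TRUE)
}

spec_values <- function(x) if (is_spectrum(x)) x$values else as.numeric(x)

#' Define a spectrometer
#'
#' The channel count follows from range and step as
#' `floor((wl_max - wl_min) / step) + 1`.
#'
#' @param name sensor label.
#' @param wl_min,wl_max spectral range in nm.
#' @param step sampling step (resolution) in nm.
#' @param rate_hz acquisition rate in spectra per second.
#' @return A `"sensor_spec"` object with a `$wavelengths` grid.
#' @examples
#' s <- sensor_spec("demo", 900, 1860, 8.2, 12.5)
#' s$n_channels  # 118
#' @export
sensor_spec <- function(name, wl_min, wl_max, step, rate_hz) {
  stopifnot(wl_min < wl_max, step > 0, rate_hz > 0)
  n <- floor((wl_max - wl_min) / step + 1e-9) + 1L
  structure(list(name = name, wl_min = wl_min, wl_max = wl_max,
                 step = step, n_channels = as.integer(n),
                 rate_hz = rate_hz,
                 wavelengths = wl_min + step * (seq_len(n) - 1)),
            class = "sensor_spec")
}

#' @export
print.sensor_spec <- function(x, ...) {
  cat(sprintf("<sensor %s: %g-%g nm, %g nm step, %d channels, %g Hz>\n",
              x$name, x$wl_min, x$wl_max, x$step, x$n_channels, x$rate_hz))
  invisible(x)
}

#' Built-in sensor definitions
#'
#' `sensor1()` is a bench-grade NIR spectrometer (1100-2100 nm, 2 nm step,
#' 501 channels, 14 Hz). `sensor2()` is a miniaturized micro-spectrometer
#' (900-1860 nm, 8.2 nm resolution, 118 channels, 12.5 Hz), the device the
#' automated acquisition workflow targets.
#'
#' @return A [sensor_spec()] object.
#' @export
sensor1 <- function() sensor_spec("sensor1", 1100, 2100, 2, 14)

#' @rdname sensor1
#' @export
sensor2 <- function() sensor_spec("sensor2", 900, 1860, 8.2, 12.5)

## Evaluate code under a temporary RNG state; the global stream is restored
## afterwards so seeded generator calls do not perturb callers.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

## ---- small planar geometry helpers ----------------------------------------

EARTH_RADIUS_M <- 6371008.8

## Local azimuthal-equidistant-style projection about an origin: adequate for
## sub-kilometre vineyard plots where curvature is negligible.
lonlat_to_xy <- function(lon, lat, origin) {
  lat0 <- origin[2] * pi / 180
  cbind(x = (lon - origin[1]) * pi / 180 * EARTH_RADIUS_M * cos(lat0),
        y = (lat - origin[2]) * pi / 180 * EARTH_RADIUS_M)
}

xy_to_lonlat <- function(x, y, origin) {
  lat0 <- origin[2] * pi / 180
  cbind(lon = origin[1] + x / (EARTH_RADIUS_M * cos(lat0)) * 180 / pi,
        lat = origin[2] + y / EARTH_RADIUS_M * 180 / pi)
}

## Even-odd rule point-in-polygon; `poly` is a two-column matrix, open or
## closed ring. Points exactly on a vertical edge count as inside.
point_in_polygon <- function(px, py, poly) {
  nx <- poly[, 1]; ny <- poly[, 2]
  n <- length(nx)
  if (nx[1] == nx[n] && ny[1] == ny[n]) {
    nx <- nx[-n]; ny <- ny[-n]; n <- n - 1L
  }
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ny[i] > py) != (ny[j] > py)) &
      (px < (nx[j] - nx[i]) * (py - ny[i]) / (ny[j] - ny[i]) + nx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
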