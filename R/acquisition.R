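## Automated acquisition workflow: two-point reflectance calibration,
## leaf-signature capture, and streaming capture with live cosine filtering
## and GPS pairing. The workflow is a strict state machine — dark, then
## white, then signature, then measurement — mirroring the button sequence
## of the field software.

#' Two-point reflectance calibration
#'
#' `R(wl) = (S(wl) - D(wl)) / (W(wl) - D(wl))` channel-wise, with a dark
#' reference D (shuttered) and a white reference W (reflectance standard).
#' Values below 0 or above 1 (noise at calibration edges) are kept, not
#' clipped: downstream scatter correction is scale-invariant and clipping
#' would only distort.
#'
#' @param sample raw [spectrum()] to calibrate.
#' @param dark,white reference spectra on the same wavelength grid.
#' @return A reflectance [spectrum()].
#' @export
compute_reflectance <- function(sample, dark, white) {
  check_same_grid(sample, dark, "sample and dark reference")
  check_same_grid(sample, white, "sample and white reference")
  s <- spec_values(sample); d <- spec_values(dark); w <- spec_values(white)
  denom <- w - d
  bad <- which(denom == 0)
  if (length(bad)) {
    stop(sprintf("white and dark references coincide at %d channel(s): %s",
                 length(bad),
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  wl <- if (is_spectrum(sample)) sample$wavelengths else
    stop("sample must be a spectrum")
  spectrum(wl, (s - d) / denom, kind = "reflectance",
           meta = if (is_spectrum(sample)) sample$meta else list())
}

## Vectorized calibration of a frames-by-channels raw-count matrix.
calibrate_stream <- function(counts, dark, white) {
  denom <- white - dark
  if (any(denom == 0)) {
    stop("white and dark references coincide at some channel(s)")
  }
  sweep(sweep(counts, 2, dark, "-"), 2, denom, "/")
}

#' Mean of the five largest channel values
#'
#' The live sanity statistic shown during referencing: a saturated or dark
#' frame is immediately visible from it.
#'
#' @param s a [spectrum()] or numeric vector with at least five channels.
#' @return Numeric scalar.
#' @examples
#' top5_mean(c(1, 2, 3, 4, 5, 6))  # 4
#' @export
top5_mean <- function(s) {
  v <- spec_values(s)
  if (length(v) < 5L) stop("top5_mean needs at least 5 channels")
  mean(sort(v, decreasing = TRUE)[1:5])
}

#' Start an acquisition session
#'
#' Sessions advance through a fixed state machine:
#' [acq_dark()] -> [acq_white()] -> [acq_signature()] -> [acq_measure()];
#' calling a step before its predecessors errors, naming the missing step.
#'
#' @param threshold cosine filter threshold (default 0.985).
#' @param gps_tolerance maximum |frame time - fix time| for GPS pairing,
#'   seconds; frames without a fix inside it are flagged unlocated but
#'   still filtered.
#' @return An `"acquisition_session"`.
#' @export
acquisition_session <- function(threshold = 0.985, gps_tolerance = 0.5) {
  structure(list(threshold = threshold, gps_tolerance = gps_tolerance,
                 dark = NULL, white = NULL, signature = NULL,
                 accepted = NULL, accepted_meta = NULL,
                 rejected_count = 0L, n_frames = 0L, log = list()),
            class = "acquisition_session")
}

require_step <- function(session, step) {
  if (is.null(session[[step]])) {
    stop(sprintf("workflow out of order: %s reference not captured yet", step))
  }
}

#' Acquisition workflow steps
#'
#' Capture the dark reference, the white reference, and the single-leaf
#' spectral signature, in that order. `acq_signature()` accepts either an
#' already calibrated reflectance spectrum or a raw one (calibrated against
#' the stored references). Each step records the top-5-channel mean in the
#' session log.
#'
#' @param session an [acquisition_session()].
#' @param s the captured [spectrum()].
#' @return The updated session.
#' @export
acq_dark <- function(session, s) {
  session$dark <- s
  session$log$dark_top5 <- top5_mean(s)
  session
}

#' @rdname acq_dark
#' @export
acq_white <- function(session, s) {
  require_step(session, "dark")
  check_same_grid(s, session$dark, "white and dark references")
  session$white <- s
  session$log$white_top5 <- top5_mean(s)
  session
}

#' @rdname acq_dark
#' @export
acq_signature <- function(session, s) {
  require_step(session, "dark")
  require_step(session, "white")
  if (is_spectrum(s) && s$kind == "raw") {
    s <- compute_reflectance(s, session$dark, session$white)
  }
  check_same_grid(s, session$dark, "signature and references")
  session$signature <- s
  session$log$signature_top5 <- top5_mean(s)
  session
}

#' Stream measurement with live filtering and georeferencing
#'
#' Calibrates each raw frame to reflectance, pairs it with the
#' nearest-in-time GPS fix (within the session tolerance; otherwise the
#' frame is flagged unlocated but still filtered), and accepts it iff its
#' cosine similarity to the leaf signature reaches the threshold.
#'
#' @param session an [acquisition_session()] with all references captured.
#' @param counts frames-by-channels raw count matrix.
#' @param timestamps frame times, seconds.
#' @param gps optional data frame `timestamp, lon, lat` (e.g. a 20 Hz RTK
#'   track).
#' @return The session, with `accepted` (reflectance matrix),
#'   `accepted_meta` (timestamp, lon, lat, located, similarity) and
#'   `rejected_count` filled in.
#' @export
acq_measure <- function(session, counts, timestamps, gps = NULL) {
  require_step(session, "dark")
  require_step(session, "white")
  require_step(session, "signature")
  refl <- calibrate_stream(counts, session$dark$values, session$white$values)
  flt <- filter_stream(refl, session$signature,
                       filter_config(session$threshold))
  meta <- data.frame(timestamp = timestamps,
                     lon = NA_real_, lat = NA_real_, located = FALSE,
                     similarity = flt$similarity)
  if (!is.null(gps) && nrow(gps)) {
    ord <- order(gps$timestamp)
    gps <- gps[ord, , drop = FALSE]
    ## nearest fix via the sorted track: candidate below and above each frame
    lo <- findInterval(timestamps, gps$timestamp)
    lo_c <- pmax(lo, 1L)
    hi_c <- pmin(lo + 1L, nrow(gps))
    nearest <- ifelse(abs(gps$timestamp[lo_c] - timestamps) <=
                        abs(gps$timestamp[hi_c] - timestamps), lo_c, hi_c)
    dt <- abs(gps$timestamp[nearest] - timestamps)
    ok <- dt <= session$gps_tolerance
    meta$lon[ok] <- gps$lon[nearest[ok]]
    meta$lat[ok] <- gps$lat[nearest[ok]]
    meta$located <- ok
  }
  session$accepted <- refl[flt$accepted, , drop = FALSE]
  session$accepted_meta <- meta[flt$accepted, , drop = FALSE]
  session$rejected_count <- session$rejected_count + length(flt$rejected)
  session$n_frames <- session$n_frames + nrow(refl)
  session
}

#' Replay a full acquisition session
#'
#' Convenience wrapper running the state machine end to end on stored
#' inputs, optionally writing the per-step files the field software
#' produces (dark/white/signature spectra, accepted table, session log).
#'
#' @param counts frames-by-channels raw count matrix.
#' @param timestamps frame times, seconds.
#' @param dark,white raw reference [spectrum()]s.
#' @param signature leaf signature (reflectance, or raw to be calibrated).
#' @param threshold cosine threshold, default 0.985.
#' @param gps optional GPS track (`timestamp, lon, lat`).
#' @param out_dir optional output directory for the per-step files.
#' @return The completed `"acquisition_session"`.
#' @export
run_session <- function(counts, timestamps, dark, white, signature,
                        threshold = 0.985, gps = NULL, out_dir = NULL) {
  s <- acquisition_session(threshold)
  s <- acq_dark(s, dark)
  s <- acq_white(s, white)
  s <- acq_signature(s, signature)
  s <- acq_measure(s, counts, timestamps, gps)
  if (!is.null(out_dir)) write_session(s, out_dir)
  s
}

#' @export
print.acquisition_session <- function(x, ...) {
  cat(sprintf("<acquisition session: %d frames, %d accepted, %d rejected (threshold %.3f)>\n",
              x$n_frames, if (is.null(x$accepted)) 0L else nrow(x$accepted),
              x$rejected_count, x$threshold))
  invisible(x)
}

write_spectrum_file <- function(s, path) {
  tab <- data.frame(wavelength_nm = sprintf("%.2f", s$wavelengths),
                    value = format(s$values, digits = 6, trim = TRUE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_session <- function(session, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_spectrum_file(session$dark, file.path(out_dir, "dark.txt"))
  write_spectrum_file(session$white, file.path(out_dir, "white.txt"))
  write_spectrum_file(session$signature, file.path(out_dir, "signature.txt"))
  if (!is.null(session$accepted)) {
    tab <- cbind(session$accepted_meta[, c("timestamp", "lon", "lat")],
                 as.data.frame(session$accepted))
    names(tab) <- c("timestamp", "lon", "lat",
                    sprintf("%.2f", session$signature$wavelengths))
    utils::write.table(format(tab, digits = 6, trim = TRUE),
                       file.path(out_dir,
                                 sprintf("accepted_%s.txt",
                                         format(Sys.time(), "%Y%m%d_%H%M%S"))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log <- c(sprintf("threshold=%g", session$threshold),
           sprintf("n_frames=%d", session$n_frames),
           sprintf("n_accepted=%d",
                   if (is.null(session$accepted)) 0L else nrow(session$accepted)),
           sprintf("n_rejected=%d", session$rejected_count),
           sprintf("dark_top5=%g", session$log$dark_top5),
           sprintf("white_top5=%g", session$log$white_top5),
           sprintf("signature_top5=%g", session$log$signature_top5))
  writeLines(log, file.path(out_dir, "session_log.txt"))
  invisible(out_dir)
}
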