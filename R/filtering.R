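#' Cosine similarity between two spectra
#'
#' `dot(a, b) / (||a|| * ||b||)`, in `[-1, 1]`. Scale-invariant: positive
#' rescaling of either spectrum leaves the value unchanged, which is what
#' makes it usable on uncalibrated streams.
#'
#' @param a,b [spectrum()] objects or plain numeric vectors on the same
#'   wavelength grid.
#' @return A unitless similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (is_spectrum(a) && is_spectrum(b)) check_same_grid(a, b)
  va <- spec_values(a); vb <- spec_values(b)
  if (length(va) != length(vb)) stop("spectra differ in channel count")
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero spectrum")
  min(max(sum(va * vb) / (na * nb), -1), 1)
}

#' Filter configuration
#'
#' @param threshold cosine acceptance threshold in `(0, 1]`; the field
#'   deployments used 0.985. Frames with similarity exactly equal to the
#'   threshold are accepted.
#' @param method similarity method; only `"cosine"` is implemented.
#' @export
filter_config <- function(threshold = 0.985, method = "cosine") {
  method <- match.arg(method)
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  structure(list(method = method, threshold = threshold),
            class = "filter_config")
}

#' Screen a stream against the leaf spectral signature
#'
#' Accepts every frame whose cosine similarity to the signature is at least
#' the threshold; order is preserved and the boundary case (similarity
#' exactly equal to the threshold) is accepted.
#'
#' @param spectra a frames-by-channels matrix, or a list of [spectrum()]
#'   objects / numeric vectors.
#' @param signature the single-leaf reference spectrum.
#' @param cfg a [filter_config()].
#' @return list with integer index vectors `accepted` and `rejected`
#'   (partitioning the stream) and the per-frame `similarity`.
#' @export
filter_stream <- function(spectra, signature, cfg = filter_config()) {
  sig <- spec_values(signature)
  if (sqrt(sum(sig^2)) == 0) stop("signature must be a nonzero spectrum")
  mat <- stream_matrix(spectra)
  if (ncol(mat) != length(sig)) {
    stop("stream and signature differ in channel count")
  }
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0)) stop("stream contains a zero spectrum")
  sims <- as.numeric(mat %*% sig) / (norms * sqrt(sum(sig^2)))
  acc <- which(sims >= cfg$threshold)
  list(accepted = acc, rejected = setdiff(seq_len(nrow(mat)), acc),
       similarity = sims)
}

stream_matrix <- function(spectra) {
  if (is.matrix(spectra)) return(spectra)
  do.call(rbind, lapply(spectra, spec_values))
}

#' Allocate georeferenced frames to replication blocks
#'
#' Point-in-polygon assignment of accepted frames to the layout's blocks;
#' frames outside every block polygon are dropped (counted, not fatal).
#'
#' @param points data frame with `lon`, `lat` (one row per frame, in stream
#'   order).
#' @param layout a [field_layout()].
#' @return list of per-block assignments (`block_id`, `treatment`, integer
#'   `idx` into `points`) plus `n_outside`, the dropped-frame count.
#' @export
assign_blocks <- function(points, layout) {
  stopifnot(all(c("lon", "lat") %in% names(points)))
  taken <- rep(FALSE, nrow(points))
  out <- lapply(layout$blocks, function(blk) {
    inside <- point_in_polygon(points$lon, points$lat, blk$polygon) & !taken
    taken[inside] <<- TRUE
    list(block_id = blk$block_id, treatment = blk$treatment,
         idx = which(inside))
  })
  names(out) <- vapply(layout$blocks, `[[`, "", "block_id")
  list(blocks = out, n_outside = sum(!taken))
}

#' Average the accepted spectra of one block
#'
#' Channel-wise arithmetic mean; the number of averaged frames is kept as
#' metadata.
#'
#' @param spectra frames-by-channels matrix (or list coercible to one) of
#'   the block's accepted reflectance spectra.
#' @param wavelengths wavelength grid, nm.
#' @param block_id label used in error messages and metadata.
#' @return A reflectance [spectrum()] with `meta$n_averaged`.
#' @export
block_average <- function(spectra, wavelengths, block_id = "?") {
  mat <- stream_matrix(spectra)
  if (is.null(mat) || nrow(mat) == 0) {
    stop(sprintf("block %s has no accepted spectra to average", block_id))
  }
  spectrum(wavelengths, colMeans(mat), kind = "reflectance",
           meta = list(block_id = block_id, n_averaged = nrow(mat)))
}

#' Build calibration samples from filtered passes
#'
#' Replays the acquisition session for each pass (dark/white calibration,
#' signature screening against the cosine threshold, GPS pairing), then
#' allocates accepted frames to blocks and block-averages them; the
#' block-mean spectrum is paired with each of that block's marked-vine
#' potential references, giving (by default) 3 samples per block and date
#' — 36 samples per date on the 12-block layout.
#'
#' @param campaign a `"campaign"` from [simulate_campaign()].
#' @param layout a [field_layout()]; defaults to the campaign's.
#' @param cfg a [filter_config()].
#' @return A `"psi_samples"` object: `$spectra` (samples x channels
#'   reflectance matrix), `$wavelengths`, `$info` (psi_mpa, date, block_id,
#'   treatment, vine_group, lon, lat, n_averaged), and per-date filter
#'   counts in `$log`.
#' @export
build_samples <- function(campaign, layout = campaign$layout,
                          cfg = filter_config()) {
  rows <- list(); specs <- list(); log <- list()
  for (d in names(campaign$passes)) {
    pass <- campaign$passes[[d]]
    wl <- pass$sensor$wavelengths
    ses <- run_session(pass$spectra, pass$frames$timestamp,
                       pass$dark, pass$white, pass$signature,
                       threshold = cfg$threshold, gps = pass$gps)
    located <- ses$accepted_meta$located
    asg <- assign_blocks(ses$accepted_meta[located, c("lon", "lat")], layout)
    log[[d]] <- c(n_frames = ses$n_frames, n_accepted = nrow(ses$accepted),
                  n_rejected = ses$rejected_count,
                  n_outside = asg$n_outside)
    acc_idx <- which(located)
    for (blk in asg$blocks) {
      if (length(blk$idx) == 0) next
      avg <- block_average(ses$accepted[acc_idx[blk$idx], , drop = FALSE],
                           wl, blk$block_id)
      refs <- pass$references[pass$references$block_id == blk$block_id, ]
      for (r in seq_len(nrow(refs))) {
        rows[[length(rows) + 1L]] <- data.frame(
          psi_mpa = refs$psi_mpa[r], date = d,
          block_id = blk$block_id, treatment = blk$treatment,
          vine_group = refs$vine_group[r],
          lon = refs$lon[r], lat = refs$lat[r],
          n_averaged = avg$meta$n_averaged, stringsAsFactors = FALSE)
        specs[[length(specs) + 1L]] <- avg$values
      }
    }
  }
  psi_samples(do.call(rbind, specs),
              campaign$sensor$wavelengths,
              do.call(rbind, c(rows, list(make.row.names = FALSE))),
              log = do.call(rbind, log))
}

#' Calibration sample container
#'
#' @param spectra samples-by-channels reflectance matrix.
#' @param wavelengths channel wavelengths, nm.
#' @param info data frame with one row per sample; must contain `psi_mpa`
#'   (non-positive) and `date`.
#' @param log optional per-date filtering counts.
#' @export
psi_samples <- function(spectra, wavelengths, info, log = NULL) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) != nrow(info)) stop("spectra and info row counts differ")
  if (ncol(spectra) != length(wavelengths)) {
    stop("spectra and wavelength grid differ in channel count")
  }
  if (any(!is.finite(spectra))) stop("sample spectra must be finite")
  if (any(info$psi_mpa > 0)) stop("stem water potential must be <= 0 MPa")
  structure(list(spectra = spectra, wavelengths = wavelengths,
                 info = info, log = log),
            class = "psi_samples")
}

#' @export
print.psi_samples <- function(x, ...) {
  cat(sprintf("<psi samples: n=%d, %d channels, %d dates, psi %.2f..%.2f MPa>\n",
              nrow(x$spectra), ncol(x$spectra), length(unique(x$info$date)),
              min(x$info$psi_mpa), max(x$info$psi_mpa)))
  invisible(x)
}

#' @export
`[.psi_samples` <- function(x, i, ...) {
  psi_samples(x$spectra[i, , drop = FALSE], x$wavelengths,
              x$info[i, , drop = FALSE], log = x$log)
}

#' @export
dim.psi_samples <- function(x) dim(x$spectra)
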