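## Water-status mapping: thin-plate spline interpolation of point
## potentials over the plot, classification into at most five zones, and
## map-to-map agreement reporting.

tps_kernel <- function(r) ifelse(r > 0, r^2 * log(r), 0)

## Solve the bordered thin-plate system
##   [K + lambda*I  P] [w]   [v]
##   [P'            0] [a] = [0],  P = [1 x y]
## w are kernel weights, a the affine part. lambda = 0 gives exact
## interpolation; lambda > 0 trades fidelity for smoothness.
tps_solve <- function(x, y, v, lambda = 0) {
  n <- length(x)
  if (n < 3L) stop("thin-plate spline needs at least 3 points")
  K <- tps_kernel(sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2))
  P <- cbind(1, x, y)
  if (lambda == 0 && qr(P)$rank < 3L) {
    stop("points are collinear or duplicated: exact interpolation is singular; use smoothing > 0")
  }
  A <- rbind(cbind(K + diag(lambda, n), P),
             cbind(t(P), matrix(0, 3, 3)))
  sol <- tryCatch(solve(A, c(v, 0, 0, 0)),
                  error = function(e) stop(
                    "thin-plate system is singular (duplicate points?); use smoothing > 0"))
  list(w = sol[1:n], a = sol[n + 1:3], x = x, y = y)
}

tps_eval <- function(fitobj, gx, gy) {
  K <- tps_kernel(sqrt(outer(gx, fitobj$x, "-")^2 +
                         outer(gy, fitobj$y, "-")^2))
  drop(K %*% fitobj$w) + fitobj$a[1] + fitobj$a[2] * gx + fitobj$a[3] * gy
}

## minimum distance from points (px, py) to a polygon boundary
dist_to_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  d <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[j, 1]; by <- poly[j, 2]
    len2 <- (bx - ax)^2 + (by - ay)^2
    t <- if (len2 == 0) 0 else
      pmin(pmax(((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / len2, 0), 1)
    d <- pmin(d, sqrt((px - ax - t * (bx - ax))^2 +
                        (py - ay - t * (by - ay))^2))
  }
  d
}

#' Interpolate point potentials into a plot surface
#'
#' Fits a thin-plate spline (radial kernel `r^2 log r` plus an affine
#' part) through the point measurements or predictions and evaluates it on
#' a regular grid. With `smoothing = 0` the surface passes exactly through
#' every data point and reproduces constant and planar fields; positive
#' smoothing relaxes fidelity. Longitude/latitude inputs are projected to
#' a local metric plane before distances are computed. Grid cells farther
#' than `buffer` outside the convex hull of the points are masked.
#'
#' @param points data frame with `lon`, `lat` (or `x`, `y` in metres) and
#'   `psi_mpa`.
#' @param cell_size grid cell edge, m (default 2, below the 2.6 m row
#'   spacing).
#' @param smoothing ridge penalty `lambda >= 0` on the kernel weights.
#' @param buffer mask buffer outside the point hull, m (default one row
#'   spacing).
#' @param origin lon/lat projection origin; default, the centroid of the
#'   points.
#' @return A `"map_grid"`: `x`, `y` (cell centre coordinates, m), `values`
#'   (matrix, MPa; `NA` outside the mask), `mask`, `cell_size`, `origin`,
#'   and the input `points` (with projected coordinates).
#' @export
tps_interpolate <- function(points, cell_size = 2, smoothing = 0,
                            buffer = 2.6, origin = NULL) {
  stopifnot("psi_mpa" %in% names(points))
  if (all(c("lon", "lat") %in% names(points))) {
    if (is.null(origin)) origin <- c(mean(points$lon), mean(points$lat))
    xy <- lonlat_to_xy(points$lon, points$lat, origin)
  } else {
    stopifnot(all(c("x", "y") %in% names(points)))
    xy <- cbind(x = points$x, y = points$y)
    if (is.null(origin)) origin <- c(NA, NA)
  }
  fit <- tps_solve(xy[, 1], xy[, 2], points$psi_mpa, lambda = smoothing)
  gx <- seq(min(xy[, 1]) - buffer, max(xy[, 1]) + buffer, by = cell_size)
  gy <- seq(min(xy[, 2]) - buffer, max(xy[, 2]) + buffer, by = cell_size)
  gg <- expand.grid(x = gx, y = gy)
  hull <- grDevices::chull(xy)
  hull_poly <- xy[hull, , drop = FALSE]
  inside <- point_in_polygon(gg$x, gg$y, hull_poly)
  near <- dist_to_polygon(gg$x, gg$y, hull_poly) <= buffer
  mask <- matrix(inside | near, length(gx), length(gy))
  vals <- matrix(NA_real_, length(gx), length(gy))
  vals[mask] <- tps_eval(fit, gg$x[mask], gg$y[mask])
  structure(list(x = gx, y = gy, values = vals, mask = mask,
                 cell_size = cell_size, origin = origin,
                 points = cbind(as.data.frame(xy), psi_mpa = points$psi_mpa),
                 smoothing = smoothing,
                 class_breaks = NULL, class_id = NULL, labels = NULL),
            class = "map_grid")
}

#' @export
print.map_grid <- function(x, ...) {
  cat(sprintf("<map grid: %d x %d cells (%.1f m), %d in plot, psi %.2f..%.2f MPa%s>\n",
              length(x$x), length(x$y), x$cell_size, sum(x$mask),
              min(x$values[x$mask]), max(x$values[x$mask]),
              if (!is.null(x$class_id))
                sprintf(", %d classes", length(x$labels)) else ""))
  invisible(x)
}

#' Classify a water-status surface into irrigation zones
#'
#' At most five classes, to keep the map decision-ready. Breaks are
#' computed over unmasked cells by quantiles (near-equal cell counts) or
#' equal intervals; class 1 is the most negative (most stressed) zone and
#' labels are ordered accordingly.
#'
#' @param grid a [tps_interpolate()] result.
#' @param n_classes 1 to 5 zones.
#' @param scheme `"quantile"` or `"equal_interval"`.
#' @return The grid with `class_breaks` (internal break values, MPa,
#'   ascending), `class_id` (matrix) and `labels` filled in.
#' @export
classify_map <- function(grid, n_classes = 5,
                         scheme = c("quantile", "equal_interval")) {
  scheme <- match.arg(scheme)
  if (n_classes > 5) stop("no more than five classes are allowed")
  if (n_classes < 1) stop("need at least one class")
  v <- grid$values[grid$mask]
  if (length(v) < n_classes) stop("fewer unmasked cells than classes")
  breaks <- if (n_classes == 1) numeric(0) else if (scheme == "quantile") {
    unname(stats::quantile(v, probs = seq_len(n_classes - 1) / n_classes,
                           type = 7))
  } else {
    min(v) + diff(range(v)) * seq_len(n_classes - 1) / n_classes
  }
  ids <- matrix(NA_integer_, nrow(grid$values), ncol(grid$values))
  ids[grid$mask] <- findInterval(v, breaks, left.open = FALSE) + 1L
  edges <- c(min(v), breaks, max(v))
  grid$class_breaks <- breaks
  grid$class_id <- ids
  grid$labels <- sprintf("[%.2f, %.2f] MPa", utils::head(edges, -1),
                         utils::tail(edges, -1))
  grid$scheme <- scheme
  grid
}

#' Agreement between two water-status maps
#'
#' Cell-wise comparison of two grids on the same specification (e.g. the
#' map from model predictions against the map from the reference method):
#' Pearson correlation, root-mean-square difference in MPa, and — when
#' both are classified — the fraction of unmasked cells assigned the same
#' class.
#'
#' @param predicted,reference [tps_interpolate()] grids on identical
#'   specs.
#' @return list with `r`, `rmsd`, `class_agreement` (NA when either map
#'   is unclassified) and `n_cells`.
#' @export
compare_maps <- function(predicted, reference) {
  if (length(predicted$x) != length(reference$x) ||
      length(predicted$y) != length(reference$y) ||
      max(abs(predicted$x - reference$x)) > 1e-9 ||
      max(abs(predicted$y - reference$y)) > 1e-9) {
    stop("maps are not on the same grid specification")
  }
  both <- predicted$mask & reference$mask
  a <- predicted$values[both]; b <- reference$values[both]
  agree <- NA_real_
  if (!is.null(predicted$class_id) && !is.null(reference$class_id)) {
    agree <- mean(predicted$class_id[both] == reference$class_id[both])
  }
  list(r = if (stats::sd(a) > 0 && stats::sd(b) > 0) stats::cor(a, b)
       else NA_real_,
       rmsd = sqrt(mean((a - b)^2)),
       class_agreement = agree,
       n_cells = sum(both))
}

#' Export a map grid to GeoJSON
#'
#' Writes unmasked cells as square polygon features with `psi` and (when
#' classified) `class` / `label` properties. Cells are georeferenced via
#' the grid's projection origin; metric-only grids use raw x/y as
#' coordinates.
#'
#' @param grid a (classified) [tps_interpolate()] grid.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
map_to_geojson <- function(grid, path) {
  h <- grid$cell_size / 2
  feats <- list()
  georef <- !any(is.na(grid$origin))
  for (i in seq_along(grid$x)) {
    for (j in seq_along(grid$y)) {
      if (!grid$mask[i, j]) next
      cx <- grid$x[i]; cy <- grid$y[j]
      ring_xy <- cbind(c(cx - h, cx + h, cx + h, cx - h, cx - h),
                       c(cy - h, cy - h, cy + h, cy + h, cy - h))
      ring <- if (georef) {
        xy_to_lonlat(ring_xy[, 1], ring_xy[, 2], grid$origin)
      } else ring_xy
      props <- list(psi = grid$values[i, j])
      if (!is.null(grid$class_id)) {
        props$class <- grid$class_id[i, j]
        props$label <- grid$labels[grid$class_id[i, j]]
      }
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(ring)),
                          function(r) unname(ring[r, ])))),
        properties = props)
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Plot a water-status map
#'
#' @param x a [tps_interpolate()] grid, classified or not.
#' @param ... passed to [graphics::image()].
#' @export
plot.map_grid <- function(x, ...) {
  vals <- if (!is.null(x$class_id)) x$class_id else x$values
  graphics::image(x$x, x$y, vals, asp = 1, xlab = "x (m)", ylab = "y (m)",
                  col = grDevices::hcl.colors(
                    if (!is.null(x$class_id)) length(x$labels) else 25,
                    "Blue-Red", rev = TRUE), ...)
  graphics::points(x$points$x, x$points$y, pch = 3, cex = 0.6)
  invisible(x)
}
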