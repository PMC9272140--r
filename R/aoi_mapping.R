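# Window rectangles are (cx, cy, w, h) in degrees of visual angle, origin at
# screen centre. Rectangle membership is half-open: left and top edges
# inclusive, right and bottom exclusive, so every point gets at most one AOI.

in_rect <- function(x, y, rect) {
  x0 <- rect[1] - rect[3] / 2; x1 <- rect[1] + rect[3] / 2
  y0 <- rect[2] - rect[4] / 2; y1 <- rect[2] + rect[4] / 2
  !is.na(x) & !is.na(y) & x >= x0 & x < x1 & y > y0 & y <= y1
}

#' Assign fixation centroids to areas of interest
#'
#' Labels each centroid `"face"`, `"agr"` or `"off"` by point-in-rectangle
#' on the trial's two image windows. Boundaries are half-open (left/top edge
#' inclusive, right/bottom exclusive).
#'
#' @param x,y centroid coordinates (deg), vectorized.
#' @param layout one-row trial layout (see [simulate_session()] layouts)
#'   with disjoint `face_*` and `agr_*` window rectangles.
#' @return character vector over `{"face", "agr", "off"}`.
#' @export
assign_aoi <- function(x, y, layout) {
  face <- c(layout$face_cx, layout$face_cy, layout$face_w, layout$face_h)
  agr <- c(layout$agr_cx, layout$agr_cy, layout$agr_w, layout$agr_h)
  if (max(face[1] - face[3] / 2, agr[1] - agr[3] / 2) <
      min(face[1] + face[3] / 2, agr[1] + agr[3] / 2) &&
      max(face[2] - face[4] / 2, agr[2] - agr[4] / 2) <
      min(face[2] + face[4] / 2, agr[2] + agr[4] / 2))
    stop_("face and AGR windows overlap in trial %s", layout$trial)
  out <- rep("off", length(x))
  out[in_rect(x, y, face)] <- "face"
  out[in_rect(x, y, agr)] <- "agr"
  out
}

#' Facial region-of-interest map
#'
#' An ROI map ties named closed polygons (`forehead`, `eyes`, `nose`,
#' `mouth`) to a face image window; everything inside the window but outside
#' the named polygons is the implicit `"other"` region.
#'
#' @param window window rectangle `c(cx, cy, w, h)` (deg).
#' @param polygons named list of polygons, each a two-column matrix of
#'   vertices in window coordinates (closed implicitly).
#' @param image_id optional image identifier.
#' @return object of class `roi_map`.
#' @export
roi_map <- function(window, polygons, image_id = NA_character_) {
  stopifnot(length(window) == 4, window[3] > 0, window[4] > 0)
  allowed <- c("forehead", "eyes", "nose", "mouth")
  if (length(polygons) && !all(names(polygons) %in% allowed))
    stop_("polygon names must be among: %s", paste(allowed, collapse = ", "))
  x0 <- window[1] - window[3] / 2; x1 <- window[1] + window[3] / 2
  y0 <- window[2] - window[4] / 2; y1 <- window[2] + window[4] / 2
  for (nm in names(polygons)) {
    p <- polygons[[nm]]
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3)
      stop_("polygon '%s' must be a matrix with >= 3 vertices and 2 columns", nm)
    if (any(p[, 1] < x0 - 1e-9 | p[, 1] > x1 + 1e-9 |
            p[, 2] < y0 - 1e-9 | p[, 2] > y1 + 1e-9))
      stop_("polygon '%s' extends outside the window", nm)
  }
  structure(list(image_id = image_id, window = as.numeric(window),
                 polygons = polygons),
            class = "roi_map")
}

#' Default facial ROI map
#'
#' Rectangular forehead/eyes/nose/mouth regions laid out on the upper part
#' of the face window, scaled with the window. Forehead and eyes together
#' cover about 10.3% of the window area, mirroring the compact hand-drawn
#' ROIs of face images.
#'
#' @param window window rectangle `c(cx, cy, w, h)`.
#' @return an [roi_map()].
#' @export
default_roi_map <- function(window = c(0, 0, 8, 8)) {
  s <- window[3] / 8
  rect_poly <- function(x0, x1, y0, y1)
    cbind(window[1] + s * c(x0, x1, x1, x0),
          window[2] + s * c(y0, y0, y1, y1))
  roi_map(window, list(
    forehead = rect_poly(-1.5, 1.5, 1.6, 3.0),
    eyes = rect_poly(-1.5, 1.5, 0.6, 1.4),
    nose = rect_poly(-0.5, 0.5, -0.6, 0.4),
    mouth = rect_poly(-0.8, 0.8, -2.0, -1.4)))
}

# Point-in-polygon by even-odd ray casting; polygon boundaries are inclusive.
point_in_polygon <- function(px, py, poly) {
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    dx <- xs[j] - xs[i]; dy <- ys[j] - ys[i]
    cross <- (px - xs[i]) * dy - (py - ys[i]) * dx
    scale <- max(1, abs(dx) + abs(dy))
    if (abs(cross) < 1e-12 * scale) {
      dot <- (px - xs[i]) * dx + (py - ys[i]) * dy
      len2 <- dx * dx + dy * dy
      if (dot >= -1e-12 && dot <= len2 + 1e-12) return(TRUE)  # on boundary
    }
    if ((ys[i] > py) != (ys[j] > py)) {
      xint <- xs[i] + (py - ys[i]) * (xs[j] - xs[i]) / (ys[j] - ys[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Shoelace area; errors on self-intersecting rings.
polygon_area <- function(poly, check = TRUE) {
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- length(xs)
  if (check && n >= 4) {
    seg <- function(i) c(i, if (i == n) 1L else i + 1L)
    for (i in seq_len(n - 2)) {
      for (j in (i + 2):n) {
        if (i == 1 && j == n) next  # adjacent through closure
        a <- seg(i); b <- seg(j)
        if (segments_cross(poly[a[1], ], poly[a[2], ], poly[b[1], ], poly[b[2], ]))
          stop_("self-intersecting polygon (edges %d and %d cross)", i, j)
      }
    }
  }
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

# Proper segment intersection test (shared endpoints do not count).
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Assign a face-window centroid to a facial ROI
#'
#' Point-in-polygon tests run in fixed precedence order forehead, eyes,
#' nose, mouth (the first containing polygon wins; polygon boundaries are
#' inclusive); a point in no polygon is `"other"`.
#'
#' @param x,y centroid coordinates (deg); must lie inside the map's window.
#' @param map an [roi_map()].
#' @return one of `"forehead"`, `"eyes"`, `"nose"`, `"mouth"`, `"other"`.
#' @export
assign_roi <- function(x, y, map) {
  stopifnot(inherits(map, "roi_map"))
  w <- map$window
  if (!(x >= w[1] - w[3] / 2 && x < w[1] + w[3] / 2 &&
        y > w[2] - w[4] / 2 && y <= w[2] + w[4] / 2))
    stop_("centroid (%.3f, %.3f) is outside the ROI map window; assign AOI first", x, y)
  for (nm in c("forehead", "eyes", "nose", "mouth")) {
    p <- map$polygons[[nm]]
    if (!is.null(p) && point_in_polygon(x, y, p)) return(nm)
  }
  "other"
}

#' Fraction of the face window covered by each ROI
#'
#' Shoelace polygon areas over the window area; the named fractions plus the
#' residual `other` sum to 1.
#'
#' @param map an [roi_map()].
#' @return named numeric vector (`forehead`, `eyes`, `nose`, `mouth`,
#'   `other`) summing to 1.
#' @export
roi_area_fractions <- function(map) {
  stopifnot(inherits(map, "roi_map"))
  win_area <- map$window[3] * map$window[4]
  out <- c(forehead = 0, eyes = 0, nose = 0, mouth = 0)
  for (nm in names(map$polygons))
    out[nm] <- polygon_area(map$polygons[[nm]]) / win_area
  c(out, other = 1 - sum(out))
}

# Uniform landing point inside a named ROI ("other" = window minus polygons),
# by rejection sampling. Used by the synthetic generator.
sample_point_in_roi <- function(map, roi) {
  w <- map$window
  if (roi == "other") {
    repeat {
      px <- stats::runif(1, w[1] - w[3] / 2, w[1] + w[3] / 2)
      py <- stats::runif(1, w[2] - w[4] / 2, w[2] + w[4] / 2)
      hit <- FALSE
      for (p in map$polygons) if (point_in_polygon(px, py, p)) { hit <- TRUE; break }
      if (!hit) return(c(px, py))
    }
  }
  p <- map$polygons[[roi]]
  if (is.null(p)) stop_("ROI map has no polygon '%s'", roi)
  bx <- range(p[, 1]); by <- range(p[, 2])
  repeat {
    px <- stats::runif(1, bx[1], bx[2]); py <- stats::runif(1, by[1], by[2])
    if (point_in_polygon(px, py, p)) return(c(px, py))
  }
}

#' Build a gaze heat map
#'
#' Bins in-window gaze samples on an `n_bins` x `n_bins` grid. Raw counts
#' conserve the sample count exactly; optional Gaussian smoothing yields a
#' density normalized to sum 1.
#'
#' @param x,y sample coordinates (deg); all must lie within `window`
#'   (closed boundaries for binning purposes).
#' @param window window rectangle `c(cx, cy, w, h)`.
#' @param n_bins grid resolution per axis (default 50).
#' @param smoothing_sigma_bins Gaussian smoothing SD in bin units (default
#'   1; 0 skips smoothing and normalizes raw counts).
#' @return object of class `gaze_heatmap`: list with `counts` (integer
#'   matrix, rows = x bins), `density`, `x_edges`, `y_edges`.
#' @export
gaze_heatmap <- function(x, y, window, n_bins = 50, smoothing_sigma_bins = 1) {
  if (!is_scalar_number(n_bins) || n_bins < 1) stop_("n_bins must be >= 1")
  n_bins <- as.integer(n_bins)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  x0 <- window[1] - window[3] / 2; x1 <- window[1] + window[3] / 2
  y0 <- window[2] - window[4] / 2; y1 <- window[2] + window[4] / 2
  if (any(x < x0 | x > x1 | y < y0 | y > y1))
    stop_("gaze_heatmap: samples outside the window; filter to in-window first")
  xe <- seq(x0, x1, length.out = n_bins + 1L)
  ye <- seq(y0, y1, length.out = n_bins + 1L)
  ix <- pmin(findInterval(x, xe, rightmost.closed = TRUE), n_bins)
  iy <- pmin(findInterval(y, ye, rightmost.closed = TRUE), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  if (length(ix)) {
    tab <- table(factor(ix, levels = seq_len(n_bins)),
                 factor(iy, levels = seq_len(n_bins)))
    counts <- matrix(as.integer(tab), n_bins, n_bins)
  }
  density <- smooth_counts(counts, smoothing_sigma_bins)
  structure(list(counts = counts, density = density, x_edges = xe, y_edges = ye,
                 window = as.numeric(window)),
            class = "gaze_heatmap")
}

# Separable Gaussian smoothing (zero padding) followed by sum-1 normalization.
smooth_counts <- function(counts, sigma) {
  total <- sum(counts)
  if (total == 0) return(matrix(0, nrow(counts), ncol(counts)))
  if (sigma <= 0) return(counts / total)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (s in -r:r) {
      idx <- seq_len(n) + s
      ok <- idx >= 1 & idx <= n
      out[ok] <- out[ok] + k[s + r + 1] * v[idx[ok]]
    }
    out
  }
  sm <- apply(counts, 2, conv1)
  sm <- t(apply(sm, 1, conv1))
  sm / sum(sm)
}

#' @export
print.gaze_heatmap <- function(x, ...) {
  cat(sprintf("<gaze_heatmap> %dx%d bins, %d samples\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
plot.gaze_heatmap <- function(x, ...) {
  graphics::image(x$x_edges, x$y_edges, x$density, useRaster = TRUE,
                  xlab = "x (deg)", ylab = "y (deg)", ...)
  invisible(x)
}
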