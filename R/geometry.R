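#' Blade area of a leaf contour
#'
#' Area enclosed by the contour polygon (shoelace rule on the vertex cycle).
#' The result is independent of traversal orientation and of which vertex
#' the outline starts at.
#'
#' @param contour a [leaf_contour()].
#' @return area in cm^2.
#' @export
polygon_area <- function(contour) {
  stopifnot_contour(contour)
  abs(signed_area(contour$vertices))
}

#' Leaf length along the base-apex axis
#'
#' Euclidean distance from the petiole attachment vertex to the apex vertex.
#'
#' @param contour a [leaf_contour()].
#' @return length in cm.
#' @export
leaf_length <- function(contour) {
  stopifnot_contour(contour)
  b <- contour$vertices[contour$base_index, ]
  a <- contour$vertices[contour$apex_index, ]
  L <- sqrt(sum((a - b)^2))
  if (L <= 1e-12)
    stop("base and apex coincide: leaf axis is degenerate", call. = FALSE)
  L
}

#' Maximum leaf width perpendicular to the base-apex axis
#'
#' The width is the longest chord perpendicular to the line connecting the
#' leaf base and apex. The contour is translated and rotated so the axis
#' lies on +x; the polygon's vertical extent (maximum minus minimum boundary
#' crossing, with edges linearly interpolated) is then evaluated on a grid
#' of `n_stations` equally spaced axis positions united with every vertex
#' position, and the maximum extent is returned. Including the vertex
#' stations means piecewise-linear maxima (e.g. a triangle's base edge) are
#' hit exactly; the uniform grid guarantees resolution between vertices of
#' coarse outlines.
#'
#' @param contour a [leaf_contour()].
#' @param n_stations number of equally spaced evaluation positions (>= 2).
#' @return width in cm.
#' @export
leaf_width <- function(contour, n_stations = 2001L) {
  stopifnot_contour(contour)
  if (n_stations < 2L) stop("`n_stations` must be >= 2", call. = FALSE)
  v <- contour$vertices
  b <- v[contour$base_index, ]
  a <- v[contour$apex_index, ]
  L <- sqrt(sum((a - b)^2))
  if (L <= 1e-12)
    stop("base and apex coincide: leaf axis is degenerate", call. = FALSE)
  co <- (a[1L] - b[1L]) / L
  si <- (a[2L] - b[2L]) / L
  px <- (v[, 1L] - b[1L]) * co + (v[, 2L] - b[2L]) * si
  py <- -(v[, 1L] - b[1L]) * si + (v[, 2L] - b[2L]) * co

  stations <- sort(unique(c(seq(min(px), max(px), length.out = n_stations), px)))
  ymax <- rep(-Inf, length(stations))
  ymin <- rep(Inf, length(stations))

  n <- length(px)
  nxt <- c(2:n, 1L)
  qx <- px[nxt]; qy <- py[nxt]
  for (e in seq_len(n)) {
    x1 <- px[e]; x2 <- qx[e]; y1 <- py[e]; y2 <- qy[e]
    if (x1 == x2) {
      k <- findInterval(x1, stations)
      if (k >= 1L && stations[k] == x1) {
        ymax[k] <- max(ymax[k], y1, y2)
        ymin[k] <- min(ymin[k], y1, y2)
      }
      next
    }
    lo <- min(x1, x2); hi <- max(x1, x2)
    k1 <- findInterval(lo, stations)
    if (k1 < 1L || stations[k1] < lo) k1 <- k1 + 1L
    k2 <- findInterval(hi, stations)
    if (k2 < k1) next
    idx <- k1:k2
    yy <- y1 + (stations[idx] - x1) * (y2 - y1) / (x2 - x1)
    ymax[idx] <- pmax(ymax[idx], yy)
    ymin[idx] <- pmin(ymin[idx], yy)
  }
  ext <- ymax - ymin
  ext <- ext[is.finite(ext)]
  max(ext, 0)
}

#' Measure one leaf
#'
#' Computes the four leaf variables used throughout the package: length `L`
#' (base-apex distance, cm), maximum perpendicular width `W` (cm), blade
#' area `LS` (cm^2) and the width-to-length ratio `RWL = W / L`.
#'
#' @param contour a [leaf_contour()].
#' @param n_stations grid resolution passed to [leaf_width()].
#' @return one-row data frame with columns `leaf_id`, `progeny_id`,
#'   `hybridization`, `L_cm`, `W_cm`, `LS_cm2`, `RWL`.
#' @export
#' @examples
#' tri <- leaf_contour(rbind(c(0, 0), c(0, -2), c(8, 0), c(0, 2)), 1, 3)
#' measure_leaf(tri)  # L = 8, W = 4, LS = 16, RWL = 0.5
measure_leaf <- function(contour, n_stations = 2001L) {
  stopifnot_contour(contour)
  L <- leaf_length(contour)
  W <- leaf_width(contour, n_stations = n_stations)
  LS <- polygon_area(contour)
  data.frame(leaf_id = contour$leaf_id, progeny_id = contour$progeny_id,
             hybridization = contour$hybridization,
             L_cm = L, W_cm = W, LS_cm2 = LS, RWL = W / L,
             stringsAsFactors = FALSE)
}

#' Measure a list of leaves
#'
#' @param contours list of [leaf_contour()] objects.
#' @param n_stations grid resolution passed to [leaf_width()].
#' @return data frame with one row per leaf (see [measure_leaf()]).
#' @export
measure_leaves <- function(contours, n_stations = 2001L) {
  if (length(contours) == 0L)
    stop("no contours to measure", call. = FALSE)
  do.call(rbind, lapply(contours, measure_leaf, n_stations = n_stations))
}

#' Convert scanner pixels to centimetres
#'
#' @param value length in pixels.
#' @param dpi scan resolution in dots per inch (> 0).
#' @return length in cm (`value * 2.54 / dpi`).
#' @export
#' @examples
#' pixels_to_cm(300, 300)  # 2.54
pixels_to_cm <- function(value, dpi) {
  if (!is.numeric(dpi) || length(dpi) != 1L || !is.finite(dpi) || dpi <= 0)
    stop("`dpi` must be a positive number", call. = FALSE)
  value * 2.54 / dpi
}
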