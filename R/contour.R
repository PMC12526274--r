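#' Leaf contour objects
#'
#' A `leaf_contour` stores one digitized leaf outline as an ordered, simple
#' (non-self-intersecting) planar polygon in centimetres, together with the
#' indices of the two anatomical anchor vertices: the petiole attachment
#' point (base) and the leaf tip (apex). All morphometric measurements
#' (length, width, blade area) are defined relative to the base-apex axis.
#'
#' @param vertices two-column numeric matrix (x, y) in cm; at least 3 rows.
#'   The polygon is closed implicitly (last vertex connects to the first).
#' @param base_index,apex_index 1-based indices of the base and apex vertices.
#' @param leaf_id,progeny_id character labels carried through the pipeline.
#' @param hybridization one of `"IntraH"`, `"InterH"`, `"unknown"`.
#' @param check_simple if `TRUE`, verify that the polygon has no
#'   self-intersections (pairwise segment test with x-interval pruning).
#'
#' @return an object of class `leaf_contour`: a list with elements
#'   `vertices`, `base_index`, `apex_index`, `leaf_id`, `progeny_id`,
#'   `hybridization`. Vertex order is normalized to counterclockwise.
#' @export
#' @examples
#' tri <- leaf_contour(rbind(c(0, 0), c(0, -2), c(8, 0), c(0, 2)),
#'                     base_index = 1, apex_index = 3)
#' polygon_area(tri)
leaf_contour <- function(vertices, base_index, apex_index,
                         leaf_id = "leaf", progeny_id = NA_character_,
                         hybridization = c("unknown", "IntraH", "InterH"),
                         check_simple = TRUE) {
  hybridization <- match.arg(hybridization)
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L)
    stop("`vertices` must be a numeric matrix with two columns (x, y)",
         call. = FALSE)
  n <- nrow(vertices)
  if (n < 3L) stop("a leaf contour needs at least 3 vertices", call. = FALSE)
  if (anyNA(vertices) || any(!is.finite(vertices)))
    stop("contour vertices must be finite", call. = FALSE)
  base_index <- as.integer(base_index)
  apex_index <- as.integer(apex_index)
  if (base_index < 1L || base_index > n || apex_index < 1L || apex_index > n)
    stop("base/apex indices out of range", call. = FALSE)
  if (base_index == apex_index)
    stop("base and apex must be distinct vertices", call. = FALSE)

  # normalize orientation to counterclockwise so all downstream measures are
  # invariant to how the outline was traced
  if (signed_area(vertices) < 0) {
    idx <- rev(seq_len(n))
    vertices <- vertices[idx, , drop = FALSE]
    base_index <- n + 1L - base_index
    apex_index <- n + 1L - apex_index
  }

  if (check_simple && !is_simple_polygon(vertices))
    stop("contour polygon is self-intersecting (degenerate geometry)",
         call. = FALSE)

  structure(
    list(vertices = unname(vertices), base_index = base_index,
         apex_index = apex_index, leaf_id = as.character(leaf_id),
         progeny_id = as.character(progeny_id), hybridization = hybridization),
    class = "leaf_contour")
}

#' @export
print.leaf_contour <- function(x, ...) {
  cat(sprintf("<leaf_contour> %s (progeny %s, %s): %d vertices\n",
              x$leaf_id, x$progeny_id, x$hybridization, nrow(x$vertices)))
  invisible(x)
}

#' @export
plot.leaf_contour <- function(x, ...) {
  v <- rbind(x$vertices, x$vertices[1L, ])
  graphics::plot(v, type = "l", asp = 1, xlab = "x (cm)", ylab = "y (cm)", ...)
  graphics::points(x$vertices[c(x$base_index, x$apex_index), , drop = FALSE],
                   pch = c(16, 17))
  invisible(x)
}

# signed shoelace area; > 0 for counterclockwise traversal
signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# Simplicity test: every pair of non-adjacent edges must not intersect.
# Edges are pruned by sorted x-interval overlap, so leaf-like outlines
# (few edges stacked over any axis position) test in near-linear time.
is_simple_polygon <- function(v, tol = 1e-12) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  x1 <- v[, 1L]; y1 <- v[, 2L]
  nxt <- c(2:n, 1L)
  x2 <- x1[nxt]; y2 <- y1[nxt]
  # degenerate zero-length edges collapse the adjacency logic
  if (any((x1 - x2)^2 + (y1 - y2)^2 < tol^2)) return(FALSE)
  exmin <- pmin(x1, x2); exmax <- pmax(x1, x2)
  eymin <- pmin(y1, y2); eymax <- pmax(y1, y2)
  ord <- order(exmin)
  for (ii in seq_len(n - 1L)) {
    i <- ord[ii]
    jj <- ii + 1L
    while (jj <= n && exmin[ord[jj]] <= exmax[i] + tol) {
      j <- ord[jj]
      jj <- jj + 1L
      # skip the cyclically adjacent edges (they share one endpoint)
      d <- abs(i - j)
      if (d == 1L || d == n - 1L) next
      if (eymin[j] > eymax[i] + tol || eymax[j] < eymin[i] - tol) next
      if (segments_intersect(x1[i], y1[i], x2[i], y2[i],
                             x1[j], y1[j], x2[j], y2[j], tol)) return(FALSE)
    }
  }
  TRUE
}

# robust segment intersection (closed segments) via orientation tests
segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy, tol = 1e-12) {
  o1 <- orient(ax, ay, bx, by, cx, cy, tol)
  o2 <- orient(ax, ay, bx, by, dx, dy, tol)
  o3 <- orient(cx, cy, dx, dy, ax, ay, tol)
  o4 <- orient(cx, cy, dx, dy, bx, by, tol)
  if (o1 != o2 && o3 != o4) return(TRUE)
  # collinear / touching cases
  (o1 == 0L && on_segment(ax, ay, bx, by, cx, cy, tol)) ||
  (o2 == 0L && on_segment(ax, ay, bx, by, dx, dy, tol)) ||
  (o3 == 0L && on_segment(cx, cy, dx, dy, ax, ay, tol)) ||
  (o4 == 0L && on_segment(cx, cy, dx, dy, bx, by, tol))
}

orient <- function(ax, ay, bx, by, px, py, tol) {
  cr <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  scale <- max(abs(bx - ax), abs(by - ay), abs(px - ax), abs(py - ay), 1)
  if (abs(cr) <= tol * scale) 0L else if (cr > 0) 1L else -1L
}

on_segment <- function(ax, ay, bx, by, px, py, tol) {
  px >= min(ax, bx) - tol && px <= max(ax, bx) + tol &&
  py >= min(ay, by) - tol && py <= max(ay, by) + tol
}

stopifnot_contour <- function(contour) {
  if (!inherits(contour, "leaf_contour"))
    stop("expected a `leaf_contour` object", call. = FALSE)
  contour
}
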