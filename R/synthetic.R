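#' Shape specification for synthetic leaves
#'
#' Describes a leaf outline family with analytically known Montgomery
#' proportionality constant. Supported families:
#' \describe{
#'   \item{ellipse}{axis-aligned ellipse; true alpha = pi/4.}
#'   \item{triangle}{isoceles triangle, base edge perpendicular to the axis;
#'     true alpha = 1/2.}
#'   \item{rectangle}{the bounding rectangle itself; true alpha = 1.}
#'   \item{beta_profile}{mirrored half-width profile
#'     f(t) = (W/2) g(t) / max(g) with g(t) = t^a (1-t)^b along the relative
#'     axis position t in [0, 1]. Ovate when a < b, obovate when a > b.
#'     True alpha is the Beta-function ratio B(a+1, b+1) / max(g), which
#'     equals 2/3 at a = b = 1 — the classical ovate-leaf value.}
#' }
#'
#' @param family one of `"ellipse"`, `"triangle"`, `"rectangle"`,
#'   `"beta_profile"`.
#' @param a,b beta-profile exponents (> 0; required for `beta_profile`).
#' @param rwl target width-to-length ratio in (0, 1.5].
#' @return object of class `shape_spec`.
#' @export
shape_spec <- function(family = c("ellipse", "triangle", "rectangle",
                                  "beta_profile"),
                       a = 1, b = 1, rwl = 0.4) {
  family <- match.arg(family)
  if (!is.numeric(rwl) || length(rwl) != 1L || rwl <= 0 || rwl > 1.5)
    stop("`rwl` must lie in (0, 1.5]", call. = FALSE)
  if (family == "beta_profile" && (a <= 0 || b <= 0))
    stop("beta_profile requires a > 0 and b > 0", call. = FALSE)
  structure(list(family = family, a = a, b = b, rwl = rwl),
            class = "shape_spec")
}

#' True Montgomery constant of a shape specification
#'
#' The exact ratio of blade area to the bounding rectangle L*W for a
#' noiseless leaf of the given family: pi/4 for the ellipse, 1/2 for the
#' triangle, 1 for the rectangle, and the closed-form Beta-function ratio
#' \eqn{B(a+1, b+1) / (t^{*a} (1-t^*)^b)} with \eqn{t^* = a/(a+b)} for the
#' beta profile.
#'
#' @param shape a [shape_spec()].
#' @return the dimensionless proportionality constant.
#' @export
#' @examples
#' true_alpha(shape_spec("ellipse"))                  # pi/4
#' true_alpha(shape_spec("beta_profile", a = 1, b = 1))  # 2/3
true_alpha <- function(shape) {
  if (!inherits(shape, "shape_spec"))
    stop("expected a `shape_spec`", call. = FALSE)
  switch(shape$family,
         ellipse = pi / 4,
         triangle = 0.5,
         rectangle = 1,
         beta_profile = {
           a <- shape$a; b <- shape$b
           tstar <- a / (a + b)
           gmax <- tstar^a * (1 - tstar)^b
           beta(a + 1, b + 1) / gmax
         })
}

#' Elliptical leaf contour
#'
#' Polygon inscribed in the ellipse with major axis L on the base-apex line
#' (base at the origin, apex at (L, 0)) and minor axis W. Vertices are
#' placed at equal parameter angles so the inscribed-polygon area converges
#' to pi*L*W/4 at rate 1/n^2; the base and apex are always vertices.
#'
#' @param L,W major/minor axis lengths in cm (> 0).
#' @param n_vertices number of polygon vertices (>= 16).
#' @inheritParams leaf_contour
#' @return a [leaf_contour()].
#' @export
make_ellipse_leaf <- function(L, W, n_vertices = 256L, leaf_id = "ellipse",
                              progeny_id = NA_character_,
                              hybridization = "unknown") {
  check_dims(L, W)
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 16L) stop("`n_vertices` must be >= 16", call. = FALSE)
  m <- n_vertices %/% 2L + 1L             # upper arc, base..apex inclusive
  th_up <- seq(pi, 0, length.out = m)
  th_lo <- seq(0, pi, length.out = n_vertices - m + 2L)[-c(1L, n_vertices - m + 2L)]
  th <- c(th_up, -th_lo)
  v <- cbind(L / 2 + (L / 2) * cos(th), (W / 2) * sin(th))
  v[1L, ] <- c(0, 0); v[m, ] <- c(L, 0)   # pin anchors exactly
  leaf_contour(v, base_index = 1L, apex_index = m, leaf_id = leaf_id,
               progeny_id = progeny_id, hybridization = hybridization,
               check_simple = FALSE)
}

#' Triangular leaf contour
#'
#' Isoceles triangle with base edge of length W perpendicular to the axis
#' at the base point (origin) and apex at (L, 0). The base point itself is
#' kept as a (collinear) vertex so length is measured from the petiole
#' attachment, not a corner.
#'
#' @inheritParams make_ellipse_leaf
#' @return a [leaf_contour()].
#' @export
make_triangle_leaf <- function(L, W, leaf_id = "triangle",
                               progeny_id = NA_character_,
                               hybridization = "unknown") {
  check_dims(L, W)
  v <- rbind(c(0, 0), c(0, -W / 2), c(L, 0), c(0, W / 2))
  leaf_contour(v, base_index = 1L, apex_index = 3L, leaf_id = leaf_id,
               progeny_id = progeny_id, hybridization = hybridization,
               check_simple = FALSE)
}

#' Rectangular leaf contour
#'
#' The bounding rectangle itself (true alpha = 1), with base and apex at the
#' midpoints of the short sides.
#'
#' @inheritParams make_ellipse_leaf
#' @return a [leaf_contour()].
#' @export
make_rectangle_leaf <- function(L, W, leaf_id = "rectangle",
                                progeny_id = NA_character_,
                                hybridization = "unknown") {
  check_dims(L, W)
  v <- rbind(c(0, 0), c(0, -W / 2), c(L, -W / 2), c(L, 0),
             c(L, W / 2), c(0, W / 2))
  leaf_contour(v, base_index = 1L, apex_index = 4L, leaf_id = leaf_id,
               progeny_id = progeny_id, hybridization = hybridization,
               check_simple = FALSE)
}

#' Beta-profile leaf contour
#'
#' Mirrored half-width profile f(t) = (W/2) g(t)/max(g), g(t) = t^a (1-t)^b,
#' along axis position t in [0, 1]. The widest station sits at
#' t* = a/(a+b): ovate outlines for a < b, obovate for a > b, symmetric for
#' a = b. Both profile ends close at zero width, so the polygon is a simple
#' closed curve with base (0, 0) and apex (L, 0) as vertices.
#'
#' @inheritParams make_ellipse_leaf
#' @param a,b profile exponents (> 0).
#' @return a [leaf_contour()].
#' @export
make_beta_leaf <- function(L, W, a = 1, b = 1, n_vertices = 256L,
                           leaf_id = "beta", progeny_id = NA_character_,
                           hybridization = "unknown") {
  check_dims(L, W)
  if (!is.numeric(a) || !is.numeric(b) || a <= 0 || b <= 0)
    stop("beta profile requires a > 0 and b > 0 (profile must close at both ends)",
         call. = FALSE)
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 16L) stop("`n_vertices` must be >= 16", call. = FALSE)
  tstar <- a / (a + b)
  gmax <- tstar^a * (1 - tstar)^b
  m <- n_vertices %/% 2L + 1L
  t_up <- seq(0, 1, length.out = m)
  t_lo <- seq(1, 0, length.out = n_vertices - m + 2L)[-c(1L, n_vertices - m + 2L)]
  f <- function(t) (W / 2) * (t^a * (1 - t)^b) / gmax
  v <- rbind(cbind(L * t_up, f(t_up)), cbind(L * t_lo, -f(t_lo)))
  v[1L, ] <- c(0, 0); v[m, ] <- c(L, 0)
  leaf_contour(v, base_index = 1L, apex_index = m, leaf_id = leaf_id,
               progeny_id = progeny_id, hybridization = hybridization,
               check_simple = FALSE)
}

check_dims <- function(L, W) {
  if (!is.numeric(L) || !is.numeric(W) || length(L) != 1L || length(W) != 1L ||
      !is.finite(L) || !is.finite(W) || L <= 0 || W <= 0)
    stop("leaf dimensions L and W must be positive numbers", call. = FALSE)
}

#' Progeny specification for synthetic sampling
#'
#' Defines one simulated progeny: a shape family shared by all its leaves,
#' the number of leaves, the length range sampled, and the noise structure.
#' Defaults emulate a field collection of 228 leaves per progeny spanning
#' the mesophyll size range of coffee.
#'
#' @param progeny_id label.
#' @param hybridization `"IntraH"`, `"InterH"` or `"unknown"`.
#' @param n_leaves leaves to generate (>= 1; default 228).
#' @param shape a [shape_spec()].
#' @param length_range (min, max) leaf length in cm, 0 < min < max.
#' @param noise_sd contour jitter standard deviation as a fraction of the
#'   leaf width, applied along the local outward normal (0 = noiseless).
#' @param rwl_sd lognormal spread of the per-leaf width-to-length ratio
#'   around `shape$rwl`; 0 (default) gives exact geometric self-similarity,
#'   positive values decouple W from L as real shape variation does.
#' @param n_vertices vertices per contour.
#' @param seed integer root seed; per-leaf streams are derived from it by
#'   counter offset so generation order does not matter.
#' @return object of class `progeny_spec`.
#' @export
progeny_spec <- function(progeny_id, hybridization = "unknown",
                         n_leaves = 228L, shape = shape_spec("beta_profile"),
                         length_range = c(5, 17), noise_sd = 0, rwl_sd = 0,
                         n_vertices = 256L, seed = 1L) {
  if (!inherits(shape, "shape_spec")) stop("`shape` must be a shape_spec",
                                           call. = FALSE)
  n_leaves <- as.integer(n_leaves)
  if (n_leaves < 1L) stop("`n_leaves` must be >= 1", call. = FALSE)
  if (length(length_range) != 2L || any(length_range <= 0) ||
      length_range[1L] >= length_range[2L])
    stop("`length_range` must be positive and ordered (min < max)",
         call. = FALSE)
  if (noise_sd < 0 || rwl_sd < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  structure(list(progeny_id = as.character(progeny_id),
                 hybridization = hybridization, n_leaves = n_leaves,
                 shape = shape, length_range = as.numeric(length_range),
                 noise_sd = noise_sd, rwl_sd = rwl_sd,
                 n_vertices = as.integer(n_vertices),
                 seed = as.integer(seed)),
            class = "progeny_spec")
}

# deterministic per-leaf seed stream: linear-congruential mix of the root
# seed and the leaf counter, kept inside 32-bit integer range
leaf_stream_seed <- function(root, i) {
  as.integer((1103515245 * ((as.numeric(root) + 7919 * i) %% 65521) + 12345) %%
               2147483647)
}

#' Sample a synthetic progeny
#'
#' Generates `n_leaves` contours. Each leaf draws its length uniformly from
#' `length_range`; its width is `rwl * L` (exact geometric self-similarity)
#' unless `rwl_sd > 0`, in which case the per-leaf ratio varies
#' lognormally. Vertex jitter of standard deviation `noise_sd * W` is
#' applied along the local outward normal (base and apex anchors are left
#' untouched), truncated and, if necessary, shrunk so the polygon stays
#' simple. Identical specs (including the seed) give identical output.
#'
#' @param spec a [progeny_spec()].
#' @return list of [leaf_contour()] objects.
#' @export
sample_progeny <- function(spec) {
  if (!inherits(spec, "progeny_spec"))
    stop("expected a `progeny_spec`", call. = FALSE)
  lapply(seq_len(spec$n_leaves), function(i) {
    set.seed(leaf_stream_seed(spec$seed, i))
    L <- stats::runif(1L, spec$length_range[1L], spec$length_range[2L])
    rwl <- spec$shape$rwl
    if (spec$rwl_sd > 0)
      rwl <- rwl * exp(stats::rnorm(1L, 0, spec$rwl_sd))
    W <- rwl * L
    id <- sprintf("%s_%04d", spec$progeny_id, i)
    leaf <- switch(spec$shape$family,
      ellipse = make_ellipse_leaf(L, W, spec$n_vertices, id,
                                  spec$progeny_id, spec$hybridization),
      triangle = make_triangle_leaf(L, W, id, spec$progeny_id,
                                    spec$hybridization),
      rectangle = make_rectangle_leaf(L, W, id, spec$progeny_id,
                                      spec$hybridization),
      beta_profile = make_beta_leaf(L, W, spec$shape$a, spec$shape$b,
                                    spec$n_vertices, id, spec$progeny_id,
                                    spec$hybridization))
    if (spec$noise_sd > 0) leaf <- jitter_contour(leaf, spec$noise_sd * W)
    leaf
  })
}

# Gaussian jitter along local outward normals. Displacements are truncated
# at 3 sd and at 45% of the shorter adjacent edge, then the whole jitter is
# halved (up to 6 times) if the perturbed polygon self-intersects, so the
# output always stays a simple polygon.
jitter_contour <- function(contour, sd_abs) {
  v <- contour$vertices
  n <- nrow(v)
  prv <- c(n, seq_len(n - 1L))
  nxt <- c(2:n, 1L)
  d1 <- v - v[prv, , drop = FALSE]
  d2 <- v[nxt, , drop = FALSE] - v
  len1 <- sqrt(rowSums(d1^2)); len2 <- sqrt(rowSums(d2^2))
  tang <- d1 / pmax(len1, 1e-300) + d2 / pmax(len2, 1e-300)
  tlen <- sqrt(rowSums(tang^2))
  tang <- tang / pmax(tlen, 1e-300)
  normal <- cbind(tang[, 2L], -tang[, 1L])   # outward for CCW traversal
  cap <- pmin(3 * sd_abs, 0.45 * pmin(len1, len2))
  eps <- stats::rnorm(n, 0, sd_abs)
  eps <- pmin(pmax(eps, -cap), cap)
  eps[c(contour$base_index, contour$apex_index)] <- 0
  for (attempt in 0:6) {
    w <- v + (eps / 2^attempt) * normal
    if (is_simple_polygon(w)) {
      contour$vertices <- w
      return(contour)
    }
  }
  contour   # give up on jitter rather than emit a degenerate polygon
}
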