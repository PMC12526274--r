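unit_square <- function(clockwise = FALSE) {
  v <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  if (clockwise) v <- v[c(1L, 4L, 3L, 2L), ]
  leaf_contour(v, base_index = 1L, apex_index = 3L)
}

rigid_motion <- function(contour, theta, shift) {
  R <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  contour$vertices <- sweep(contour$vertices %*% t(R), 2L, -shift)
  contour
}

test_that("polygon area is exact on squares and orientation-invariant", {
  expect_identical(polygon_area(unit_square()), 1)
  expect_identical(polygon_area(unit_square(clockwise = TRUE)), 1)
  # cyclic start-vertex invariance
  v <- rbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_identical(polygon_area(leaf_contour(v, 4L, 2L)), 1)
})

test_that("regular polygon areas match the closed form (n/2) sin(2 pi/n)", {
  for (n in c(360L, 3600L)) {
    th <- 2 * pi * (seq_len(n) - 1L) / n
    ngon <- leaf_contour(cbind(cos(th), sin(th)), 1L, n %/% 2L + 1L,
                         check_simple = FALSE)
    expect_equal(polygon_area(ngon), n / 2 * sin(2 * pi / n),
                 tolerance = 1e-12)
  }
  th <- 2 * pi * (0:3599) / 3600
  ngon <- leaf_contour(cbind(cos(th), sin(th)), 1L, 1801L,
                       check_simple = FALSE)
  expect_equal(polygon_area(ngon), pi, tolerance = 1e-4)
})

test_that("leaf length is the base-apex distance", {
  tri <- make_triangle_leaf(10, 2)
  expect_identical(leaf_length(tri), 10)
  v <- rbind(c(0, 0), c(3, -1), c(3, 4), c(0, 2))
  expect_identical(leaf_length(leaf_contour(v, 1L, 3L)), 5)
})

test_that("leaf width hits piecewise-linear maxima exactly", {
  tri <- leaf_contour(rbind(c(0, 0), c(0, -2), c(8, 0), c(0, 2)), 1L, 3L)
  expect_equal(leaf_width(tri), 4, tolerance = 1e-12)
  e <- make_ellipse_leaf(10, 4, 1024)
  expect_equal(leaf_width(e), 4, tolerance = 1e-3 / 4)
})

test_that("L, W and LS are invariant under rigid motions", {
  set.seed(42)
  base <- make_beta_leaf(12, 5, 1, 1.4, 128)
  m0 <- measure_leaf(base)
  for (r in 1:5) {
    moved <- rigid_motion(base, stats::runif(1, 0, 2 * pi),
                          stats::rnorm(2, 0, 20))
    m1 <- measure_leaf(moved)
    expect_equal(m1$L_cm, m0$L_cm, tolerance = 1e-9)
    expect_equal(m1$W_cm, m0$W_cm, tolerance = 1e-9)
    expect_equal(m1$LS_cm2, m0$LS_cm2, tolerance = 1e-9)
  }
})

test_that("measurements are scale-equivariant", {
  base <- make_beta_leaf(12, 5, 1.2, 1.8, 128)
  m0 <- measure_leaf(base)
  s <- 2.7
  scaled <- base
  scaled$vertices <- base$vertices * s
  m1 <- measure_leaf(scaled)
  expect_equal(m1$L_cm, s * m0$L_cm, tolerance = 1e-12)
  expect_equal(m1$W_cm, s * m0$W_cm, tolerance = 1e-9)
  expect_equal(m1$LS_cm2, s^2 * m0$LS_cm2, tolerance = 1e-12)
  expect_equal(m1$RWL, m0$RWL, tolerance = 1e-9)
})

test_that("blade area never exceeds the bounding rectangle L * W", {
  set.seed(7)
  for (r in 1:10) {
    sh <- shape_spec("beta_profile", stats::runif(1, 0.5, 3),
                     stats::runif(1, 0.5, 3), rwl = stats::runif(1, 0.2, 0.6))
    sp <- progeny_spec("B", n_leaves = 1, shape = sh, noise_sd = 0.01,
                       n_vertices = 128, seed = r)
    m <- measure_leaves(sample_progeny(sp))
    expect_lte(m$LS_cm2, m$L_cm * m$W_cm * (1 + 1e-9))
  }
})

test_that("width converges in the station grid resolution", {
  lf <- make_beta_leaf(11, 4.5, 1, 1.3, 256)
  w1 <- leaf_width(lf, n_stations = 2001L)
  w2 <- leaf_width(lf, n_stations = 4001L)
  expect_equal(w2, w1, tolerance = 1e-6)
})

test_that("degenerate geometry is rejected", {
  expect_error(leaf_contour(rbind(c(0, 0), c(1, 0)), 1L, 2L), "3 vertices")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(leaf_contour(bowtie, 1L, 3L), "self-intersecting")
  sq <- unit_square()
  expect_error(leaf_contour(sq$vertices, 2L, 2L), "distinct")
  degen <- leaf_contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 0) + 1e-15),
                        1L, 2L, check_simple = FALSE)
  degen$base_index <- 1L; degen$apex_index <- 4L
  expect_error(leaf_length(degen), "degenerate")
})

test_that("pixel-to-cm conversion follows the scan resolution", {
  expect_identical(pixels_to_cm(300, 300), 2.54)
  expect_identical(pixels_to_cm(0, 300), 0)
  expect_identical(pixels_to_cm(150, 300), 1.27)
  expect_error(pixels_to_cm(10, 0), "positive")
})
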