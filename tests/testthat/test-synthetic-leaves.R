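test_that("ellipse leaves reproduce the analytic area, width and ratio", {
  e <- make_ellipse_leaf(10, 4, 4096)
  expect_equal(polygon_area(e), pi * 5 * 2, tolerance = 1e-3 / (pi * 10))
  expect_equal(leaf_width(e), 4, tolerance = 1e-3 / 4)
  m <- measure_leaf(e)
  expect_equal(m$LS_cm2 / (m$L_cm * m$W_cm), pi / 4, tolerance = 1e-3)
})

test_that("triangle leaves are exact", {
  t1 <- make_triangle_leaf(8, 4)
  expect_identical(polygon_area(t1), 16)
  m <- measure_leaf(t1)
  expect_identical(m$LS_cm2 / (m$L_cm * m$W_cm), 0.5)
  expect_identical(measure_leaf(make_triangle_leaf(1, 1))$RWL, 1)
})

test_that("beta-profile leaves have the widest station at a/(a+b)", {
  b <- make_beta_leaf(10, 4, 1, 1, 4096)
  widest <- b$vertices[which.max(abs(b$vertices[, 2L])), 1L] / 10
  expect_equal(widest, 0.5, tolerance = 1e-3)
  ov <- make_beta_leaf(10, 4, 1, 2, 4096)
  widest_ov <- ov$vertices[which.max(abs(ov$vertices[, 2L])), 1L] / 10
  expect_equal(widest_ov, 1 / 3, tolerance = 1e-3)
})

test_that("true_alpha matches the quadrature oracle for beta profiles", {
  expect_equal(true_alpha(shape_spec("beta_profile", 1, 1)), 2 / 3,
               tolerance = 1e-6)
  for (ab in list(c(1, 1), c(1, 2), c(2, 2), c(0.8, 1.6), c(3, 1.2))) {
    expect_equal(true_alpha(shape_spec("beta_profile", ab[1L], ab[2L])),
                 quad_alpha(ab[1L], ab[2L]), tolerance = 1e-9)
  }
  expect_identical(true_alpha(shape_spec("ellipse")), pi / 4)
  expect_identical(true_alpha(shape_spec("triangle")), 0.5)
  expect_identical(true_alpha(shape_spec("rectangle")), 1)
})

test_that("a measured beta leaf recovers its analytic Montgomery ratio", {
  m <- measure_leaf(make_beta_leaf(10, 4, 2, 2, 4096))
  expect_equal(m$LS_cm2 / (m$L_cm * m$W_cm), quad_alpha(2, 2),
               tolerance = 1e-3)
})

test_that("sample_progeny is bitwise deterministic given the seed", {
  sp <- progeny_spec("P7", "IntraH", n_leaves = 5,
                     shape = shape_spec("ellipse", rwl = 0.4),
                     noise_sd = 0.01, rwl_sd = 0.02, seed = 7)
  expect_identical(sample_progeny(sp), sample_progeny(sp))
})

test_that("noiseless leaves of every family match true alpha to 1e-3", {
  shapes <- list(shape_spec("ellipse", rwl = 0.35),
                 shape_spec("triangle", rwl = 0.5),
                 shape_spec("rectangle", rwl = 0.3),
                 shape_spec("beta_profile", 1, 1.5, rwl = 0.4))
  for (sh in shapes) {
    sp <- progeny_spec("Q", n_leaves = 4, shape = sh, noise_sd = 0,
                       n_vertices = 2048, seed = 3)
    m <- measure_leaves(sample_progeny(sp))
    ratio <- m$LS_cm2 / (m$L_cm * m$W_cm)
    expect_true(all(abs(ratio - true_alpha(sh)) < 1e-3),
                info = sh$family)
  }
})

test_that("noiseless self-similar progenies scale as LS proportional to L^2", {
  sp <- progeny_spec("S", n_leaves = 40,
                     shape = shape_spec("beta_profile", 1, 1.3, rwl = 0.42),
                     noise_sd = 0, n_vertices = 512, seed = 11)
  m <- measure_leaves(sample_progeny(sp))
  fit <- stats::lm(log(LS_cm2) ~ log(L_cm), data = m)
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.999999)
  expect_equal(unname(stats::coef(fit)[2L]), 2, tolerance = 1e-3)
})

test_that("contour jitter perturbs vertices but keeps polygons simple", {
  sp <- progeny_spec("N", n_leaves = 10,
                     shape = shape_spec("beta_profile", 1, 1.2, rwl = 0.4),
                     noise_sd = 0.02, n_vertices = 128, seed = 5)
  leaves <- sample_progeny(sp)
  sp0 <- sp; sp0$noise_sd <- 0
  clean <- sample_progeny(sp0)
  moved <- mapply(function(a, b) max(abs(a$vertices - b$vertices)),
                  leaves, clean)
  expect_true(all(moved > 0))
  # constructor validation re-run proves simplicity
  for (lf in leaves)
    expect_silent(leaf_contour(lf$vertices, lf$base_index, lf$apex_index))
})

test_that("invalid generator arguments are rejected", {
  expect_error(make_ellipse_leaf(-1, 4), "positive")
  expect_error(make_ellipse_leaf(10, 4, n_vertices = 8), ">= 16")
  expect_error(make_triangle_leaf(0, 1), "positive")
  expect_error(make_beta_leaf(10, 4, a = 0, b = 1), "a > 0")
  expect_error(shape_spec("beta_profile", a = -1), "a > 0")
  expect_error(shape_spec("ellipse", rwl = 0), "rwl")
  expect_error(progeny_spec("X", length_range = c(5, 5)), "ordered")
  expect_error(progeny_spec("X", n_leaves = 0), "n_leaves")
})
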