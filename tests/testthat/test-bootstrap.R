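exact_m1_data <- function(n = 30, alpha = 0.67) {
  L <- seq(5, 15, length.out = n)
  data.frame(L_cm = L, W_cm = 0.4 * L, LS_cm2 = alpha * 0.4 * L^2)
}

test_that("zero-residual data give a zero-width interval at the truth", {
  ci <- bootstrap_ci(exact_m1_data(), "M1_alpha",
                     bootstrap_config(B = 200, seed = 4))
  expect_equal(ci$low, 0.67, tolerance = 1e-12)
  expect_equal(ci$high, 0.67, tolerance = 1e-12)
})

test_that("intervals are reproducible under a fixed seed", {
  set.seed(99)
  d <- sim_m1_measurements(60)
  cfg <- bootstrap_config(B = 300, seed = 11)
  a <- bootstrap_ci(d, "M1_alpha", cfg)
  b <- bootstrap_ci(d, "M1_alpha", cfg)
  expect_identical(a, b)
  cb <- bootstrap_ci(d, "M2_beta", cfg)
  cb2 <- bootstrap_ci(d, "M2_beta", cfg)
  expect_identical(cb, cb2)
})

test_that("interval endpoints are monotone in the confidence level", {
  set.seed(5)
  d <- sim_m1_measurements(80)
  levels <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  cis <- lapply(levels, function(lv)
    bootstrap_ci(d, "M1_alpha", bootstrap_config(B = 400, level = lv,
                                                 seed = 2)))
  for (i in seq_len(length(levels) - 1L)) {
    expect_lte(cis[[i + 1L]]$low, cis[[i]]$low + 1e-12)
    expect_gte(cis[[i + 1L]]$high, cis[[i]]$high - 1e-12)
  }
})

test_that("bootstrapped M2 intervals cover the generating exponent", {
  set.seed(6)
  L <- stats::runif(80, 5, 17)
  d <- data.frame(L_cm = L, W_cm = 0.4 * L,
                  LS_cm2 = 0.27 * L^2 + stats::rnorm(80, 0, 0.8))
  ci <- bootstrap_ci(d, "M2_beta", bootstrap_config(B = 200, seed = 8))
  expect_lt(ci$low, 2.05)
  expect_gt(ci$high, 1.95)
  expect_false(ci$unstable)
})

test_that("reference decisions use closed-interval containment", {
  above <- test_reference(c(0.670, 0.680), 2 / 3, "H4")
  expect_true(above$supported)
  expect_identical(above$direction, "above")
  inside <- test_reference(c(0.660, 0.670), 2 / 3, "H4")
  expect_false(inside$supported)
  expect_identical(inside$direction, "contains")
  boundary <- test_reference(c(2 / 3, 0.670), 2 / 3, "H4")
  expect_false(boundary$supported)
  below <- test_reference(c(0.650, 0.656), 2 / 3, "H4")
  expect_identical(below$direction, "below")
  expect_true(below$supported)
})

test_that("published interval endpoints reproduce the decision directions", {
  # progeny CI endpoints read as data: one interval above and one below the
  # ovate reference 2/3, both excluding it
  p4 <- test_reference(c(0.68267, 0.68910), 2 / 3, "H4")
  expect_true(p4$supported)
  expect_identical(p4$direction, "above")
  p10 <- test_reference(c(0.65010, 0.65602), 2 / 3, "H4")
  expect_true(p10$supported)
  expect_identical(p10$direction, "below")
  # the same intervals exclude the species extremes from both sides
  expect_identical(test_reference(c(0.68267, 0.68910), 0.64340)$direction,
                   "above")
  expect_identical(test_reference(c(0.68267, 0.68910), 0.70125)$direction,
                   "below")
})

test_that("group-vs-pooled difference test behaves on constructed data", {
  d <- exact_m1_data(50)
  cfg <- bootstrap_config(B = 200, seed = 3)
  same <- test_vs_pooled(d, d, cfg)
  expect_false(same$supported)
  expect_identical(same$direction, "contains")

  # group alpha 0.69 embedded in pooled data of alpha 0.66: delta > 0
  hi <- exact_m1_data(200, alpha = 0.69)
  lo <- exact_m1_data(200, alpha = 0.66)
  pooled <- rbind(hi, lo)
  dec <- test_vs_pooled(hi, pooled, cfg)
  expect_true(dec$supported)
  expect_identical(dec$direction, "above")
  expect_lt(dec$p_value, 0.05)

  dec2 <- test_vs_pooled(hi, pooled, cfg)
  expect_identical(dec, dec2)
})

test_that("bootstrap preconditions are enforced", {
  expect_error(bootstrap_config(B = 1), ">= 2")
  expect_error(bootstrap_config(level = 1), "0, 1")
  expect_error(bootstrap_ci(exact_m1_data(1), "M1_alpha"), "at least 2")
  expect_error(test_vs_pooled(exact_m1_data(10), exact_m1_data(5)),
               "at least as large")
})
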