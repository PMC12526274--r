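test_that("ellipticity index rescales alpha with the ellipse at 1", {
  expect_identical(ellipticity_index(pi / 4), 1)
  alphas <- seq(0.4, 0.8, by = 0.05)
  expect_true(all(diff(ellipticity_index(alphas)) > 0))
  expect_error(ellipticity_index(0), "positive")
})

test_that("Hotelling's T2 vanishes for identical samples and matches the
           univariate t in one dimension", {
  X <- matrix(stats::rnorm(45, 3), ncol = 3)
  same <- hotelling_t2(X, X)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  set.seed(12)
  for (r in 1:4) {
    a <- matrix(stats::rnorm(20), ncol = 1)
    b <- matrix(stats::rnorm(25, 0.5), ncol = 1)
    t2 <- hotelling_t2(a, b)
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(t2$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(t2$p_value, tt$p.value, tolerance = 1e-9)
  }
})

test_that("Hotelling's T2 detects a large mean shift and is affine
           invariant", {
  set.seed(13)
  a <- matrix(stats::rnorm(90), ncol = 3)
  b <- matrix(stats::rnorm(90), ncol = 3)
  b[, 1L] <- b[, 1L] + 3
  shifted <- hotelling_t2(a, b)
  expect_lt(shifted$p_value, 0.001)

  A <- matrix(c(2, 0.5, -1, 1, 3, 0, 0.2, -0.7, 1.5), 3L)
  shift <- c(10, -5, 2)
  ta <- sweep(a %*% A, 2L, -shift)
  tb <- sweep(b %*% A, 2L, -shift)
  trans <- hotelling_t2(ta, tb)
  expect_equal(trans$statistic, shifted$statistic, tolerance = 1e-6)
})

test_that("Mardia's tests separate gaussian from skewed data", {
  set.seed(14)
  gauss <- matrix(stats::rnorm(3 * 2000), ncol = 3)
  mg <- mardia_test(gauss)
  expect_gt(mg$skewness$p_value, 0.01)
  expect_gt(mg$kurtosis$p_value, 0.01)

  skewed <- matrix(stats::rexp(3 * 500), ncol = 3)
  ms <- mardia_test(skewed)
  expect_lt(ms$skewness$p_value, 0.01)

  expect_error(mardia_test(matrix(stats::rnorm(6), ncol = 3)),
               "more observations")
})

test_that("Box's M distinguishes equal from unequal covariances", {
  set.seed(15)
  a <- matrix(stats::rnorm(400), ncol = 2)
  b <- matrix(stats::rnorm(400), ncol = 2)
  expect_gt(box_m(list(a, b))$p_value, 0.01)
  expect_lt(box_m(list(a, 3 * b))$p_value, 0.01)
  expect_error(box_m(list(a)), "at least two")
})

test_that("PAM recovers the obvious 1-D partition with its exact cost", {
  r <- pam_cluster(matrix(c(0, 1, 10, 11)), k = 2, scale = FALSE)
  expect_identical(unname(r$labels), c(1L, 1L, 2L, 2L))
  expect_equal(r$total_cost, 2, tolerance = 1e-12)
  expect_true(r$silhouette_defined)
  expect_gt(r$silhouette, 0.8)
})

test_that("PAM with k = n has zero cost and an undefined silhouette", {
  X <- matrix(stats::rnorm(10), ncol = 2)
  r <- pam_cluster(X, k = 5, scale = FALSE)
  expect_equal(r$total_cost, 0, tolerance = 1e-12)
  expect_false(r$silhouette_defined)
  expect_identical(r$silhouette, 0)
  expect_error(pam_cluster(X, k = 6), "1 <= k <= n")
})

test_that("PAM swap descent is monotone and reaches the brute-force
           optimum on small instances", {
  set.seed(16)
  for (r in 1:8) {
    n <- sample(5:8, 1L)
    k <- sample(2:3, 1L)
    X <- matrix(stats::rnorm(2 * n), ncol = 2)
    fit <- pam_cluster(X, k, scale = FALSE)
    expect_true(all(diff(fit$cost_trace) <= 1e-12))
    expect_equal(fit$total_cost, brute_force_pam_cost(X, k),
                 tolerance = 1e-9)
  }
})

test_that("PAM agrees with the reference implementation", {
  skip_if_not_installed("cluster")
  set.seed(17)
  for (r in 1:5) {
    X <- matrix(stats::rnorm(40), ncol = 2)
    ours <- pam_cluster(X, 3, scale = FALSE)
    ref <- cluster::pam(X, 3)
    ref_cost <- sum(apply(as.matrix(stats::dist(X))[, ref$id.med,
                                                    drop = FALSE], 1L, min))
    expect_equal(ours$total_cost, ref_cost, tolerance = 1e-9)
  }
})

test_that("select_k finds well-separated blob counts and breaks ties low", {
  set.seed(18)
  two <- rbind(matrix(stats::rnorm(60, 0, 0.3), ncol = 2),
               matrix(stats::rnorm(60, 5, 0.3), ncol = 2))
  expect_identical(select_k(two, 2:5, gap_B = 20, seed = 1), 2L)
  three <- rbind(matrix(stats::rnorm(40, 0, 0.3), ncol = 2),
                 matrix(stats::rnorm(40, 6, 0.3), ncol = 2),
                 cbind(stats::rnorm(20, 3, 0.3), stats::rnorm(20, 6, 0.3)))
  expect_identical(select_k(three, 2:5, gap_B = 20, seed = 1), 3L)
  flat <- matrix(1, nrow = 10, ncol = 2)
  expect_identical(select_k(flat, 2:4), 2L)
})

test_that("cluster stability separates real structure from noise", {
  set.seed(20)
  blobs <- rbind(matrix(stats::rnorm(50, 0, 0.4), ncol = 2),
                 matrix(stats::rnorm(50, 8, 0.4), ncol = 2))
  stab <- cluster_stability(blobs, 2, B = 100, seed = 2)
  expect_true(all(stab > 0.9))

  noise <- matrix(stats::runif(100), ncol = 2)
  stab_noise <- cluster_stability(noise, 2, B = 100, seed = 2)
  expect_lt(mean(stab_noise), mean(stab))

  tiny <- cluster_stability(blobs, 2, B = 2, seed = 5)
  tiny2 <- cluster_stability(blobs, 2, B = 2, seed = 5)
  expect_identical(tiny, tiny2)
})

test_that("chi-squared homogeneity matches the hand-computed Pearson
           formula", {
  flat <- chi2_homogeneity(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$statistic, 0, tolerance = 1e-12)
  expect_equal(flat$p_value, 1, tolerance = 1e-12)

  tab <- rbind(c(20, 18), c(6, 11))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  res <- chi2_homogeneity(tab)
  expect_equal(res$statistic, stat, tolerance = 1e-12)
  expect_gt(res$p_value, 0.05)

  expect_error(chi2_homogeneity(rbind(c(0, 0), c(3, 4))), "zero margin")
  expect_error(chi2_homogeneity(rbind(c(1.5, 2), c(3, 4))), "integers")
})

test_that("Spearman correlations with Bonferroni adjustment", {
  x <- 1:20
  d <- data.frame(a = x, b = x^3, c = -x)
  res <- spearman_bonferroni(d)
  expect_equal(res$gamma[res$var1 == "a" & res$var2 == "b"], 1,
               tolerance = 1e-12)
  expect_equal(res$gamma[res$var1 == "a" & res$var2 == "c"], -1,
               tolerance = 1e-12)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15, na.rm = TRUE))
  expect_true(all(res$p_adjusted <= 1, na.rm = TRUE))

  const <- data.frame(a = x, b = rep(1, 20))
  resc <- spearman_bonferroni(const)
  expect_true(is.na(resc$gamma))

  # null calibration: large rank correlations are rare for independent data
  set.seed(21)
  extreme <- 0L
  for (s in 1:300) {
    u <- stats::runif(55); v <- stats::runif(55)
    if (abs(stats::cor(u, v, method = "spearman")) > 0.5)
      extreme <- extreme + 1L
  }
  expect_lt(extreme / 300, 0.01)
})

test_that("PCA projection handles exact low-rank and full-rank data", {
  x <- seq(1, 10, length.out = 25)
  line <- cbind(x, 2 * x + 3, -x)
  pl <- pca_project(line, 2)
  expect_equal(pl$explained[1L], 1, tolerance = 1e-9)

  set.seed(22)
  iso <- matrix(stats::rnorm(3 * 3000), ncol = 3)
  pi3 <- pca_project(iso, 3)
  expect_equal(sum(pi3$explained), 1, tolerance = 1e-9)
  expect_true(all(abs(pi3$explained - 1 / 3) < 0.05))
})
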