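# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths so each comparison is a genuine cross-check.

# Montgomery constant of a beta half-width profile by adaptive quadrature
quad_alpha <- function(a, b) {
  tstar <- a / (a + b)
  gmax <- tstar^a * (1 - tstar)^b
  stats::integrate(function(t) t^a * (1 - t)^b, 0, 1,
                   rel.tol = 1e-12)$value / gmax
}

# refined grid search for the slope of a through-the-origin regression;
# after bracketing, the vertex of the parabola through the three lowest
# grid points pins the SSE minimizer (the SSE is exactly quadratic in a)
grid_search_alpha <- function(lw, ls, lo = 0, hi = 2, rounds = 2L) {
  sse <- function(a) sum((ls - a * lw)^2)
  for (r in seq_len(rounds)) {
    grid <- seq(lo, hi, length.out = 401L)
    vals <- vapply(grid, sse, 0)
    i <- min(max(which.min(vals), 2L), length(grid) - 1L)
    lo <- grid[i - 1L]
    hi <- grid[i + 1L]
  }
  h <- (hi - lo) / 2
  mid <- lo + h
  mid - h * (sse(hi) - sse(lo)) / (2 * (sse(hi) - 2 * sse(mid) + sse(lo)))
}

# exhaustive PAM oracle: best medoid set over all combinations
brute_force_pam_cost <- function(X, k) {
  D <- as.matrix(stats::dist(X))
  sets <- utils::combn(nrow(X), k)
  min(apply(sets, 2L, function(m)
    sum(apply(D[, m, drop = FALSE], 1L, min))))
}

# simulated Montgomery measurement table: LW from self-similar leaves,
# additive gaussian blade-area error
sim_m1_measurements <- function(n, alpha = 0.67, sigma = 1.8, rwl = 0.4,
                                length_range = c(5, 17)) {
  L <- stats::runif(n, length_range[1L], length_range[2L])
  W <- rwl * L
  data.frame(L_cm = L, W_cm = W,
             LS_cm2 = alpha * L * W + stats::rnorm(n, 0, sigma))
}

# per-progeny feature vectors (mean LS, mean RWL, EI) for two shape regimes
two_regime_features <- function(n_per = 12L,
                                alpha_means = c(0.660, 0.685),
                                rwl_means = c(0.38, 0.42),
                                ls_means = c(30, 33)) {
  make_regime <- function(g) {
    alpha <- stats::rnorm(n_per, alpha_means[g], 0.004)
    cbind(mean_LS = stats::rnorm(n_per, ls_means[g], 2),
          mean_RWL = stats::rnorm(n_per, rwl_means[g], 0.008),
          EI = 4 * alpha / pi)
  }
  X <- rbind(make_regime(1L), make_regime(2L))
  rownames(X) <- sprintf("P%02d", seq_len(2L * n_per))
  list(features = X, truth = rep(1:2, each = n_per))
}

# best label agreement between a clustering and the known partition
label_agreement <- function(labels, truth) {
  max(mean(labels == truth), mean((3L - labels) == truth))
}
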