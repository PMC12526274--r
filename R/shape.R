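#' Ellipticity index
#'
#' `EI = 4 * alpha / pi` rescales the Montgomery constant so an ideal
#' ellipse scores exactly 1; triangular outlines score 2/pi (~0.64). It
#' quantifies how far a leaf's blade area falls from that of the ellipse
#' inscribed in the same bounding rectangle, without needing the perimeter.
#' Note it cannot distinguish ovate from obovate outlines.
#'
#' @param alpha Montgomery proportionality constant(s), > 0.
#' @return ellipticity index, same length as `alpha`.
#' @export
#' @examples
#' ellipticity_index(pi / 4)  # 1
ellipticity_index <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha <= 0))
    stop("`alpha` must be positive", call. = FALSE)
  4 * alpha / pi
}

test_result <- function(statistic, df, p_value, method = "") {
  structure(list(statistic = unname(statistic), df = df,
                 p_value = unname(min(max(p_value, 0), 1)), method = method),
            class = "foliometry_test")
}

#' @export
print.foliometry_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.5f, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(unlist(x$df), collapse = ", "), x$p_value))
  invisible(x)
}

as_data_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("data matrix contains missing values", call. = FALSE)
  X
}

#' Two-sample Hotelling's T-squared test
#'
#' Tests equality of two multivariate mean vectors under a common
#' covariance: `T2 = (nA*nB/(nA+nB)) * d' S^-1 d` with `d` the mean
#' difference and `S` the pooled covariance, converted to an exact F
#' statistic with `(p, nA + nB - p - 1)` degrees of freedom.
#'
#' @param groupA,groupB numeric matrices (rows = observations, columns =
#'   the p variables).
#' @return a test result with elements `statistic` (T2), `df`, `p_value`
#'   and `F`.
#' @export
hotelling_t2 <- function(groupA, groupB) {
  A <- as_data_matrix(groupA); B <- as_data_matrix(groupB)
  if (ncol(A) != ncol(B)) stop("dimension mismatch", call. = FALSE)
  p <- ncol(A); nA <- nrow(A); nB <- nrow(B)
  if (nA + nB - 2L <= p)
    stop("too few observations for the dimension (need nA + nB - 2 > p)",
         call. = FALSE)
  d <- colMeans(A) - colMeans(B)
  S <- ((nA - 1) * stats::cov(A) + (nB - 1) * stats::cov(B)) / (nA + nB - 2)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("pooled covariance is singular", call. = FALSE))
  T2 <- (nA * nB / (nA + nB)) * drop(t(d) %*% Sinv %*% d)
  Fstat <- T2 * (nA + nB - p - 1) / (p * (nA + nB - 2))
  pv <- stats::pf(Fstat, p, nA + nB - p - 1, lower.tail = FALSE)
  out <- test_result(T2, list(p = p, df2 = nA + nB - p - 1), pv,
                     "Hotelling's T2")
  out$F <- Fstat
  out
}

#' Mardia's multivariate normality tests
#'
#' Computes Mardia's multivariate skewness `b1p` and kurtosis `b2p` with
#' their asymptotic references: `n * b1p / 6` against chi-squared with
#' `p(p+1)(p+2)/6` df, and the standardized kurtosis against N(0, 1)
#' (two-sided). The scatter matrix uses the maximum-likelihood divisor `n`.
#'
#' @param X numeric matrix of observations (n > p).
#' @return list with components `skewness` and `kurtosis`, each a test
#'   result.
#' @export
mardia_test <- function(X) {
  X <- as_data_matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than variables", call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X))
  S <- crossprod(Xc) / n
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("covariance matrix is singular", call. = FALSE))
  Y <- Xc %*% Sinv
  # b1p = mean over all ordered pairs of (x_i' S^-1 x_j)^3, computed in row
  # blocks to keep memory at O(block * n)
  b1 <- 0
  block <- max(1L, min(n, 512L))
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    M <- Y[s:e, , drop = FALSE] %*% t(Xc)
    b1 <- b1 + sum(M^3)
  }
  b1 <- b1 / n^2
  d2 <- rowSums(Y * Xc)
  b2 <- mean(d2^2)

  skew_stat <- n * b1 / 6
  skew_df <- p * (p + 1) * (p + 2) / 6
  skew_p <- stats::pchisq(skew_stat, skew_df, lower.tail = FALSE)
  kurt_z <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  kurt_p <- 2 * stats::pnorm(abs(kurt_z), lower.tail = FALSE)
  list(skewness = test_result(skew_stat, list(chisq_df = skew_df), skew_p,
                              "Mardia skewness"),
       kurtosis = test_result(kurt_z, list(reference = "N(0,1)"), kurt_p,
                              "Mardia kurtosis"))
}

#' Box's M test of covariance homogeneity
#'
#' Chi-squared approximation of Box's M statistic for equality of the
#' group covariance matrices.
#'
#' @param groups list of at least two numeric matrices with the same
#'   number of columns; each group needs more rows than columns.
#' @return a test result.
#' @export
box_m <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("`groups` must be a list of at least two samples", call. = FALSE)
  groups <- lapply(groups, as_data_matrix)
  p <- ncol(groups[[1L]])
  if (any(vapply(groups, ncol, 1L) != p))
    stop("all groups must share the same variables", call. = FALSE)
  ns <- vapply(groups, nrow, 1L)
  if (any(ns <= p))
    stop("each group needs more observations than variables", call. = FALSE)
  g <- length(groups)
  N <- sum(ns)
  covs <- lapply(groups, stats::cov)
  Sp <- Reduce(`+`, Map(function(S, n) (n - 1) * S, covs, ns)) / (N - g)
  lds <- vapply(covs, function(S) {
    d <- determinant(S, logarithm = TRUE)
    if (d$sign <= 0) stop("a group covariance is singular", call. = FALSE)
    as.numeric(d$modulus)
  }, 0)
  dp <- determinant(Sp, logarithm = TRUE)
  if (dp$sign <= 0) stop("pooled covariance is singular", call. = FALSE)
  M <- (N - g) * as.numeric(dp$modulus) - sum((ns - 1) * lds)
  c1 <- (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1)) *
        (sum(1 / (ns - 1)) - 1 / (N - g))
  stat <- M * (1 - c1)
  df <- p * (p + 1) * (g - 1) / 2
  test_result(stat, list(chisq_df = df),
              stats::pchisq(stat, df, lower.tail = FALSE), "Box's M")
}

#' Partitioning around medoids
#'
#' Deterministic PAM on Euclidean dissimilarities: the BUILD phase greedily
#' seeds `k` medoids, the SWAP phase applies steepest-descent medoid swaps
#' until no swap lowers the total dissimilarity to the nearest medoid. All
#' ties break toward the lowest index, so results are reproducible without
#' randomness. The mean silhouette width of the final partition is
#' attached (reported as 0, flagged undefined, when k = 1 or k = n).
#'
#' @param X numeric matrix or data frame (rows = objects).
#' @param k number of clusters, 1 <= k <= n.
#' @param scale standardize columns to zero mean / unit variance first
#'   (recommended when variables are on incommensurate scales).
#' @return object of class `cluster_report`: `k`, `labels` (cluster id per
#'   row, named from rownames), `medoids` (row indices), `medoid_ids`
#'   (rownames when present), `total_cost`, `silhouette`,
#'   `silhouette_defined`, `cost_trace` (total cost after BUILD and after
#'   each accepted swap; non-increasing), `stability` (`NULL` until
#'   [cluster_stability()] fills it).
#' @export
#' @examples
#' pam_cluster(matrix(c(0, 1, 10, 11)), k = 2, scale = FALSE)$total_cost  # 2
pam_cluster <- function(X, k, scale = TRUE) {
  X <- as_data_matrix(X)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("`k` must satisfy 1 <= k <= n", call. = FALSE)
  if (scale) X <- scale_columns(X)
  D <- as.matrix(stats::dist(X))

  # BUILD
  medoids <- integer(0)
  medoids[1L] <- which.min(rowSums(D))
  while (length(medoids) < k) {
    dn <- apply(D[, medoids, drop = FALSE], 1L, min)
    cand <- setdiff(seq_len(n), medoids)
    gain <- vapply(cand, function(c) sum(pmax(dn - D[, c], 0)), 0)
    medoids <- c(medoids, cand[which.max(gain)])
  }
  medoids <- sort(medoids)
  cost_of <- function(m) sum(apply(D[, m, drop = FALSE], 1L, min))
  cost <- cost_of(medoids)
  trace <- cost

  # SWAP (steepest descent, deterministic tie-break by lowest index pair)
  if (k < n) {
    repeat {
      best <- cost; best_m <- NA_integer_; best_h <- NA_integer_
      nonmed <- setdiff(seq_len(n), medoids)
      for (mi in seq_along(medoids)) {
        for (h in nonmed) {
          m2 <- medoids; m2[mi] <- h
          cst <- cost_of(m2)
          if (cst < best - 1e-12) {
            best <- cst; best_m <- mi; best_h <- h
          }
        }
      }
      if (is.na(best_m)) break
      medoids[best_m] <- best_h
      medoids <- sort(medoids)
      cost <- best
      trace <- c(trace, cost)
    }
  }

  labels <- apply(D[, medoids, drop = FALSE], 1L, which.min)
  sil_def <- k > 1L && k < n
  sil <- if (sil_def) mean_silhouette(D, labels) else 0
  structure(list(k = k, labels = labels, medoids = medoids,
                 medoid_ids = if (!is.null(rownames(X))) rownames(X)[medoids]
                              else medoids,
                 total_cost = cost, silhouette = sil,
                 silhouette_defined = sil_def, cost_trace = trace,
                 stability = NULL),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("PAM clustering: k = %d, total cost = %.4f, mean silhouette = %.3f\n",
              x$k, x$total_cost, x$silhouette))
  print(table(cluster = x$labels))
  invisible(x)
}

scale_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-300] <- 1
  out <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  rownames(out) <- rownames(X)
  out
}

mean_silhouette <- function(D, labels) {
  n <- nrow(D)
  ids <- sort(unique(labels))
  # duplicated points can leave a medoid with an empty cluster; a
  # one-cluster partition has no defined silhouette
  if (length(ids) < 2L) return(0)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    same <- which(labels == own)
    if (length(same) == 1L) { s[i] <- 0; next }
    a <- sum(D[i, same]) / (length(same) - 1L)
    b <- min(vapply(setdiff(ids, own), function(cl)
      mean(D[i, labels == cl]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

within_dispersion <- function(D2, labels) {
  # Tibshirani's W_k: sum over clusters of (sum of squared pairwise
  # dissimilarities) / (2 * cluster size)
  sum(vapply(unique(labels), function(cl) {
    idx <- which(labels == cl)
    sum(D2[idx, idx]) / (2 * length(idx))
  }, 0))
}

#' Choose the number of clusters by majority vote
#'
#' Votes three internal indices over `k_range` — maximum mean silhouette
#' width, maximum Calinski-Harabasz pseudo-F, and the gap statistic with a
#' uniform (bounding-box) reference — and returns the k preferred by the
#' majority; all ties resolve toward the smallest k. The gap index votes
#' via the standard one-standard-error rule (smallest k whose gap is
#' within one reference SE of the next k), falling back to the gap
#' maximizer.
#'
#' @param X numeric matrix or data frame.
#' @param k_range candidate cluster counts, a subset of 2..(n-1).
#' @param scale standardize columns first (see [pam_cluster()]).
#' @param gap_B number of uniform reference datasets for the gap index.
#' @param seed seed for the gap reference draws.
#' @return the selected k (integer).
#' @export
select_k <- function(X, k_range = 2:6, scale = TRUE, gap_B = 50L, seed = 1L) {
  X <- as_data_matrix(X)
  n <- nrow(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > n - 1L))
    stop("`k_range` must lie within 2..(n-1)", call. = FALSE)
  if (scale) X <- scale_columns(X)
  D <- as.matrix(stats::dist(X))
  D2 <- D^2

  # degenerate data (all points coincide): nothing to separate
  if (max(D) < 1e-12) return(min(k_range))

  fits <- lapply(k_range, function(k) pam_cluster(X, k, scale = FALSE))
  sil <- vapply(fits, function(f) f$silhouette, 0)

  gmean <- colMeans(X)
  tss <- sum(sweep(X, 2L, gmean)^2)
  ch <- vapply(seq_along(k_range), function(i) {
    k <- k_range[i]; lab <- fits[[i]]$labels
    wss <- sum(vapply(unique(lab), function(cl) {
      idx <- which(lab == cl)
      sum(sweep(X[idx, , drop = FALSE], 2L,
                colMeans(X[idx, , drop = FALSE]))^2)
    }, 0))
    bss <- tss - wss
    val <- (bss / (k - 1)) / (wss / (n - k))
    if (is.finite(val)) val else -Inf
  }, 0)

  log_w_obs <- log(vapply(fits, function(f) within_dispersion(D2, f$labels), 0))
  set.seed(as.integer(seed))
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  log_w_ref <- matrix(NA_real_, nrow = gap_B, ncol = length(k_range))
  for (b in seq_len(gap_B)) {
    R <- sapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]))
    DR2 <- as.matrix(stats::dist(R))^2
    for (i in seq_along(k_range)) {
      fr <- pam_cluster(R, k_range[i], scale = FALSE)
      log_w_ref[b, i] <- log(within_dispersion(DR2, fr$labels))
    }
  }
  gap <- colMeans(log_w_ref) - log_w_obs
  se <- apply(log_w_ref, 2L, stats::sd) * sqrt(1 + 1 / gap_B)
  gap_vote <- NA_integer_
  for (i in seq_len(length(k_range) - 1L)) {
    if (is.finite(gap[i]) && gap[i] >= gap[i + 1L] - se[i + 1L]) {
      gap_vote <- k_range[i]; break
    }
  }
  if (is.na(gap_vote)) gap_vote <- k_range[which.max(gap)]

  votes <- c(k_range[which.max(sil)], k_range[which.max(ch)], gap_vote)
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}

#' Bootstrap cluster stability (Jaccard index)
#'
#' For each of `B` bootstrap resamples the data are re-clustered with PAM
#' at the same k, and each original cluster is matched to the new cluster
#' with which it shares the largest Jaccard overlap (computed on the set
#' of distinct original observations present in the resample). Per-cluster
#' mean Jaccard values near 1 indicate stable, reproducible clusters;
#' values toward 0.5 and below indicate pattern-free structure.
#'
#' @param X numeric matrix or data frame.
#' @param k number of clusters.
#' @param B bootstrap resamples (>= 2).
#' @param seed integer seed.
#' @param scale standardize columns first.
#' @return numeric vector of per-cluster mean Jaccard indices (length k).
#' @export
cluster_stability <- function(X, k, B = 100L, seed = 1L, scale = TRUE) {
  X <- as_data_matrix(X)
  if (B < 2L) stop("`B` must be >= 2", call. = FALSE)
  if (scale) X <- scale_columns(X)
  base <- pam_cluster(X, k, scale = FALSE)
  orig <- split(seq_len(nrow(X)), base$labels)
  set.seed(as.integer(seed))
  acc <- matrix(0, nrow = B, ncol = length(orig))
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(X), replace = TRUE)
    uni <- unique(idx)
    fb <- pam_cluster(X[idx, , drop = FALSE], k, scale = FALSE)
    # label of each distinct original point = label at its first occurrence
    lab_u <- fb$labels[match(uni, idx)]
    new <- split(uni, lab_u)
    for (ci in seq_along(orig)) {
      # compare on the points actually present in this resample
      present <- intersect(orig[[ci]], uni)
      if (!length(present)) { acc[b, ci] <- 0; next }
      best <- 0
      for (dj in new) {
        j <- length(intersect(present, dj)) / length(union(present, dj))
        if (j > best) best <- j
      }
      acc[b, ci] <- best
    }
  }
  colMeans(acc)
}

#' Chi-squared test of homogeneity
#'
#' Pearson chi-squared test (no continuity correction) that the row groups
#' share one distribution over the columns; for a 2 x 2 table the df is 1.
#'
#' @param table matrix of nonnegative integer counts with positive row and
#'   column margins.
#' @return a test result.
#' @export
#' @examples
#' chi2_homogeneity(rbind(c(20, 18), c(6, 11)))
chi2_homogeneity <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero margin", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result(ct$statistic, list(chisq_df = unname(ct$parameter)),
              ct$p.value, "Pearson chi-squared (homogeneity)")
}

#' Spearman correlations with Bonferroni adjustment
#'
#' All pairwise Spearman rank correlations between the supplied columns;
#' p-values are multiplied by the number of pairs (Bonferroni) and capped
#' at 1. A constant column yields an undefined correlation, flagged with
#' `NA` rather than an error.
#'
#' @param vars data frame or matrix of numeric columns (>= 3 rows).
#' @return data frame with columns `var1`, `var2`, `gamma`, `p_value`,
#'   `p_adjusted`.
#' @export
spearman_bonferroni <- function(vars) {
  X <- as_data_matrix(vars)
  if (nrow(X) < 3L) stop("need at least 3 observations", call. = FALSE)
  nv <- ncol(X)
  if (nv < 2L) stop("need at least 2 variables", call. = FALSE)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("V", seq_len(nv))
  pairs <- utils::combn(nv, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(q) {
    i <- pairs[1L, q]; j <- pairs[2L, q]
    if (stats::sd(X[, i]) < 1e-300 || stats::sd(X[, j]) < 1e-300)
      return(data.frame(var1 = nm[i], var2 = nm[j], gamma = NA_real_,
                        p_value = NA_real_, p_adjusted = NA_real_))
    ct <- suppressWarnings(stats::cor.test(X[, i], X[, j],
                                           method = "spearman",
                                           exact = FALSE))
    data.frame(var1 = nm[i], var2 = nm[j], gamma = unname(ct$estimate),
               p_value = ct$p.value,
               p_adjusted = min(1, ct$p.value * ncol(pairs)))
  })
  do.call(rbind, res)
}

#' Principal-component projection of standardized variables
#'
#' Projects the rows onto the leading principal axes of the standardized
#' (zero mean, unit variance) data, for two-dimensional display of the
#' progeny cloud.
#'
#' @param X numeric matrix or data frame (n > dims).
#' @param dims number of leading components to keep.
#' @return list with `coordinates` (n x dims score matrix) and `explained`
#'   (variance fraction per retained component).
#' @export
pca_project <- function(X, dims = 2L) {
  X <- as_data_matrix(X)
  dims <- as.integer(dims)
  if (nrow(X) <= dims)
    stop("need more observations than projected dimensions", call. = FALSE)
  Z <- scale_columns(X)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  dims <- min(dims, ncol(pc$x))
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = pc$x[, seq_len(dims), drop = FALSE],
       explained = frac[seq_len(dims)])
}
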