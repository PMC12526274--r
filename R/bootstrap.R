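#' Bootstrap configuration
#'
#' @param B number of resamples (>= 2; the study default is 10,000).
#' @param level two-sided confidence level in (0, 1); default 0.95.
#' @param seed integer seed; identical configurations give identical
#'   intervals.
#' @return object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 10000L, level = 0.95, seed = 1L) {
  B <- as.integer(B)
  if (B < 2L) stop("`B` must be >= 2", call. = FALSE)
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("`level` must lie in (0, 1)", call. = FALSE)
  structure(list(B = B, level = level, seed = as.integer(seed)),
            class = "bootstrap_config")
}

# deterministic stream id per (seed, group label) so every fitted group gets
# its own reproducible resampling sequence
stream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Percentile-bootstrap confidence interval for an allometric parameter
#'
#' Resamples leaves with replacement `B` times, refits the chosen model on
#' each resample, and returns the empirical `(1 - level)/2` and
#' `1 - (1 - level)/2` quantiles of the parameter (the bootstrap percentile
#' method). Replicates in which the model fails to fit (e.g. a degenerate
#' resample for the power law) are dropped and counted; if more than 5% are
#' dropped the result carries a warning flag.
#'
#' @param data measurement data frame (see [measure_leaves()]).
#' @param model which parameter to bootstrap: `"M1_alpha"` (Montgomery
#'   constant), `"M2_alpha"` or `"M2_beta"` (power-law parameters).
#' @param cfg a [bootstrap_config()].
#' @param stream optional label mixed into the seed so different groups
#'   fitted under one configuration use distinct, reproducible streams.
#' @return object of class `percentile_ci`: list with `low`, `high`,
#'   `level`, `B`, `dropped`, `unstable` (TRUE when > 5% of replicates were
#'   dropped).
#' @export
bootstrap_ci <- function(data, model = c("M1_alpha", "M2_alpha", "M2_beta"),
                         cfg = bootstrap_config(), stream = model) {
  model <- match.arg(model)
  d <- check_measurements(data, need = c("L_cm", "W_cm", "LS_cm2"))
  n <- nrow(d)
  if (n < 2L) stop("bootstrap needs at least 2 leaves", call. = FALSE)
  if (!inherits(cfg, "bootstrap_config"))
    stop("`cfg` must be a bootstrap_config", call. = FALSE)
  set.seed(stream_seed(cfg$seed, paste0(model, stream[1L])))

  if (model == "M1_alpha") {
    lw <- d$L_cm * d$W_cm
    num <- d$LS_cm2 * lw
    den <- lw^2
    idx <- matrix(sample.int(n, n * cfg$B, replace = TRUE), nrow = n)
    theta <- colSums(matrix(num[idx], nrow = n)) /
             colSums(matrix(den[idx], nrow = n))
    dropped <- sum(!is.finite(theta))
    theta <- theta[is.finite(theta)]
  } else {
    theta <- numeric(cfg$B)
    ok <- logical(cfg$B)
    for (r in seq_len(cfg$B)) {
      db <- d[sample.int(n, n, replace = TRUE), , drop = FALSE]
      fit <- tryCatch(fit_power_law(db), error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$alpha) && is.finite(fit$beta)) {
        theta[r] <- if (model == "M2_alpha") fit$alpha else fit$beta
        ok[r] <- TRUE
      }
    }
    dropped <- sum(!ok)
    theta <- theta[ok]
  }
  if (length(theta) < 2L)
    stop("all bootstrap replicates failed", call. = FALSE)
  q <- stats::quantile(theta, probs = c((1 - cfg$level) / 2,
                                        1 - (1 - cfg$level) / 2),
                       names = FALSE, type = 7)
  structure(list(low = q[1L], high = q[2L], level = cfg$level, B = cfg$B,
                 dropped = dropped, unstable = dropped > 0.05 * cfg$B),
            class = "percentile_ci")
}

#' @export
print.percentile_ci <- function(x, ...) {
  cat(sprintf("%.0f%% percentile bootstrap CI: (%.5f, %.5f)  [B = %d%s]\n",
              100 * x$level, x$low, x$high, x$B,
              if (x$dropped > 0) sprintf(", %d replicates dropped", x$dropped)
              else ""))
  invisible(x)
}

as_ci_pair <- function(ci) {
  if (inherits(ci, "percentile_ci")) return(c(ci$low, ci$high))
  ci <- as.numeric(ci)
  if (length(ci) != 2L || anyNA(ci) || ci[1L] > ci[2L])
    stop("`ci` must be an ordered (low, high) pair", call. = FALSE)
  ci
}

#' Reference-value hypothesis decision from a confidence interval
#'
#' Decides whether a confidence interval excludes a fixed reference value.
#' Containment uses the closed interval (a reference exactly on an endpoint
#' counts as contained). The hypothesis is supported precisely when the
#' reference is excluded, with `direction` reporting which side the
#' interval falls on.
#'
#' @param ci a [bootstrap_ci()] result or an ordered numeric pair.
#' @param reference the fixed value tested against.
#' @param hypothesis label (`"H1"` ... `"H5"` in the study battery).
#' @return object of class `hypothesis_decision`: list with `hypothesis`,
#'   `reference`, `ci`, `contained`, `direction` (`"above"`, `"below"` or
#'   `"contains"`), `supported` (= `!contained`), `p_value` (`NA` here;
#'   filled by [test_vs_pooled()]).
#' @export
#' @examples
#' test_reference(c(0.670, 0.680), 2 / 3, "H4")$direction  # "above"
test_reference <- function(ci, reference, hypothesis = "H") {
  ci <- as_ci_pair(ci)
  contained <- ci[1L] <= reference && reference <= ci[2L]
  direction <- if (ci[1L] > reference) "above"
               else if (ci[2L] < reference) "below"
               else "contains"
  structure(list(hypothesis = hypothesis, reference = reference, ci = ci,
                 contained = contained, direction = direction,
                 supported = !contained, p_value = NA_real_),
            class = "hypothesis_decision")
}

#' @export
print.hypothesis_decision <- function(x, ...) {
  cat(sprintf("%s vs %.5f: CI (%.5f, %.5f) -> %s (%s%s)\n",
              x$hypothesis, x$reference, x$ci[1L], x$ci[2L],
              if (x$supported) "supported" else "not supported", x$direction,
              if (is.finite(x$p_value)) sprintf(", p = %.4f", x$p_value)
              else ""))
  invisible(x)
}

#' Bootstrap test of a group's Montgomery constant against the pooled fit
#'
#' Bootstraps the difference `delta_b = alpha_group,b - alpha_pooled,b`,
#' resampling the group and the pooled table independently within each
#' paired replicate, and decides whether the percentile interval of delta
#' excludes zero. The pooled table keeps the focal group inside it, exactly
#' as the study pools all leaves; the induced dependence is deliberate and
#' uncorrected. The attached p-value is the usual two-sided bootstrap
#' sign probability `2 * min(P(delta <= 0), P(delta >= 0))`.
#'
#' @param group measurement data frame for the focal group.
#' @param pooled measurement data frame for all leaves (a superset of
#'   `group`).
#' @param cfg a [bootstrap_config()].
#' @param stream label mixed into the seed (defaults to the group's
#'   progeny id when present).
#' @return a `hypothesis_decision` for the difference (reference 0) with
#'   its bootstrap p-value.
#' @export
test_vs_pooled <- function(group, pooled, cfg = bootstrap_config(),
                           stream = NULL) {
  g <- check_measurements(group, need = c("L_cm", "W_cm", "LS_cm2"))
  p <- check_measurements(pooled, need = c("L_cm", "W_cm", "LS_cm2"))
  if (nrow(g) < 2L) stop("group must contain at least 2 leaves", call. = FALSE)
  if (nrow(p) < nrow(g))
    stop("`pooled` must be at least as large as `group`", call. = FALSE)
  if (is.null(stream))
    stream <- if (!is.null(g$progeny_id)) g$progeny_id[1L] else "group"
  set.seed(stream_seed(cfg$seed, paste0("H1", stream)))

  boot_alpha <- function(d, B) {
    n <- nrow(d)
    lw <- d$L_cm * d$W_cm
    num <- d$LS_cm2 * lw
    den <- lw^2
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    colSums(matrix(num[idx], nrow = n)) / colSums(matrix(den[idx], nrow = n))
  }
  delta <- boot_alpha(g, cfg$B) - boot_alpha(p, cfg$B)
  keep <- is.finite(delta)
  delta <- delta[keep]
  q <- stats::quantile(delta, probs = c((1 - cfg$level) / 2,
                                        1 - (1 - cfg$level) / 2),
                       names = FALSE, type = 7)
  dec <- test_reference(q, 0, "H1")
  dec$p_value <- 2 * min(mean(delta <= 0), mean(delta >= 0))
  dec$p_value <- min(dec$p_value, 1)
  dec
}
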