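#' Fit the Montgomery proportionality model
#'
#' Model 1: `LS = alpha * L * W + e`. Because the model is linear in alpha,
#' the least-squares estimate through the origin has the closed form
#' `alpha = sum(LS * LW) / sum(LW^2)` with `LW = L * W`; no iteration is
#' needed, which also makes bootstrap refits cheap. Note this is the
#' regression slope, not the mean of the per-leaf ratios `LS / LW` — the
#' two only coincide when every leaf has the same `LW`.
#'
#' @param data data frame with columns `L_cm`, `W_cm`, `LS_cm2`
#'   (as produced by [measure_leaves()]).
#' @return object of class `montgomery_fit`: list with `alpha`, `rmse`
#'   (cm^2, over the fitted values), `n`, and `ci` (`NULL` until filled by
#'   [bootstrap_ci()]).
#' @export
#' @examples
#' d <- data.frame(L_cm = c(5, 10), W_cm = c(2, 4), LS_cm2 = 0.67 * c(10, 40))
#' fit_montgomery(d)$alpha  # 0.67
fit_montgomery <- function(data) {
  d <- check_measurements(data, need = c("L_cm", "W_cm", "LS_cm2"))
  if (nrow(d) < 1L) stop("empty measurement table", call. = FALSE)
  lw <- d$L_cm * d$W_cm
  if (any(lw <= 0)) stop("all leaves must have positive L * W", call. = FALSE)
  alpha <- sum(d$LS_cm2 * lw) / sum(lw^2)
  pred <- alpha * lw
  structure(list(alpha = alpha, ci = NULL,
                 rmse = rmse(d$LS_cm2, pred), n = nrow(d)),
            class = "montgomery_fit")
}

#' @export
print.montgomery_fit <- function(x, ...) {
  cat(sprintf("Montgomery fit (LS = alpha * L * W): alpha = %.5f", x$alpha))
  if (!is.null(x$ci))
    cat(sprintf(" (%.5f-%.5f)", x$ci[1L], x$ci[2L]))
  cat(sprintf(", RMSE = %.3f cm^2, n = %d\n", x$rmse, x$n))
  invisible(x)
}

#' Fit the power-law similarity model
#'
#' Model 2: `LS = alpha * L^beta + e`, fitted by damped Gauss-Newton
#' (Levenberg-Marquardt) least squares in the original scale, so the
#' additive-error statistical model is minimized as written rather than its
#' log transform. Starting values come from the ordinary least-squares
#' regression of `log(LS)` on `log(L)`, which is basin-correct for power
#' laws. Under the principle of similarity (geometrically self-similar
#' leaves) the exponent beta equals 2.
#'
#' @param data data frame with columns `L_cm`, `LS_cm2`; at least 3 rows.
#' @param tol convergence tolerance on the relative parameter change.
#' @param max_iter iteration cap; exceeding it (or an unidentifiable
#'   exponent, e.g. all lengths equal) yields `converged = FALSE` rather
#'   than an error.
#' @return object of class `power_law_fit`: list with `alpha`, `beta`,
#'   `alpha_ci`, `beta_ci` (`NULL` until bootstrapped), `rmse`, `n`,
#'   `converged`.
#' @export
#' @examples
#' d <- data.frame(L_cm = 5:14, LS_cm2 = 0.3 * (5:14)^2)
#' f <- fit_power_law(d)
#' c(f$alpha, f$beta)  # 0.3, 2
fit_power_law <- function(data, tol = 1e-10, max_iter = 200L) {
  d <- check_measurements(data, need = c("L_cm", "LS_cm2"))
  if (nrow(d) < 3L)
    stop("power-law fit needs at least 3 leaves", call. = FALSE)
  L <- d$L_cm; LS <- d$LS_cm2
  if (any(L <= 0) || any(LS <= 0))
    stop("L and LS must be positive", call. = FALSE)
  n <- length(L)

  out <- structure(list(alpha = NA_real_, beta = NA_real_, alpha_ci = NULL,
                        beta_ci = NULL, rmse = NA_real_, n = n,
                        converged = FALSE),
                   class = "power_law_fit")
  if (stats::var(log(L)) < 1e-24) {
    # all lengths identical: beta is unidentifiable
    out$alpha <- mean(LS) / L[1L]^2
    out$beta <- 2
    out$rmse <- rmse(LS, out$alpha * L^out$beta)
    return(out)
  }

  # log-log OLS start
  cf <- stats::lm.fit(cbind(1, log(L)), log(LS))$coefficients
  a <- exp(cf[1L]); b <- cf[2L]

  lambda <- 1e-3
  sse <- sum((LS - a * L^b)^2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lb <- L^b
    r <- LS - a * lb
    J <- cbind(lb, a * lb * log(L))
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    step_ok <- FALSE
    for (k in 1:30) {
      A <- JtJ + lambda * diag(diag(JtJ), 2L)
      delta <- tryCatch(solve(A, g), error = function(e) NULL)
      if (!is.null(delta)) {
        a2 <- a + delta[1L]; b2 <- b + delta[2L]
        if (a2 > 0) {
          sse2 <- sum((LS - a2 * L^b2)^2)
          if (is.finite(sse2) && sse2 <= sse) {
            rel <- max(abs(delta[1L]) / max(abs(a), 1e-12),
                       abs(delta[2L]) / max(abs(b), 1e-12))
            a <- a2; b <- b2; sse <- sse2
            lambda <- max(lambda / 3, 1e-12)
            step_ok <- TRUE
            if (rel < tol) converged <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 5
    }
    if (converged || !step_ok) break
  }

  out$alpha <- unname(a); out$beta <- unname(b)
  out$rmse <- rmse(LS, a * L^b)
  out$converged <- converged
  out
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit (LS = alpha * L^beta): alpha = %.5f, beta = %.5f",
              x$alpha, x$beta))
  if (!is.null(x$beta_ci))
    cat(sprintf(" (beta CI %.5f-%.5f)", x$beta_ci[1L], x$beta_ci[2L]))
  cat(sprintf(", RMSE = %.3f cm^2, n = %d%s\n", x$rmse, x$n,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Root mean squared error
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1L)
    stop("`observed` and `predicted` must have equal, positive length",
         call. = FALSE)
  sqrt(mean((observed - predicted)^2))
}

check_measurements <- function(data, need) {
  if (!is.data.frame(data))
    stop("measurements must be a data frame", call. = FALSE)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("measurement table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  data
}
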