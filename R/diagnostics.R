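as_params <- function(object) {
  if (inherits(object, "cubinar_fit")) object$params
  else if (inherits(object, "cubinar_params")) object
  else stop("expected a cubinar_fit or cubinar_params object")
}

#' Conditional mean and variance of one component
#'
#' One-step-ahead moments of component `i` given its previous count and the
#' regime transition `r -> s`:
#' mean \eqn{\alpha_i x_{prev} + \mu_i(s, r)} and variance
#' \eqn{\alpha_i(1 - \alpha_i) x_{prev} + \mu_i(s, r)} — the binomial
#' thinning variance plus the Poisson innovation variance.
#'
#' @param x_prev previous count of the component.
#' @param object a [cubinar_params()] or fitted model.
#' @param r regime at `t-1`; `s` regime at `t`.
#' @param s see `r`.
#' @param component 1 or 2.
#' @return named vector `c(mean = , var = )`.
#' @export
conditional_moments <- function(x_prev, object, r, s, component = 1) {
  p <- as_params(object)
  ip <- innovation_params(p, r, s)
  a <- if (component == 1) p$alpha1 else p$alpha2
  mu <- if (component == 1) ip$mu1 else ip$mu2
  c(mean = a * x_prev + mu, var = a * (1 - a) * x_prev + mu)
}

# vectorized conditional moments over t = 2..n for both components
cond_moments_path <- function(series, p) {
  r <- series$states[-series$n]
  s <- series$states[-1]
  phi_star <- p$phi * (1 - p$alpha1 * p$alpha2)
  mu1 <- p$lambda1[s] - p$alpha1 * p$lambda1[r]
  mu2 <- p$lambda2[s] - p$alpha2 * p$lambda2[r]
  if (any(mu1 - phi_star <= 0) || any(mu2 - phi_star <= 0))
    stop_if_infeasible(p)
  x1p <- series$x1[-series$n]; x2p <- series$x2[-series$n]
  list(mean1 = p$alpha1 * x1p + mu1,
       mean2 = p$alpha2 * x2p + mu2,
       var1 = p$alpha1 * (1 - p$alpha1) * x1p + mu1,
       var2 = p$alpha2 * (1 - p$alpha2) * x2p + mu2,
       mu1 = mu1, mu2 = mu2)
}

#' Standardized Pearson residuals
#'
#' \eqn{(x_{i,t} - E[X_{i,t} \mid x_{i,t-1}]) / \sqrt{Var(X_{i,t} \mid
#' x_{i,t-1})}} for `t = 2..n` and each component. Under an adequate model
#' the residual series have mean close to 0, variance close to 1, and no
#' autocorrelation or cross-correlation.
#'
#' @param series a [cubinar_series()].
#' @param object a fitted model or parameter vector.
#' @return an `(n-1)` x 2 matrix of residuals, columns `x1`, `x2`.
#' @export
pearson_residuals <- function(series, object) {
  p <- as_params(object)
  stop_if_infeasible(p)
  cm <- cond_moments_path(series, p)
  cbind(x1 = (series$x1[-1] - cm$mean1) / sqrt(cm$var1),
        x2 = (series$x2[-1] - cm$mean2) / sqrt(cm$var2))
}

residual_summary <- function(res, lag.max = 10) {
  list(mean = colMeans(res),
       var = apply(res, 2, var),
       acf1 = apply(res, 2, function(z)
         acf(z, lag.max = lag.max, plot = FALSE)$acf[-1]),
       cross_cor = stats::cor(res[, 1], res[, 2]))
}

# exact univariate conditional pmf of component i at one transition:
# binomial(x_prev, alpha) convolved with Poisson(mu)
cond_pmf1 <- function(x, x_prev, alpha, mu) {
  k <- 0:min(x, x_prev)
  sum(dbinom(k, x_prev, alpha) * dpois(x - k, mu))
}

cond_cdf1 <- function(x, x_prev, alpha, mu) {
  if (x < 0) return(0)
  sum(vapply(0:x, cond_pmf1, 0, x_prev = x_prev, alpha = alpha, mu = mu))
}

#' Non-randomized PIT histogram
#'
#' Probability integral transform diagnostic for count data: each
#' observation contributes a piecewise-linear cdf segment between
#' `F(x_t - 1)` and `F(x_t)` of its exact one-step conditional distribution
#' (binomial thinning convolved with the Poisson innovation), aggregated
#' into a histogram whose bin heights average to exactly 1. Uniform bars
#' indicate a calibrated predictive distribution; a U shape signals
#' under-dispersion or a misplaced mean.
#'
#' @param series a [cubinar_series()].
#' @param object a fitted model or parameter vector.
#' @param bins number of histogram bins (default 10).
#' @return a `bins` x 2 matrix of bin heights, one column per component.
#' @export
pit_histogram <- function(series, object, bins = 10) {
  stopifnot(bins >= 2)
  p <- as_params(object)
  stop_if_infeasible(p)
  cm <- cond_moments_path(series, p)
  u <- seq(0, 1, length.out = bins + 1)
  heights <- matrix(NA_real_, bins, 2, dimnames = list(NULL, c("x1", "x2")))
  for (i in 1:2) {
    x <- if (i == 1) series$x1 else series$x2
    alpha <- if (i == 1) p$alpha1 else p$alpha2
    mu <- if (i == 1) cm$mu1 else cm$mu2
    n1 <- series$n - 1
    Fbar <- numeric(bins + 1)  # mean PIT cdf at the bin edges
    for (t in seq_len(n1)) {
      Fl <- cond_cdf1(x[t + 1] - 1, x[t], alpha, mu[t])
      Fu <- cond_cdf1(x[t + 1], x[t], alpha, mu[t])
      w <- pmin(pmax((u - Fl) / (Fu - Fl), 0), 1)
      Fbar <- Fbar + w
    }
    Fbar <- Fbar / n1
    heights[, i] <- diff(Fbar) * bins
  }
  heights
}

#' Mean logarithmic score
#'
#' The average negative log one-step predictive probability,
#' \eqn{\frac{1}{n-1}\sum_{t=2}^n -\log P(x_t \mid x_{t-1})}, i.e.
#' `-loglik / (n - 1)`. Lower is better; the score is proper, so the
#' generating parameters minimize its expectation.
#'
#' @param series a [cubinar_series()].
#' @param object a fitted model or parameter vector.
#' @return scalar mean score.
#' @export
log_score <- function(series, object) {
  p <- as_params(object)
  -cubinar_loglik(series, p, strict = TRUE) / (series$n - 1)
}

#' In- and out-of-sample RMSE of one-step-ahead predictions
#'
#' Root mean square error between the observations and their conditional
#' expectations. The in-sample RMSE uses the supplied fit over
#' `t = 2..n`. For the out-of-sample RMSE the model is refitted (same
#' method) to the series without its last `holdout` observations, and the
#' holdout points are predicted one step ahead using the realized regimes
#' and the actual previous counts.
#'
#' @param series a [cubinar_series()].
#' @param fit a `"cubinar_fit"` (or a bare [cubinar_params()], refitted by
#'   CML for the out-of-sample part).
#' @param holdout number of trailing observations to hold out (default
#'   10); `0` skips the out-of-sample part.
#' @return a list with `rmse_in` and `rmse_out`, each a named length-2
#'   vector (per component); `rmse_out` is `NA` when `holdout = 0`.
#' @export
prediction_rmse <- function(series, fit, holdout = 10) {
  if (holdout < 0 || holdout >= series$n - 2)
    stop("holdout must satisfy 0 <= holdout < n - 2")
  method <- if (inherits(fit, "cubinar_fit")) fit$method else "cml"
  p <- as_params(fit)
  cm <- cond_moments_path(series, p)
  rmse_in <- c(x1 = sqrt(mean((series$x1[-1] - cm$mean1)^2)),
               x2 = sqrt(mean((series$x2[-1] - cm$mean2)^2)))
  rmse_out <- c(x1 = NA_real_, x2 = NA_real_)
  if (holdout > 0) {
    keep <- seq_len(series$n - holdout)
    train <- cubinar_series(series$x1[keep], series$x2[keep],
                            series$states[keep], S = series$S)
    refit <- if (method == "cml") cml_fit(train, se = FALSE)
             else yw_fit(train)
    cm2 <- cond_moments_path(series, refit$params)
    idx <- (series$n - holdout):(series$n - 1)  # transitions into holdout
    rmse_out <- c(x1 = sqrt(mean((series$x1[idx + 1] - cm2$mean1[idx])^2)),
                  x2 = sqrt(mean((series$x2[idx + 1] - cm2$mean2[idx])^2)))
  }
  list(rmse_in = rmse_in, rmse_out = rmse_out)
}

#' Model-adequacy report
#'
#' Bundles the adequacy and forecast-comparison diagnostics: Pearson
#' residual summaries (mean, variance, ACF, lag-0 cross-correlation), PIT
#' histogram bin heights, mean logarithmic score, AIC, and in-/out-of-
#' sample RMSE.
#'
#' @param series a [cubinar_series()].
#' @param fit a `"cubinar_fit"`; for YW fits the log-likelihood (needed by
#'   the score and AIC) is evaluated at the YW estimate.
#' @param bins PIT bins (default 10).
#' @param holdout trailing observations held out for the out-of-sample
#'   RMSE (default 10; use 0 to skip).
#' @param lag.max residual ACF lags reported.
#' @return an object of class `"cubinar_diagnostics"`.
#' @export
diagnose <- function(series, fit, bins = 10, holdout = 10, lag.max = 10) {
  stopifnot(inherits(fit, "cubinar_fit"))
  p <- fit$params
  ll <- fit$loglik %||% cubinar_loglik(series, p, strict = TRUE)
  res <- pearson_residuals(series, p)
  out <- list(residuals = res,
              residual_summary = residual_summary(res, lag.max),
              pit = pit_histogram(series, p, bins),
              mean_log_score = -ll / (series$n - 1),
              aic = 2 * fit$n_params - 2 * ll,
              rmse = prediction_rmse(series, fit, holdout),
              n = series$n, method = fit$method)
  class(out) <- "cubinar_diagnostics"
  out
}

#' @export
print.cubinar_diagnostics <- function(x, ...) {
  rs <- x$residual_summary
  cat(sprintf("CuBINAR(1) adequacy diagnostics (%s fit, n = %d)\n",
              toupper(x$method), x$n))
  cat(sprintf("Pearson residuals: mean (%.3f, %.3f), var (%.3f, %.3f), ",
              rs$mean[1], rs$mean[2], rs$var[1], rs$var[2]))
  cat(sprintf("lag-0 cross-cor %.3f\n", rs$cross_cor))
  cat(sprintf("mean log score: %.4f, AIC: %.2f\n", x$mean_log_score, x$aic))
  cat(sprintf("RMSE in-sample: (%.3f, %.3f)", x$rmse$rmse_in[1],
              x$rmse$rmse_in[2]))
  if (all(is.finite(x$rmse$rmse_out)))
    cat(sprintf(", out-of-sample: (%.3f, %.3f)", x$rmse$rmse_out[1],
                x$rmse$rmse_out[2]))
  cat("\nPIT bin heights:\n")
  print(round(x$pit, 3))
  invisible(x)
}

#' Serialize a diagnostics report to plain text tables
#'
#' Writes the scalar summaries, the PIT heights and the residual ACF as a
#' single readable text report so any plotting layer can render them.
#'
#' @param x a `"cubinar_diagnostics"` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(x, path) {
  stopifnot(inherits(x, "cubinar_diagnostics"))
  con <- file(path, "w"); on.exit(close(con))
  rs <- x$residual_summary
  writeLines(c(sprintf("method: %s", x$method),
               sprintf("n: %d", x$n),
               sprintf("residual_mean: %.6f %.6f", rs$mean[1], rs$mean[2]),
               sprintf("residual_var: %.6f %.6f", rs$var[1], rs$var[2]),
               sprintf("residual_crosscor: %.6f", rs$cross_cor),
               sprintf("mean_log_score: %.6f", x$mean_log_score),
               sprintf("aic: %.6f", x$aic),
               sprintf("rmse_in: %.6f %.6f",
                       x$rmse$rmse_in[1], x$rmse$rmse_in[2]),
               sprintf("rmse_out: %.6f %.6f",
                       x$rmse$rmse_out[1], x$rmse$rmse_out[2]),
               "", "pit_bin x1 x2"), con)
  for (b in seq_len(nrow(x$pit)))
    writeLines(sprintf("%d %.6f %.6f", b, x$pit[b, 1], x$pit[b, 2]), con)
  writeLines(c("", "acf_lag x1 x2"), con)
  for (l in seq_len(nrow(rs$acf1)))
    writeLines(sprintf("%d %.6f %.6f", l, rs$acf1[l, 1], rs$acf1[l, 2]), con)
  invisible(path)
}
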