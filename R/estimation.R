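#' Regime-conditional sample moments
#'
#' Computes the moment statistics the Yule-Walker estimators are built
#' from, conditioning on the realized regime path:
#' \deqn{\hat\mu_i(s) = \frac{1}{n_s}\sum_t x_{i,t} 1\{s_t = s\},}
#' the regime-conditional variances and cross-covariance (same divisor
#' `n_s`), and the lag-1 covariances
#' \deqn{\hat\gamma_i(r, s) = \frac{1}{n_{r,s}}
#'   \sum_{t \ge 2} (x_{i,t} - \hat\mu_i(s))(x_{i,t-1} - \hat\mu_i(r))
#'   1\{s_{t-1} = r, s_t = s\}.}
#' Cells whose divisor is zero are returned as `NA` rather than raising an
#' error; whether that blocks estimation is decided by the caller.
#'
#' @param series a [cubinar_series()] with `n >= 2`.
#' @return an object of class `"cubinar_moments"`: `mu` and `gamma0`
#'   (`S` x 2 matrices, columns = components), `gamma12` (length `S`),
#'   `gamma_lag` (`S` x `S` x 2 array, `[r, s, i]`), and `counts` from
#'   [state_counts()].
#' @export
sample_moments <- function(series) {
  stopifnot(inherits(series, "cubinar_series"), series$n >= 2)
  S <- series$S
  x <- cbind(series$x1, series$x2)
  st <- series$states
  counts <- state_counts(st, S)

  mu <- matrix(NA_real_, S, 2, dimnames = list(NULL, c("x1", "x2")))
  gamma0 <- mu
  gamma12 <- rep(NA_real_, S)
  for (s in seq_len(S)) {
    idx <- st == s
    if (!any(idx)) next
    mu[s, ] <- colMeans(x[idx, , drop = FALSE])
    d1 <- x[idx, 1] - mu[s, 1]
    d2 <- x[idx, 2] - mu[s, 2]
    gamma0[s, ] <- c(mean(d1^2), mean(d2^2))
    gamma12[s] <- mean(d1 * d2)
  }

  gamma_lag <- array(NA_real_, c(S, S, 2))
  r_t <- st[-series$n]
  s_t <- st[-1]
  for (r in seq_len(S)) for (s in seq_len(S)) {
    idx <- which(r_t == r & s_t == s)  # positions t-1; observation t = idx+1
    if (!length(idx)) next
    for (i in 1:2)
      gamma_lag[r, s, i] <- mean((x[idx + 1, i] - mu[s, i]) *
                                 (x[idx, i] - mu[r, i]))
  }

  structure(list(mu = mu, gamma0 = gamma0, gamma12 = gamma12,
                 gamma_lag = gamma_lag, counts = counts, n = series$n, S = S),
            class = "cubinar_moments")
}

#' Yule-Walker estimation of the Poi-CuBINAR(1) model
#'
#' Method-of-moments estimators built from [sample_moments()]:
#' \deqn{\hat\alpha_i = \sum_{r,s} \frac{n_{r,s}}{n - 1}
#'   \frac{\hat\gamma_i(r, s)}{\hat\gamma_{ii,0}(r)}, \qquad
#'   \hat\lambda_i(s) = \hat\mu_i(s), \qquad
#'   \hat\phi = \sum_s \frac{n_s}{n} \hat\gamma_{12,0}(s).}
#' Estimates outside the box `[0, 1)` for the thinning probabilities or
#' below 0 for `phi` (a small-sample event) are clipped to the boundary and
#' the clipping recorded on the returned object.
#'
#' @param series a [cubinar_series()]; every regime must be visited at
#'   least twice and have positive regime-conditional variance for both
#'   components.
#' @return an object of class `"cubinar_fit"` with elements `params`,
#'   `method = "yw"`, `clipped` (character vector of clipped parameter
#'   names), and `moments`.
#' @seealso [cml_fit()] for the likelihood-based estimator.
#' @export
yw_fit <- function(series) {
  m <- sample_moments(series)
  S <- m$S
  if (any(m$counts$n_s < 2))
    stop("regime(s) ", paste(which(m$counts$n_s < 2), collapse = ", "),
         " visited fewer than twice; Yule-Walker estimation needs every ",
         "regime occupied")
  if (any(m$gamma0 <= 0))
    stop("zero regime-conditional variance in regime(s) ",
         paste(which(apply(m$gamma0 <= 0, 1, any)), collapse = ", "),
         "; the lag-ratio estimator of alpha is undefined")

  n <- m$n
  alpha <- numeric(2)
  for (i in 1:2) {
    term <- m$gamma_lag[, , i] / matrix(m$gamma0[, i], S, S)
    w <- m$counts$n_rs / (n - 1)
    alpha[i] <- sum(w * term, na.rm = TRUE)
  }
  phi <- sum(m$counts$n_s / n * m$gamma12)

  clipped <- character(0)
  for (i in 1:2) {
    if (alpha[i] < 0) { alpha[i] <- 0; clipped <- c(clipped, paste0("alpha", i)) }
    if (alpha[i] >= 1) { alpha[i] <- 1 - 1e-6; clipped <- c(clipped, paste0("alpha", i)) }
  }
  if (phi < 0) { phi <- 0; clipped <- c(clipped, "phi") }

  params <- cubinar_params(alpha[1], alpha[2], phi,
                           lambda1 = m$mu[, 1], lambda2 = m$mu[, 2])
  new_cubinar_fit(params = params, method = "yw", clipped = clipped,
                  moments = m, n = n, converged = TRUE)
}

new_cubinar_fit <- function(params, method, n, converged,
                            loglik = NULL, se = NULL, vcov = NULL,
                            clipped = character(0), moments = NULL,
                            boundary = FALSE, optim_info = NULL) {
  structure(list(params = params, method = method, n = n,
                 converged = converged, loglik = loglik, se = se,
                 vcov = vcov, clipped = clipped, moments = moments,
                 boundary = boundary, optim_info = optim_info,
                 n_params = as.integer(2 * params$S + 3)),
            class = "cubinar_fit")
}

#' @export
coef.cubinar_fit <- function(object, ...) coef(object$params)

#' @export
logLik.cubinar_fit <- function(object, ...) {
  if (is.null(object$loglik))
    stop("no log-likelihood stored for a ", object$method, " fit; ",
         "use cubinar_loglik() to evaluate it")
  structure(object$loglik, df = object$n_params, nobs = object$n - 1,
            class = "logLik")
}

#' @export
print.cubinar_fit <- function(x, ...) {
  cat(sprintf("Poi-CuBINAR(1) fit (%s), n = %d, %d regime%s\n",
              toupper(x$method), x$n, x$params$S,
              if (x$params$S == 1) "" else "s"))
  est <- coef(x)
  tab <- data.frame(estimate = est)
  if (!is.null(x$se)) tab$std.error <- x$se[names(est)]
  print(round(tab, 4))
  if (!is.null(x$loglik))
    cat(sprintf("logLik = %.3f, AIC = %.1f\n", x$loglik,
                2 * x$n_params - 2 * x$loglik))
  if (length(x$clipped))
    cat("clipped to boundary:", paste(x$clipped, collapse = ", "), "\n")
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  if (x$boundary) cat("note: estimate on or near the feasibility boundary\n")
  invisible(x)
}

#' One-step transition probability of the Poi-CuBINAR(1) model
#'
#' Evaluates \eqn{P(X_t = x \mid X_{t-1} = x_{prev})} for the regime
#' transition `r -> s`: the double binomial convolution over the thinning
#' survivors of each component against the bivariate Poisson innovation pmf
#' of that transition. This is the pure-R reference route; the model
#' likelihood ([cubinar_loglik()]) evaluates the same quantity through a
#' compiled kernel.
#'
#' @param x,x_prev integer pairs `c(x1, x2)` of current and previous
#'   counts.
#' @param params a feasible [cubinar_params()] object.
#' @param r regime at `t-1`; `s` regime at `t`.
#' @param s see `r`.
#' @param log logical; return the log probability?
#' @return a probability in `(0, 1]` (or its log).
#' @export
transition_pmf <- function(x, x_prev, params, r, s, log = FALSE) {
  stop_if_infeasible(params)
  stopifnot(length(x) == 2, length(x_prev) == 2,
            all(x >= 0), all(x_prev >= 0))
  ip <- innovation_params(params, r, s)
  k <- 0:min(x[1], x_prev[1])
  l <- 0:min(x[2], x_prev[2])
  b1 <- dbinom(k, x_prev[1], params$alpha1)
  b2 <- dbinom(l, x_prev[2], params$alpha2)
  kl <- expand.grid(k = k, l = l)
  f <- exp(bpoi_logpmf_cpp(as.integer(x[1] - kl$k), as.integer(x[2] - kl$l),
                           ip$lambda1_star, ip$lambda2_star, ip$phi_star))
  p <- sum(as.vector(outer(b1, b2)) * f)
  if (log) base::log(p) else p
}

#' Conditional log-likelihood of a Poi-CuBINAR(1) parameter vector
#'
#' \eqn{L = \sum_{t=2}^n \log P(X_t(s_t) \mid X_{t-1}(s_{t-1}))}, the sum
#' of log one-step transition probabilities given the realized regime path.
#' Evaluated by a compiled kernel that tabulates the innovation pmfs per
#' regime transition. Infeasible parameters yield `-Inf` (useful as an
#' optimizer penalty) unless `strict = TRUE`, in which case they raise an
#' error.
#'
#' @param series a [cubinar_series()].
#' @param params a [cubinar_params()] object.
#' @param strict error on infeasible parameters instead of returning
#'   `-Inf`?
#' @return a scalar log-likelihood.
#' @export
cubinar_loglik <- function(series, params, strict = FALSE) {
  stopifnot(inherits(series, "cubinar_series"),
            inherits(params, "cubinar_params"))
  if (series$S > params$S)
    stop("series uses regime labels beyond the parameter regime set")
  if (strict) stop_if_infeasible(params)
  cubinar_loglik_cpp(series$x1, series$x2, series$states,
                     params$alpha1, params$alpha2,
                     params$lambda1, params$lambda2, params$phi)
}

## ---- CML machinery -------------------------------------------------------

# unconstrained working scale: logit for alphas, log for phi and lambdas
par_to_theta <- function(p) {
  c(qlogis(p$alpha1), qlogis(p$alpha2), log(p$phi),
    log(p$lambda1), log(p$lambda2))
}

theta_to_par <- function(theta, S) {
  cubinar_params(plogis(theta[1]), plogis(theta[2]), exp(theta[3]),
                 lambda1 = exp(theta[3 + 1:S]),
                 lambda2 = exp(theta[3 + S + 1:S]))
}

# nudge a (possibly boundary or infeasible) init strictly inside the
# feasible region: epsilon pushback off the box edges, then shrink phi and,
# if needed, the alphas until every Remark-type inequality has slack
feasible_init <- function(p, eps = 1e-3) {
  a1 <- min(max(p$alpha1, eps), 1 - eps)
  a2 <- min(max(p$alpha2, eps), 1 - eps)
  phi <- max(p$phi, eps)
  l1 <- pmax(p$lambda1, eps)
  l2 <- pmax(p$lambda2, eps)
  p <- cubinar_params(a1, a2, phi, l1, l2)
  for (k in 1:200) {
    if (validate_params(p)$feasible) return(p)
    phi <- phi * 0.7
    if (k > 25) { a1 <- a1 * 0.9; a2 <- a2 * 0.9 }
    p <- cubinar_params(a1, a2, max(phi, 1e-8), l1, l2)
  }
  stop("could not construct a feasible starting value")
}

#' Conditional maximum likelihood estimation
#'
#' Maximizes the conditional log-likelihood over an unconstrained working
#' scale (logit for the thinning probabilities, log for `phi` and the
#' regime means), with the feasibility inequalities of the innovation laws
#' enforced through a penalty: infeasible proposals score `-Inf` and are
#' rejected by the line search. The optimizer is BFGS started at the
#' Yule-Walker estimate (pushed strictly inside the feasible region when
#' the YW solution sits on a boundary); on failure it restarts once from a
#' perturbed point and falls back to Nelder-Mead. Approximate standard
#' errors come from the observed information: a central-difference Hessian
#' of the log-likelihood on the working scale at the optimum (relative step
#' `1e-5`), inverted and delta-method mapped back to the natural scale.
#'
#' @param series a [cubinar_series()]; same occupancy requirements as
#'   [yw_fit()].
#' @param init optional [cubinar_params()] starting value; default is the
#'   Yule-Walker fit.
#' @param se compute approximate standard errors? Skipping them
#'   (`se = FALSE`) saves the Hessian evaluations in large Monte-Carlo
#'   studies.
#' @param control passed to [stats::optim()] (maxit etc.).
#' @return a `"cubinar_fit"` with `method = "cml"`, the maximized `loglik`,
#'   standard errors (`se`, on the natural scale) and convergence status.
#'   Non-convergence is reported in the `converged` flag, never silently.
#' @export
cml_fit <- function(series, init = NULL, se = TRUE, control = list()) {
  stopifnot(inherits(series, "cubinar_series"))
  if (is.null(init)) {
    ywf <- yw_fit(series)
    init <- ywf$params
  } else {
    stopifnot(inherits(init, "cubinar_params"))
    if (init$S != series$S)
      stop("init has ", init$S, " regimes but the series has ", series$S)
  }
  init <- feasible_init(init)
  S <- init$S
  x1 <- series$x1; x2 <- series$x2; st <- series$states

  nll <- function(theta) {
    if (any(!is.finite(theta))) return(1e10)
    a1 <- plogis(theta[1]); a2 <- plogis(theta[2]); phi <- exp(theta[3])
    ll <- cubinar_loglik_cpp(x1, x2, st, a1, a2,
                             exp(theta[3 + 1:S]), exp(theta[3 + S + 1:S]),
                             phi)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  theta0 <- par_to_theta(init)
  ctl <- modifyList(list(maxit = 500), control)
  opt <- optim(theta0, nll, method = "BFGS", control = ctl)
  if (opt$convergence != 0) {
    # one perturbed restart, then a simplex pass, before reporting failure
    opt2 <- optim(opt$par + runif(length(theta0), -0.05, 0.05), nll,
                  method = "BFGS", control = ctl)
    if (opt2$value < opt$value) opt <- opt2
    if (opt$convergence != 0) {
      opt3 <- optim(opt$par, nll, method = "Nelder-Mead",
                    control = modifyList(ctl, list(maxit = 2000)))
      if (opt3$value <= opt$value) opt <- opt3
    }
  }
  # never return something worse than the start
  if (opt$value > nll(theta0) + 1e-8) {
    opt$par <- theta0
    opt$value <- nll(theta0)
    opt$convergence <- 1L
  }

  params <- theta_to_par(opt$par, S)
  se_vec <- NULL; vcov <- NULL
  if (se) {
    h <- num_hessian(nll, opt$par)
    se_vec <- rep(NA_real_, length(opt$par))
    vc_theta <- try(solve(h), silent = TRUE)
    if (!inherits(vc_theta, "try-error") && all(diag(vc_theta) > 0)) {
      # delta method: d(natural)/d(working) is diagonal
      jac <- c(params$alpha1 * (1 - params$alpha1),
               params$alpha2 * (1 - params$alpha2),
               params$phi, params$lambda1, params$lambda2)
      vcov <- vc_theta * tcrossprod(jac)
      se_vec <- sqrt(diag(vcov))
    }
    names(se_vec) <- param_names(S)
    if (!is.null(vcov)) dimnames(vcov) <- list(param_names(S), param_names(S))
  }

  # the feasible set is open; an estimate whose smallest innovation-rate
  # margin (or distance to the alpha box edge) has collapsed is a boundary
  # solution, not an interior maximum
  phi_star <- params$phi * (1 - params$alpha1 * params$alpha2)
  margins <- outer(seq_len(S), seq_len(S), function(r, s)
    pmin(params$lambda1[s] - params$alpha1 * params$lambda1[r],
         params$lambda2[s] - params$alpha2 * params$lambda2[r]) - phi_star)
  boundary <- min(margins) < 1e-3 * (1 + max(params$lambda1, params$lambda2)) ||
    max(params$alpha1, params$alpha2) > 1 - 1e-4
  new_cubinar_fit(params = params, method = "cml", n = series$n,
                  converged = opt$convergence == 0, loglik = -opt$value,
                  se = se_vec, vcov = vcov, boundary = boundary,
                  optim_info = opt[c("convergence", "counts", "message")])
}

# central-difference Hessian with relative step; enough for standard
# errors without pulling in a differentiation package
num_hessian <- function(f, x, rel = 1e-5) {
  p <- length(x)
  h <- rel * pmax(abs(x), 1)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- numeric(p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' @importFrom utils modifyList
NULL

#' Plain-text report of a fitted model
#'
#' @param fit a `"cubinar_fit"`.
#' @return a character vector of report lines (estimates, standard errors
#'   where available, log-likelihood, AIC, convergence and clipping flags).
#' @export
report_fit <- function(fit) {
  stopifnot(inherits(fit, "cubinar_fit"))
  est <- coef(fit)
  lines <- c(sprintf("method: %s", fit$method),
             sprintf("n: %d", fit$n),
             sprintf("regimes: %d", fit$params$S),
             sprintf("converged: %s", fit$converged))
  for (nm in names(est)) {
    se_txt <- if (!is.null(fit$se) && is.finite(fit$se[nm]))
      sprintf(" (se %.4f)", fit$se[nm]) else ""
    lines <- c(lines, sprintf("%s: %.6f%s", nm, est[nm], se_txt))
  }
  if (!is.null(fit$loglik))
    lines <- c(lines, sprintf("loglik: %.6f", fit$loglik),
               sprintf("aic: %.4f", 2 * fit$n_params - 2 * fit$loglik))
  if (length(fit$clipped))
    lines <- c(lines, paste("clipped:", paste(fit$clipped, collapse = ",")))
  lines
}
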