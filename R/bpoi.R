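#' Bivariate Poisson distribution
#'
#' Density, sampling and probability generating function for the bivariate
#' Poisson law \eqn{BPoi(\lambda_1, \lambda_2, \phi)}, parameterized by the
#' two marginal means and the (nonnegative) covariance. The law is that of
#' \eqn{(U + W, V + W)} with independent Poisson components
#' \eqn{U \sim Poi(\theta_1)}, \eqn{V \sim Poi(\theta_2)},
#' \eqn{W \sim Poi(\theta_{12})}, where \eqn{\theta_i = \lambda_i - \phi} and
#' \eqn{\theta_{12} = \phi}.
#'
#' `dbpoi()` evaluates the pmf
#' \deqn{f(x_1, x_2) = e^{-(\theta_1 + \theta_2 + \theta_{12})}
#'   \sum_{i=0}^{\min(x_1, x_2)}
#'   \frac{\theta_1^{x_1 - i}\,\theta_2^{x_2 - i}\,\theta_{12}^i}
#'        {(x_1 - i)!\,(x_2 - i)!\,i!}}
#' with the finite sum accumulated in log space (log-sum-exp with a running
#' maximum), so counts up to the order of 10^3 are handled without overflow.
#'
#' @param x1,x2 nonnegative integer count vectors (recycled to a common
#'   length).
#' @param lambda1,lambda2 marginal means, strictly positive.
#' @param phi covariance between the components, `0 <= phi < min(lambda1,
#'   lambda2)`. `phi = 0` gives two independent Poissons.
#' @param log logical; return the log pmf?
#' @return `dbpoi()` returns a numeric vector of (log) probabilities.
#' @examples
#' dbpoi(0, 0, 2, 3, 0.5)           # exp(-(1.5 + 2.5 + 0.5))
#' rbpoi(5, 2, 3, 0.5)
#' bpoi_pgf(1, 1, 2, 3, 0.5)        # 1
#' @export
dbpoi <- function(x1, x2, lambda1, lambda2, phi, log = FALSE) {
  th <- bpoi_mean_to_component(lambda1, lambda2, phi)
  n <- max(length(x1), length(x2))
  x1 <- rep_len(as.integer(x1), n)
  x2 <- rep_len(as.integer(x2), n)
  if (any(x1 < 0) || any(x2 < 0)) stop("counts must be nonnegative")
  out <- bpoi_logpmf_cpp(x1, x2, th$theta1, th$theta2, th$theta12)
  if (log) out else exp(out)
}

#' @rdname dbpoi
#' @param n number of draws.
#' @details `rbpoi()` samples by trivariate reduction: three independent
#'   Poisson draws per observation, exact and O(1) per draw.
#' @return `rbpoi()` returns an `n` x 2 integer matrix with columns
#'   `x1`, `x2`.
#' @export
rbpoi <- function(n, lambda1, lambda2, phi) {
  th <- bpoi_mean_to_component(lambda1, lambda2, phi)
  w <- rpois(n, th$theta12)
  cbind(x1 = rpois(n, th$theta1) + w,
        x2 = rpois(n, th$theta2) + w)
}

#' @rdname dbpoi
#' @param a1,a2 arguments of the probability generating function, in
#'   `[0, 1]`.
#' @details The pgf is
#'   \eqn{E[a_1^{X_1} a_2^{X_2}] = \exp\{\lambda_1(a_1 - 1) +
#'   \lambda_2(a_2 - 1) + \phi(a_1 - 1)(a_2 - 1)\}}.
#' @export
bpoi_pgf <- function(a1, a2, lambda1, lambda2, phi) {
  bpoi_mean_to_component(lambda1, lambda2, phi)  # validates the law
  stopifnot(all(a1 >= 0 & a1 <= 1), all(a2 >= 0 & a2 <= 1))
  exp(lambda1 * (a1 - 1) + lambda2 * (a2 - 1) + phi * (a1 - 1) * (a2 - 1))
}

#' Convert between the two bivariate Poisson parameterizations
#'
#' The mean/covariance parameterization \eqn{(\lambda_1, \lambda_2, \phi)}
#' and the independent-component parameterization \eqn{(\theta_1, \theta_2,
#' \theta_{12})} are linked by \eqn{\theta_i = \lambda_i - \phi},
#' \eqn{\theta_{12} = \phi}; the maps are exact inverses of each other.
#'
#' @inheritParams dbpoi
#' @return a list with elements `theta1`, `theta2`, `theta12`
#'   (resp. `lambda1`, `lambda2`, `phi`).
#' @export
bpoi_mean_to_component <- function(lambda1, lambda2, phi) {
  if (any(phi < 0)) stop("phi must be nonnegative")
  if (any(lambda1 - phi <= 0) || any(lambda2 - phi <= 0))
    stop("infeasible bivariate Poisson law: need lambda_i > phi ",
         "(component rates must be positive)")
  list(theta1 = lambda1 - phi, theta2 = lambda2 - phi, theta12 = phi)
}

#' @rdname bpoi_mean_to_component
#' @param theta1,theta2 rates of the independent parts, strictly positive.
#' @param theta12 rate of the shared part, nonnegative.
#' @export
bpoi_component_to_mean <- function(theta1, theta2, theta12) {
  if (any(theta1 <= 0) || any(theta2 <= 0)) stop("theta1, theta2 must be > 0")
  if (any(theta12 < 0)) stop("theta12 must be nonnegative")
  list(lambda1 = theta1 + theta12, lambda2 = theta2 + theta12, phi = theta12)
}
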