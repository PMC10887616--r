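#' CuBINAR(1) parameter container
#'
#' Bundles the full parameter vector of the circumstance-driven bivariate
#' Poisson INAR(1) model: thinning probabilities `alpha1`, `alpha2`, the
#' cross-covariance `phi`, and the regime-wise marginal means
#' `lambda1[s]`, `lambda2[s]` for `s` in `1..S`. `S = 1` gives the
#' stationary bivariate Poisson INAR(1) special case.
#'
#' Structural validity (`0 <= alpha_i < 1`, `phi >= 0`,
#' `lambda_i(s) > 0`) is enforced here; the deeper feasibility conditions
#' that make the innovation laws well defined are checked by
#' [validate_params()].
#'
#' @param alpha1,alpha2 binomial-thinning survival probabilities, in
#'   `[0, 1)`.
#' @param phi cross-covariance of the observations, `phi >= 0`.
#' @param lambda1,lambda2 numeric vectors of length `S` of regime-wise
#'   marginal means, strictly positive.
#' @return an object of class `"cubinar_params"`.
#' @examples
#' p <- cubinar_params(0.15, 0.2, 0.5, lambda1 = 1:3, lambda2 = 4:6)
#' validate_params(p)$feasible
#' @export
cubinar_params <- function(alpha1, alpha2, phi, lambda1, lambda2) {
  lambda1 <- as.numeric(lambda1)
  lambda2 <- as.numeric(lambda2)
  if (length(lambda1) != length(lambda2))
    stop("lambda1 and lambda2 must have one mean per regime (equal length)")
  S <- length(lambda1)
  if (S < 1) stop("need at least one regime")
  stopifnot(length(alpha1) == 1, length(alpha2) == 1, length(phi) == 1)
  if (alpha1 < 0 || alpha1 >= 1 || alpha2 < 0 || alpha2 >= 1)
    stop("alpha1, alpha2 must lie in [0, 1)")
  if (phi < 0) stop("phi must be nonnegative")
  if (any(lambda1 <= 0) || any(lambda2 <= 0))
    stop("all regime means lambda_i(s) must be strictly positive")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, phi = phi,
                 lambda1 = lambda1, lambda2 = lambda2, S = S),
            class = "cubinar_params")
}

#' @export
print.cubinar_params <- function(x, ...) {
  cat(if (x$S == 1) "Stationary Poi-BINAR(1) parameters\n"
      else sprintf("Poi-CuBINAR(1) parameters (%d regimes)\n", x$S))
  cat(sprintf("  alpha1 = %.4g, alpha2 = %.4g, phi = %.4g (phi* = %.4g)\n",
              x$alpha1, x$alpha2, x$phi, x$phi * (1 - x$alpha1 * x$alpha2)))
  lam <- rbind(lambda1 = x$lambda1, lambda2 = x$lambda2)
  colnames(lam) <- paste0("s=", seq_len(x$S))
  print(lam)
  invisible(x)
}

#' @export
coef.cubinar_params <- function(object, ...) {
  setNames(c(object$alpha1, object$alpha2, object$phi,
             object$lambda1, object$lambda2),
           param_names(object$S))
}

param_names <- function(S) {
  c("alpha1", "alpha2", "phi",
    paste0("lambda1(", 1:S, ")"), paste0("lambda2(", 1:S, ")"))
}

#' Feasibility of a CuBINAR(1) parameter vector
#'
#' The bivariate Poisson innovation law for the regime transition
#' `r -> s` has independent-component rates
#' \eqn{\lambda_i^* = \lambda_i(s) - \alpha_i \lambda_i(r) - \phi^*} with
#' \eqn{\phi^* = \phi(1 - \alpha_1\alpha_2)}. All `2 * S^2` of these must be
#' strictly positive for the model to exist; this function checks every
#' (component, r, s) triple and reports the violated ones.
#'
#' @param p a [cubinar_params()] object.
#' @return a list with `feasible` (logical) and `violations`, a data frame
#'   with columns `component`, `r` (regime at `t-1`), `s` (regime at `t`)
#'   and `margin` (the value of the left-hand side, `<= 0` when violated).
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "cubinar_params"))
  phi_star <- p$phi * (1 - p$alpha1 * p$alpha2)
  lam <- list(p$lambda1, p$lambda2)
  alpha <- c(p$alpha1, p$alpha2)
  grid <- expand.grid(component = 1:2, r = seq_len(p$S), s = seq_len(p$S))
  margin <- mapply(function(i, r, s) lam[[i]][s] - alpha[i] * lam[[i]][r] - phi_star,
                   grid$component, grid$r, grid$s)
  bad <- margin <= 0
  list(feasible = !any(bad),
       violations = cbind(grid[bad, , drop = FALSE],
                          margin = margin[bad]))
}

stop_if_infeasible <- function(p) {
  v <- validate_params(p)
  if (!v$feasible) {
    w <- v$violations[1, ]
    stop(sprintf(paste0("infeasible CuBINAR(1) parameters: lambda%d(%d) - ",
                        "alpha%d * lambda%d(%d) - phi* = %.4g <= 0 ",
                        "(%d violated inequalit%s in total)"),
                 w$component, w$s, w$component, w$component, w$r, w$margin,
                 nrow(v$violations),
                 if (nrow(v$violations) == 1) "y" else "ies"))
  }
  invisible(p)
}

#' Innovation law for a regime transition
#'
#' Parameters of the bivariate Poisson innovation
#' \eqn{\epsilon_t(s, r) \sim BPoi(\mu_1(s,r), \mu_2(s,r), \phi^*)} that
#' keeps the observations marginally `BPoi(lambda1[s], lambda2[s], phi)`:
#' means \eqn{\mu_i(s, r) = \lambda_i(s) - \alpha_i \lambda_i(r)}, shared
#' rate \eqn{\phi^* = \phi(1 - \alpha_1\alpha_2)}, and component rates
#' \eqn{\lambda_i^* = \mu_i(s, r) - \phi^*}.
#'
#' @param p a feasible [cubinar_params()] object.
#' @param r regime at time `t-1`.
#' @param s regime at time `t`.
#' @return a list with `mu1`, `mu2`, `phi_star`, `lambda1_star`,
#'   `lambda2_star`.
#' @export
innovation_params <- function(p, r, s) {
  stopifnot(inherits(p, "cubinar_params"),
            r >= 1, r <= p$S, s >= 1, s <= p$S)
  phi_star <- p$phi * (1 - p$alpha1 * p$alpha2)
  mu1 <- p$lambda1[s] - p$alpha1 * p$lambda1[r]
  mu2 <- p$lambda2[s] - p$alpha2 * p$lambda2[r]
  l1s <- mu1 - phi_star
  l2s <- mu2 - phi_star
  if (l1s <= 0 || l2s <= 0) {
    i <- if (l1s <= 0) 1L else 2L
    stop(sprintf(paste0("infeasible regime transition %d -> %d: lambda%d(%d)",
                        " - alpha%d * lambda%d(%d) - phi* = %.4g <= 0"),
                 r, s, i, s, i, i, r, min(l1s, l2s)))
  }
  list(mu1 = mu1, mu2 = mu2, phi_star = phi_star,
       lambda1_star = l1s, lambda2_star = l2s)
}

#' Bivariate count series with aligned regime labels
#'
#' Light container pairing the two count sequences with their circumstance
#' path. Constructed directly, by [simulate_cubinar()], or by
#' [read_series()].
#'
#' @param x1,x2 nonnegative integer count vectors of common length.
#' @param states integer regime labels in `{1..S}`, same length.
#' @param S regime-space size; defaults to `max(states)`. May exceed the
#'   observed labels (e.g. to fit a model whose regime set is known a
#'   priori), in which case estimation will fail with a clear error for the
#'   unvisited regime.
#' @return an object of class `"cubinar_series"`.
#' @export
cubinar_series <- function(x1, x2, states, S = max(states)) {
  n <- length(x1)
  if (length(x2) != n || length(states) != n)
    stop("x1, x2 and states must have the same length")
  x1 <- as.integer(x1); x2 <- as.integer(x2); states <- as.integer(states)
  if (any(is.na(x1)) || any(is.na(x2)) || any(is.na(states)))
    stop("missing values are not allowed")
  if (any(x1 < 0) || any(x2 < 0)) stop("counts must be nonnegative")
  if (any(states < 1L) || any(states > S))
    stop("state labels must lie in {1..", S, "}")
  structure(list(x1 = x1, x2 = x2, states = states, S = as.integer(S), n = n),
            class = "cubinar_series")
}

#' @export
print.cubinar_series <- function(x, ...) {
  cat(sprintf("Bivariate count series: n = %d, %d regime%s\n",
              x$n, x$S, if (x$S == 1) "" else "s"))
  print(head(as.data.frame(x), 6))
  if (x$n > 6) cat("... (", x$n - 6, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cubinar_series <- function(x, ...) {
  data.frame(t = seq_len(x$n), x1 = x$x1, x2 = x$x2, state = x$states)
}

#' @export
length.cubinar_series <- function(x) x$n

#' Simulate a Poi-CuBINAR(1) series
#'
#' Exact simulation of the recursion: the initial pair is drawn from the
#' marginal bivariate Poisson law of the initial regime (so there is no
#' burn-in), and each subsequent pair is an independent binomial thinning of
#' its predecessor plus a bivariate Poisson innovation for the realized
#' regime transition. The thinnings of the two components use independent
#' randomness given the counts (the thinning matrix is diagonal).
#'
#' @param params a feasible [cubinar_params()] object.
#' @param states integer regime path; alternatively supply `chain` and `n`
#'   to draw one.
#' @param n series length, required when `states` is not given.
#' @param chain a [markov_chain_spec()] used to draw `states` when they are
#'   not supplied.
#' @param seed optional integer seed.
#' @return a [cubinar_series()]. If some regime is never visited the series
#'   carries a warning, since parameters of that regime cannot be estimated
#'   from it.
#' @examples
#' p <- cubinar_params(0.15, 0.2, 0.5, lambda1 = 1:3, lambda2 = 4:6)
#' ch <- markov_chain_spec(c(0.33, 0.33, 0.34),
#'                         matrix(c(0.4, 0.3, 0.3,
#'                                  0.3, 0.4, 0.3,
#'                                  0.3, 0.3, 0.4), 3, byrow = TRUE))
#' y <- simulate_cubinar(p, chain = ch, n = 200, seed = 1)
#' @export
simulate_cubinar <- function(params, states = NULL, n = NULL, chain = NULL,
                             seed = NULL) {
  stop_if_infeasible(params)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(states)) {
    if (is.null(chain) || is.null(n))
      stop("supply either `states`, or `chain` and `n`")
    if (chain$S != params$S)
      stop("chain has ", chain$S, " states but params has ", params$S)
    states <- simulate_states(chain, n)
  }
  states <- as.integer(states)
  n <- length(states)
  if (n < 1) stop("states must be nonempty")
  if (any(states < 1L) || any(states > params$S))
    stop("state labels must lie in {1..", params$S, "}")

  a1 <- params$alpha1; a2 <- params$alpha2
  phi_star <- params$phi * (1 - a1 * a2)

  x1 <- integer(n); x2 <- integer(n)
  first <- rbpoi(1, params$lambda1[states[1]], params$lambda2[states[1]],
                 params$phi)
  x1[1] <- first[1, 1]; x2[1] <- first[1, 2]

  if (n > 1) {
    r <- states[-n]; s <- states[-1]
    l1s <- params$lambda1[s] - a1 * params$lambda1[r] - phi_star
    l2s <- params$lambda2[s] - a2 * params$lambda2[r] - phi_star
    # innovations are independent of the past: draw them vectorized up front
    w <- rpois(n - 1, phi_star)
    e1 <- rpois(n - 1, l1s) + w
    e2 <- rpois(n - 1, l2s) + w
    for (t in 2:n) {
      x1[t] <- rbinom(1L, x1[t - 1], a1) + e1[t - 1]
      x2[t] <- rbinom(1L, x2[t - 1], a2) + e2[t - 1]
    }
  }
  visited <- tabulate(states, nbins = params$S)
  if (any(visited == 0))
    warning("regime(s) ", paste(which(visited == 0), collapse = ", "),
            " never visited; their parameters cannot be estimated from ",
            "this series")
  cubinar_series(x1, x2, states, S = params$S)
}
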