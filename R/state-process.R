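#' Markov-chain specification for the circumstance process
#'
#' The model itself treats the regime ("circumstance") path as observed;
#' simulating it from a Markov chain is a scenario-generation convenience.
#' Row `r` of the transition matrix holds `P(s_t = s | s_{t-1} = r)`.
#'
#' @param p0 initial probability vector of length `S` (nonnegative, sums
#'   to 1).
#' @param P `S` x `S` transition probability matrix; each row a probability
#'   vector.
#' @return an object of class `"markov_chain_spec"` with elements `S`,
#'   `p0`, `P`.
#' @examples
#' ch <- markov_chain_spec(c(0.5, 0.5), rbind(c(0.4, 0.6), c(0.6, 0.4)))
#' simulate_states(ch, 10, seed = 1)
#' @export
markov_chain_spec <- function(p0, P) {
  p0 <- as.numeric(p0)
  P <- as.matrix(P)
  S <- length(p0)
  if (S < 1) stop("need at least one state")
  if (!all(dim(P) == c(S, S)))
    stop("P must be ", S, " x ", S, " to match p0")
  check_stochastic <- function(v, what) {
    if (any(v < 0) || abs(sum(v) - 1) > 1e-8)
      stop(what, " must be a probability vector (nonnegative, summing to 1)")
  }
  check_stochastic(p0, "p0")
  for (r in seq_len(S)) check_stochastic(P[r, ], paste0("row ", r, " of P"))
  structure(list(S = S, p0 = p0, P = P), class = "markov_chain_spec")
}

#' @export
print.markov_chain_spec <- function(x, ...) {
  cat("Markov chain on {1..", x$S, "}\n", sep = "")
  cat("p0:", format(x$p0), "\n")
  cat("P:\n")
  print(x$P)
  invisible(x)
}

#' Simulate a circumstance state path
#'
#' Draws `s_1` from the initial distribution and each subsequent state from
#' the transition row of its predecessor. States are 1-based labels in
#' `{1..S}`.
#'
#' @param spec a [markov_chain_spec()].
#' @param n path length, `n >= 1`.
#' @param seed optional integer seed for reproducibility.
#' @return integer vector of length `n` with attribute `S`.
#' @export
simulate_states <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "markov_chain_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  s <- integer(n)
  s[1] <- sample.int(spec$S, 1L, prob = spec$p0)
  if (n > 1)
    for (t in 2:n) s[t] <- sample.int(spec$S, 1L, prob = spec$P[s[t - 1], ])
  attr(s, "S") <- spec$S
  s
}

#' Occupancy and transition-pair counts of a state path
#'
#' Returns \eqn{n_s = \sum_t 1\{s_t = s\}} and
#' \eqn{n_{r,s} = \sum_{t \ge 2} 1\{s_{t-1} = r, s_t = s\}}, the divisors of
#' the state-conditional sample moments. Always satisfies
#' `sum(n_s) == n` and `sum(n_rs) == n - 1`.
#'
#' @param states integer state path with values in `{1..S}`.
#' @param S state-space size; defaults to the `S` attribute of `states` or,
#'   failing that, `max(states)`.
#' @return a list with `n_s` (length `S`) and `n_rs` (`S` x `S` matrix,
#'   rows = state at `t-1`).
#' @export
state_counts <- function(states, S = NULL) {
  states <- as.integer(states)
  if (is.null(S)) S <- attr(states, "S") %||% max(states)
  if (any(states < 1L) || any(states > S))
    stop("state labels must lie in {1..", S, "}")
  n <- length(states)
  n_s <- tabulate(states, nbins = S)
  n_rs <- matrix(0L, S, S)
  if (n > 1) {
    tab <- table(factor(states[-n], levels = 1:S),
                 factor(states[-1], levels = 1:S))
    n_rs <- matrix(as.integer(tab), S, S)
  }
  list(n_s = n_s, n_rs = n_rs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
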