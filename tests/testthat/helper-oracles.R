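# Brute-force reference implementations, deliberately written in the most
# direct arithmetic possible and kept independent of the package's code
# paths: plain factorials, triple loops, no tables, no log-space tricks.

oracle_bpoi_pmf <- function(x1, x2, t1, t2, t12) {
  s <- 0
  for (i in 0:min(x1, x2)) {
    term <- t1^(x1 - i) * t2^(x2 - i) *
      (if (t12 == 0 && i == 0) 1 else t12^i) /
      (factorial(x1 - i) * factorial(x2 - i) * factorial(i))
    s <- s + term
  }
  exp(-(t1 + t2 + t12)) * s
}

# one-step transition probability by direct enumeration of the thinning
# survivors against the innovation pmf
oracle_trans_prob <- function(x1t, x2t, x1p, x2p, alpha1, alpha2,
                              lam1_star, lam2_star, phi_star) {
  p <- 0
  for (k in 0:min(x1t, x1p)) {
    for (l in 0:min(x2t, x2p)) {
      p <- p + choose(x1p, k) * alpha1^k * (1 - alpha1)^(x1p - k) *
        choose(x2p, l) * alpha2^l * (1 - alpha2)^(x2p - l) *
        oracle_bpoi_pmf(x1t - k, x2t - l, lam1_star, lam2_star, phi_star)
    }
  }
  p
}

# termwise conditional log-likelihood built on the oracle transition
oracle_loglik <- function(series, p) {
  phi_star <- p$phi * (1 - p$alpha1 * p$alpha2)
  L <- 0
  for (t in 2:series$n) {
    r <- series$states[t - 1]; s <- series$states[t]
    l1s <- p$lambda1[s] - p$alpha1 * p$lambda1[r] - phi_star
    l2s <- p$lambda2[s] - p$alpha2 * p$lambda2[r] - phi_star
    L <- L + log(oracle_trans_prob(series$x1[t], series$x2[t],
                                   series$x1[t - 1], series$x2[t - 1],
                                   p$alpha1, p$alpha2, l1s, l2s, phi_star))
  }
  L
}

# a tiny hand-checkable two-regime series
toy_series <- function() {
  cubinar_series(x1 = c(1, 2, 0, 3), x2 = c(4, 3, 5, 2),
                 states = c(1, 1, 2, 1), S = 2)
}

toy_params2 <- function() {
  cubinar_params(0.15, 0.2, 0.5, lambda1 = c(1, 3), lambda2 = c(3, 5))
}
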