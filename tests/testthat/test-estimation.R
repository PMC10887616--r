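test_that("regime-conditional sample moments match hand enumeration", {
  y <- toy_series()  # x1 = (1,2,0,3), x2 = (4,3,5,2), states (1,1,2,1)
  m <- sample_moments(y)

  # regime 1 holds observations t = 1, 2, 4; regime 2 holds t = 3
  expect_equal(m$mu[1, ], c(x1 = 2, x2 = 3))
  expect_equal(m$mu[2, ], c(x1 = 0, x2 = 5))
  expect_equal(unname(m$gamma0[1, "x1"]), mean((c(1, 2, 3) - 2)^2))
  expect_equal(unname(m$gamma0[2, "x1"]), 0)
  expect_equal(m$gamma12[1], mean((c(1, 2, 3) - 2) * (c(4, 3, 2) - 3)))

  # transitions: 1->1 at t=2, 1->2 at t=3, 2->1 at t=4
  expect_equal(m$gamma_lag[1, 1, 1], (2 - 2) * (1 - 2))
  expect_equal(m$gamma_lag[1, 2, 1], (0 - 0) * (2 - 2))
  expect_equal(m$gamma_lag[2, 1, 1], (3 - 2) * (0 - 0))
  expect_equal(m$gamma_lag[2, 1, 2], (2 - 3) * (5 - 5))
  expect_true(is.na(m$gamma_lag[2, 2, 1]))

  # constant series in one regime
  yc <- cubinar_series(rep(4, 5), rep(1, 5), rep(1, 5))
  mc <- sample_moments(yc)
  expect_equal(mc$mu[1, ], c(x1 = 4, x2 = 1))
  expect_equal(unname(mc$gamma0[1, ]), c(0, 0))
})

test_that("single-regime Yule-Walker collapses to the classical lag-1 ratio", {
  p <- cubinar_params(0.3, 0.5, 0.5, lambda1 = 3, lambda2 = 4)
  y <- simulate_cubinar(p, states = rep(1, 800), seed = 31)
  f <- yw_fit(y)
  n <- y$n
  direct <- function(x) {
    mu <- mean(x)
    sum((x[-1] - mu) * (x[-n] - mu)) / (n - 1) / mean((x - mu)^2)
  }
  expect_equal(unname(coef(f)["alpha1"]), direct(y$x1), tolerance = 1e-12)
  expect_equal(unname(coef(f)["alpha2"]), direct(y$x2), tolerance = 1e-12)
  expect_equal(unname(coef(f)["lambda1(1)"]), mean(y$x1))
})

test_that("Yule-Walker finds no dependence in independent Poisson pairs", {
  p <- cubinar_params(0, 0, 0, lambda1 = 2, lambda2 = 3)
  y <- simulate_cubinar(p, states = rep(1, 2e4), seed = 32)
  f <- yw_fit(y)
  est <- coef(f)
  expect_lt(abs(est["alpha1"]), 0.05)
  expect_lt(abs(est["alpha2"]), 0.05)
  expect_lt(abs(est["phi"]), 0.05)
})

test_that("Yule-Walker refuses unusable regime occupancy", {
  y <- cubinar_series(c(1, 2, 3, 4), c(1, 0, 2, 1), c(1, 1, 1, 1), S = 2)
  expect_error(yw_fit(y), "regime")
  yc <- cubinar_series(rep(2, 10), rpois(10, 3) + 1, rep(1, 10))
  expect_error(yw_fit(yc), "variance")
})

test_that("transition pmf reduces correctly and matches the oracle", {
  p <- toy_params2()
  ip <- innovation_params(p, 1, 2)

  # no previous counts: no thinning survivors, pure innovation law
  expect_equal(transition_pmf(c(2, 3), c(0, 0), p, 1, 2),
               dbpoi(2, 3, ip$mu1, ip$mu2, ip$phi_star), tolerance = 1e-14)

  # zero thinning probabilities: the innovation pmf regardless of history
  p0 <- cubinar_params(0, 0, 0.5, lambda1 = c(1, 3), lambda2 = c(3, 5))
  ip0 <- innovation_params(p0, 2, 1)
  expect_equal(transition_pmf(c(1, 2), c(7, 9), p0, 2, 1),
               dbpoi(1, 2, ip0$mu1, ip0$mu2, ip0$phi_star),
               tolerance = 1e-14)

  for (case in list(list(x = c(2, 3), xp = c(1, 4), r = 1, s = 2),
                    list(x = c(0, 0), xp = c(3, 2), r = 2, s = 2),
                    list(x = c(5, 1), xp = c(2, 2), r = 2, s = 1))) {
    ipc <- innovation_params(p, case$r, case$s)
    expect_equal(
      transition_pmf(case$x, case$xp, p, case$r, case$s),
      oracle_trans_prob(case$x[1], case$x[2], case$xp[1], case$xp[2],
                        p$alpha1, p$alpha2, ipc$lambda1_star,
                        ipc$lambda2_star, ipc$phi_star),
      tolerance = 1e-12)
  }
})

test_that("log-likelihood agrees with termwise reference routes", {
  p <- toy_params2()
  y <- toy_series()

  # compiled kernel vs the pure-R transition pmf, term by term
  terms <- sapply(2:y$n, function(t)
    transition_pmf(c(y$x1[t], y$x2[t]), c(y$x1[t - 1], y$x2[t - 1]),
                   p, y$states[t - 1], y$states[t], log = TRUE))
  expect_equal(cubinar_loglik(y, p), sum(terms), tolerance = 1e-10)

  # and vs the independent brute-force enumeration
  expect_equal(cubinar_loglik(y, p), oracle_loglik(y, p), tolerance = 1e-10)

  # n = 2: a single transition term
  y2 <- cubinar_series(c(1, 2), c(0, 1), c(1, 2), S = 2)
  expect_equal(cubinar_loglik(y2, p),
               transition_pmf(c(2, 1), c(1, 0), p, 1, 2, log = TRUE),
               tolerance = 1e-12)
})

test_that("phi = 0 factorizes the likelihood into two univariate INAR(1) fits", {
  p <- cubinar_params(0.3, 0.4, 0, lambda1 = c(1, 2), lambda2 = c(3, 4))
  y <- simulate_cubinar(p, states = rep(1:2, length.out = 40), seed = 41)

  inar_ll <- function(x, states, alpha, lambda) {
    L <- 0
    for (t in 2:length(x)) {
      mu <- lambda[states[t]] - alpha * lambda[states[t - 1]]
      k <- 0:min(x[t], x[t - 1])
      L <- L + log(sum(dbinom(k, x[t - 1], alpha) * dpois(x[t] - k, mu)))
    }
    L
  }
  expect_equal(cubinar_loglik(y, p),
               inar_ll(y$x1, y$states, 0.3, c(1, 2)) +
                 inar_ll(y$x2, y$states, 0.4, c(3, 4)),
               tolerance = 1e-10)
})

test_that("infeasible parameters yield -Inf (or an error in strict mode)", {
  y <- toy_series()
  bad <- cubinar_params(0.9, 0, 0, lambda1 = c(1, 10), lambda2 = c(1, 1))
  expect_identical(cubinar_loglik(y, bad), -Inf)
  expect_error(cubinar_loglik(y, bad, strict = TRUE), "infeasible")
})

test_that("CML improves on its initialization and recovers the truth", {
  p <- toy_params2()
  ch <- markov_chain_spec(c(0.5, 0.5), matrix(c(0.4, 0.6, 0.6, 0.4), 2,
                                              byrow = TRUE))
  y <- simulate_cubinar(p, chain = ch, n = 1500, seed = 51)
  ywf <- yw_fit(y)
  fit <- cml_fit(y)
  expect_true(fit$converged)
  expect_gte(fit$loglik, cubinar_loglik(y, ywf$params) - 1e-6)
  est <- coef(fit)
  truth <- coef(p)
  expect_lt(max(abs(est[c("alpha1", "alpha2")] -
                      truth[c("alpha1", "alpha2")])), 0.12)
  expect_lt(max(abs(est[grep("lambda", names(est))] -
                      truth[grep("lambda", names(truth))])), 0.4)
  expect_true(all(is.finite(fit$se)))

  # starting at the truth stays in its neighborhood
  fit2 <- cml_fit(y, init = p, se = FALSE)
  expect_lt(max(abs(coef(fit2) - est)), 0.02)
})

test_that("degenerate all-zero series is flagged, not silently returned", {
  y <- cubinar_series(rep(0, 60), rep(0, 60), rep(1, 60))
  init <- cubinar_params(0.1, 0.1, 0.01, lambda1 = 0.5, lambda2 = 0.5)
  fit <- cml_fit(y, init = init, se = FALSE)
  expect_true(fit$boundary || !fit$converged)
  expect_lt(fit$params$lambda1, 0.1)
})
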