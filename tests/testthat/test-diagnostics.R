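test_that("conditional moments match the exact conditional pmf", {
  p <- toy_params2()

  # zero thinning: conditional law is the Poisson innovation itself
  p0 <- cubinar_params(0, 0, 0.3, lambda1 = c(1, 3), lambda2 = c(3, 5))
  cm0 <- conditional_moments(7, p0, 1, 2, component = 1)
  expect_equal(unname(cm0["mean"]), 3)
  expect_equal(unname(cm0["var"]), 3)

  cmz <- conditional_moments(0, p, 2, 1, component = 2)
  ip <- innovation_params(p, 2, 1)
  expect_equal(unname(cmz["mean"]), ip$mu2)
  expect_equal(unname(cmz["var"]), ip$mu2)

  # against the binomial * Poisson convolution pmf on a grid
  for (x_prev in c(0, 2, 6)) {
    cm <- conditional_moments(x_prev, p, 1, 2, component = 1)
    ip12 <- innovation_params(p, 1, 2)
    x <- 0:80
    pm <- sapply(x, function(v) {
      k <- 0:min(v, x_prev)
      sum(dbinom(k, x_prev, p$alpha1) * dpois(v - k, ip12$mu1))
    })
    expect_equal(sum(pm), 1, tolerance = 1e-10)
    expect_equal(unname(cm["mean"]), sum(x * pm), tolerance = 1e-8)
    expect_equal(unname(cm["var"]),
                 sum(x^2 * pm) - sum(x * pm)^2, tolerance = 1e-8)
  }
})

test_that("Pearson residuals match hand computation and are local", {
  p <- cubinar_params(0.5, 0.2, 0.1, lambda1 = 2, lambda2 = 1)
  y <- cubinar_series(c(3, 4), c(1, 0), c(1, 1))
  r <- pearson_residuals(y, p)
  mu1 <- 2 - 0.5 * 2  # innovation mean, regime 1 -> 1
  expect_equal(unname(r[1, "x1"]),
               (4 - (0.5 * 3 + mu1)) / sqrt(0.5 * 0.5 * 3 + mu1))

  yy <- simulate_cubinar(p, states = rep(1, 200), seed = 61)
  r0 <- pearson_residuals(yy, p)
  x1 <- yy$x1; x1[100] <- x1[100] + 25
  r1 <- pearson_residuals(cubinar_series(x1, yy$x2, yy$states), p)
  changed <- which(r1[, "x1"] != r0[, "x1"])
  expect_identical(changed, c(99L, 100L))  # the outlier and its successor
})

test_that("PIT heights average to one exactly and expose misspecification", {
  p <- toy_params2()
  ch <- markov_chain_spec(c(0.5, 0.5), matrix(c(0.4, 0.6, 0.6, 0.4), 2,
                                              byrow = TRUE))
  y <- simulate_cubinar(p, chain = ch, n = 800, seed = 62)
  for (bins in c(5, 10)) {
    h <- pit_histogram(y, p, bins = bins)
    expect_equal(colMeans(h), c(x1 = 1, x2 = 1), tolerance = 1e-12)
  }

  # grossly undersized means push mass to the upper PIT tail
  small <- cubinar_params(0.05, 0.05, 0.05, lambda1 = c(0.3, 0.9),
                          lambda2 = c(0.9, 1.5))
  hs <- pit_histogram(y, small, bins = 10)
  expect_gt(hs[10, "x1"], 2 * median(hs[, "x1"]))
})

test_that("scores and AIC follow their identities and prefer the generating model", {
  p <- toy_params2()
  ch <- markov_chain_spec(c(0.5, 0.5), matrix(c(0.4, 0.6, 0.6, 0.4), 2,
                                              byrow = TRUE))
  y <- simulate_cubinar(p, chain = ch, n = 1500, seed = 63)
  fit2 <- cml_fit(y, se = FALSE)
  expect_equal(log_score(y, fit2$params), -fit2$loglik / (y$n - 1),
               tolerance = 1e-12)
  expect_equal(AIC(fit2), 2 * (2 * 2 + 3) - 2 * fit2$loglik)

  # one-regime restriction of the same data: 2 fewer parameters, worse AIC
  y1 <- cubinar_series(y$x1, y$x2, rep(1, y$n))
  fit1 <- cml_fit(y1, se = FALSE)
  expect_identical(fit2$n_params - fit1$n_params, 2L)
  aic <- function(f) 2 * f$n_params - 2 * f$loglik
  expect_lt(aic(fit2), aic(fit1))
})

test_that("prediction RMSE matches hand computation and its symmetries", {
  p <- toy_params2()
  y <- toy_series()
  r <- prediction_rmse(y, p, holdout = 0)
  ip <- function(r_, s_) innovation_params(p, r_, s_)
  m1 <- c(0.15 * 1 + ip(1, 1)$mu1, 0.15 * 2 + ip(1, 2)$mu1,
          0.15 * 0 + ip(2, 1)$mu1)
  expect_equal(unname(r$rmse_in["x1"]),
               sqrt(mean((c(2, 0, 3) - m1)^2)), tolerance = 1e-12)

  # relabeling regimes together with their means leaves the RMSE unchanged
  p_swap <- cubinar_params(0.15, 0.2, 0.5, lambda1 = c(3, 1),
                           lambda2 = c(5, 3))
  y_swap <- cubinar_series(y$x1, y$x2, 3 - y$states, S = 2)
  r_swap <- prediction_rmse(y_swap, p_swap, holdout = 0)
  expect_equal(r$rmse_in, r_swap$rmse_in)

  # a deterministic "series" sitting exactly on its conditional mean
  pc <- cubinar_params(0, 0, 0, lambda1 = 2, lambda2 = 3)
  yc <- cubinar_series(rep(2, 10), rep(3, 10), rep(1, 10))
  expect_equal(unname(prediction_rmse(yc, pc, holdout = 0)$rmse_in),
               c(0, 0))

  expect_error(prediction_rmse(y, p, holdout = 3), "holdout")
})

test_that("the diagnostics report assembles and serializes coherently", {
  p <- toy_params2()
  ch <- markov_chain_spec(c(0.5, 0.5), matrix(c(0.4, 0.6, 0.6, 0.4), 2,
                                              byrow = TRUE))
  y <- simulate_cubinar(p, chain = ch, n = 400, seed = 64)
  fit <- cml_fit(y, se = FALSE)
  d <- diagnose(y, fit, holdout = 10)
  expect_s3_class(d, "cubinar_diagnostics")
  expect_equal(d$mean_log_score, -fit$loglik / (y$n - 1))
  expect_true(all(d$rmse$rmse_out >= 0))
  expect_equal(colMeans(d$pit), c(x1 = 1, x2 = 1), tolerance = 1e-12)

  path <- tempfile(fileext = ".txt")
  write_diagnostics(d, path)
  lines <- readLines(path)
  expect_true(any(grepl("^mean_log_score:", lines)))
  expect_true(any(grepl("^pit_bin", lines)))
})
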