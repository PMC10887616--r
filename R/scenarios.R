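#' Construct a simulation scenario
#'
#' A scenario pairs a feasible parameter vector with a regime-generating
#' Markov chain, the sample sizes to study and a replication count — the
#' unit of work for [run_study()].
#'
#' @param params a feasible [cubinar_params()].
#' @param chain a [markov_chain_spec()] with the same number of states.
#' @param sample_sizes series lengths to study.
#' @param replications Monte-Carlo replications per sample size.
#' @return an object of class `"cubinar_scenario"`.
#' @export
scenario <- function(params, chain,
                     sample_sizes = c(300, 900, 1500, 2100),
                     replications = 200) {
  stopifnot(inherits(params, "cubinar_params"),
            inherits(chain, "markov_chain_spec"))
  if (params$S != chain$S)
    stop("chain has ", chain$S, " states but params has ", params$S)
  stop_if_infeasible(params)
  stopifnot(all(sample_sizes >= 10), replications >= 1)
  structure(list(params = params, chain = chain,
                 sample_sizes = as.integer(sample_sizes),
                 replications = as.integer(replications)),
            class = "cubinar_scenario")
}

#' Built-in recovery-study scenarios
#'
#' The standard battery of parameter groups and regime chains used for
#' estimator-recovery experiments. Three-regime groups:
#' \describe{
#'   \item{(a)}{`alpha = (0.15, 0.2)`, `phi = 0.5`, `lambda1 = (1,2,3)`,
#'     `lambda2 = (4,5,6)`;}
#'   \item{(b)}{`alpha = (0.15, 0.5)`, `phi = 0.5`, same means;}
#'   \item{(c)}{`alpha = (0.4, 0.25)`, `phi = 1`, `lambda1 = (3,4,5)`,
#'     `lambda2 = (2,3,4)`;}
#' }
#' each crossed with two 3-state chains — a symmetric one
#' (`p0 = (0.33, 0.33, 0.34)`, diagonal 0.4, off-diagonal 0.3) and a
#' skewed one (`p0 = (0.6, 0.3, 0.1)`, rows `(0.6,0.3,0.1)`,
#' `(0.1,0.6,0.3)`, `(0.3,0.1,0.6)`). Two-regime groups:
#' \describe{
#'   \item{(d)}{`alpha = (0.15, 0.2)`, `phi = 0.5`, `lambda1 = (1,3)`,
#'     `lambda2 = (3,5)`;}
#'   \item{(e)}{`alpha = (0.25, 0.5)`, `phi = 1`, `lambda1 = (2,4)`,
#'     `lambda2 = (5,7)`;}
#' }
#' each crossed with the chains `p0 = (0.5, 0.5)`,
#' rows `(0.4,0.6)/(0.6,0.4)` and `p0 = (0.3, 0.7)`, rows
#' `(0.8,0.2)/(0.2,0.8)`. The innovation covariance `phi*` is always
#' derived as `phi * (1 - alpha1*alpha2)`, never stated independently.
#'
#' @return a named list of [scenario()] objects: `a1`, `a2`, ..., `e2`,
#'   where the digit indexes the chain within its regime count.
#' @export
builtin_scenarios <- function() {
  chains3 <- list(
    markov_chain_spec(c(0.33, 0.33, 0.34),
                      matrix(c(0.4, 0.3, 0.3,
                               0.3, 0.4, 0.3,
                               0.3, 0.3, 0.4), 3, byrow = TRUE)),
    markov_chain_spec(c(0.6, 0.3, 0.1),
                      matrix(c(0.6, 0.3, 0.1,
                               0.1, 0.6, 0.3,
                               0.3, 0.1, 0.6), 3, byrow = TRUE)))
  chains2 <- list(
    markov_chain_spec(c(0.5, 0.5), matrix(c(0.4, 0.6, 0.6, 0.4), 2,
                                          byrow = TRUE)),
    markov_chain_spec(c(0.3, 0.7), matrix(c(0.8, 0.2, 0.2, 0.8), 2,
                                          byrow = TRUE)))
  groups <- list(
    a = cubinar_params(0.15, 0.20, 0.5, lambda1 = c(1, 2, 3),
                       lambda2 = c(4, 5, 6)),
    b = cubinar_params(0.15, 0.50, 0.5, lambda1 = c(1, 2, 3),
                       lambda2 = c(4, 5, 6)),
    c = cubinar_params(0.40, 0.25, 1.0, lambda1 = c(3, 4, 5),
                       lambda2 = c(2, 3, 4)),
    d = cubinar_params(0.15, 0.20, 0.5, lambda1 = c(1, 3),
                       lambda2 = c(3, 5)),
    e = cubinar_params(0.25, 0.50, 1.0, lambda1 = c(2, 4),
                       lambda2 = c(5, 7)))
  out <- list()
  for (g in names(groups)) {
    chains <- if (groups[[g]]$S == 3) chains3 else chains2
    for (k in 1:2)
      out[[paste0(g, k)]] <- scenario(groups[[g]], chains[[k]])
  }
  out
}

#' Monte-Carlo estimator-recovery study
#'
#' For each replication and sample size: draw a fresh regime path from the
#' scenario's chain, simulate the series, and fit by the requested
#' estimators. Aggregates the Monte-Carlo mean, bias (MC mean minus truth)
#' and MC standard error of every parameter estimate. Replications whose
#' fit fails (an estimation error, or a CML run flagged non-converged) are
#' excluded from the summaries and counted separately.
#'
#' @param sc a [scenario()].
#' @param methods subset of `c("yw", "cml")`.
#' @param sample_sizes override of the scenario's sample sizes.
#' @param replications override of the scenario's replication count.
#' @param seed master seed; every replication seed is derived from it, so
#'   identical master seeds give bit-identical results.
#' @return a data frame of class `"cubinar_study"` with one row per
#'   method x parameter x sample size: columns `method`, `parameter`, `n`,
#'   `truth`, `mean`, `bias`, `se`, `reps_used`. Failure counts per
#'   method x sample size are in `attr(, "failures")`; the raw estimates
#'   in `attr(, "estimates")`.
#' @export
run_study <- function(sc, methods = c("yw", "cml"),
                      sample_sizes = sc$sample_sizes,
                      replications = sc$replications, seed = 1) {
  stopifnot(inherits(sc, "cubinar_scenario"))
  methods <- match.arg(methods, c("yw", "cml"), several.ok = TRUE)
  truth <- coef(sc$params)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                 replications * length(sample_sizes)),
                      nrow = replications)

  rows <- list(); fail <- list(); raw <- list()
  for (j in seq_along(sample_sizes)) {
    n <- sample_sizes[j]
    est <- lapply(methods, function(m)
      matrix(NA_real_, replications, length(truth),
             dimnames = list(NULL, names(truth))))
    names(est) <- methods
    nfail <- setNames(integer(length(methods)), methods)
    for (rep in seq_len(replications)) {
      set.seed(rep_seeds[rep, j])
      y <- suppressWarnings(
        simulate_cubinar(sc$params, chain = sc$chain, n = n))
      ywf <- try(yw_fit(y), silent = TRUE)
      for (m in methods) {
        fit <- if (m == "yw") ywf else {
          if (inherits(ywf, "try-error")) ywf
          else try(cml_fit(y, init = ywf$params, se = FALSE), silent = TRUE)
        }
        ok <- !inherits(fit, "try-error") && fit$converged
        if (ok) est[[m]][rep, ] <- coef(fit) else nfail[m] <- nfail[m] + 1L
      }
    }
    for (m in methods) {
      mc_mean <- colMeans(est[[m]], na.rm = TRUE)
      mc_se <- apply(est[[m]], 2, sd, na.rm = TRUE)
      used <- colSums(!is.na(est[[m]]))
      rows[[length(rows) + 1]] <- data.frame(
        method = m, parameter = names(truth), n = n, truth = unname(truth),
        mean = unname(mc_mean), bias = unname(mc_mean - truth),
        se = unname(mc_se), reps_used = unname(used), row.names = NULL)
      fail[[length(fail) + 1]] <- data.frame(method = m, n = n,
                                             failures = unname(nfail[m]))
      raw[[paste(m, n, sep = "_")]] <- est[[m]]
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- do.call(rbind, fail)
  attr(out, "estimates") <- raw
  class(out) <- c("cubinar_study", class(out))
  out
}

#' @export
print.cubinar_study <- function(x, digits = 4, ...) {
  cat("Monte-Carlo recovery study\n")
  df <- as.data.frame(x)
  df$mean <- round(df$mean, digits)
  df$bias <- round(df$bias, digits)
  df$se <- round(df$se, digits)
  print(df, row.names = FALSE)
  f <- attr(x, "failures")
  if (!is.null(f) && sum(f$failures) > 0) {
    cat("failed/non-converged fits:\n")
    print(f[f$failures > 0, ], row.names = FALSE)
  }
  invisible(x)
}
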