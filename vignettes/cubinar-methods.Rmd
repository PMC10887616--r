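---
title: "Circumstance-driven bivariate INAR(1) models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circumstance-driven bivariate INAR(1) models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubinar)
```

## The model

Paired low-count series — accident counts on two road types, sales of one
product in two stores, case counts in two districts — are often
cross-correlated *and* non-stationary: an observable external condition
(a promotion, an intervention, a season) shifts the level of both series at
once. `cubinar` models such data with a circumstance-driven bivariate
integer-valued autoregression of order one. Let $s_t \in \{1, \dots, S\}$ be
an observed categorical regime ("circumstance") label. The process is

$$X_t(s_t) = A \circ X_{t-1}(s_{t-1}) + \epsilon_t(s_t, s_{t-1}),
\qquad A = \mathrm{diag}(\alpha_1, \alpha_2),$$

where $\circ$ is binomial thinning applied componentwise
($\alpha \circ X$ is a sum of $X$ independent Bernoulli($\alpha$) trials) and
$\epsilon_t$ is independent of the past. The regime path itself is treated as
*given*: the model conditions on it, and nothing in the estimators requires a
model for its dynamics. (The Markov-chain generator in
`markov_chain_spec()`/`simulate_states()` exists only to produce synthetic
regime paths for simulation experiments.)

The diagonal thinning matrix is essential: it makes each component a
univariate INAR(1) with regime-switching innovations, and it lets a bivariate
Poisson innovation law propagate into a bivariate Poisson observation law.
With
$$\epsilon_t(s, r) \sim \mathrm{BPoi}\!\left(\lambda_1(s) - \alpha_1
\lambda_1(r),\; \lambda_2(s) - \alpha_2 \lambda_2(r),\; \phi^*\right),
\qquad \phi^* = \phi (1 - \alpha_1 \alpha_2),$$
the observations satisfy $\{X_{1,t}, X_{2,t}\} \sim
\mathrm{BPoi}(\lambda_1(s_t), \lambda_2(s_t), \phi)$ in every regime: means
and variances both equal $\lambda_i(s_t)$ (regime-wise equidispersion), the
within-time cross-covariance is $\phi$, the lag-1 autocovariance of component
$i$ is $\alpha_i \lambda_i(s_{t-1})$, and the lag-$k$ cross-covariance decays
as $\alpha_1^k \phi$ on stationary stretches. `BPoi`$(\lambda_1, \lambda_2,
\phi)$ here is the trivariate-reduction bivariate Poisson: $(U + W, V + W)$
with independent Poissons of rates $\lambda_1 - \phi$, $\lambda_2 - \phi$,
$\phi$, so only nonnegative cross-correlation is representable — a
deliberate non-goal of the package (`phi = 0` recovers independent
components).

**Feasibility.** All innovation laws must have strictly positive component
rates: $\lambda_i(s) - \alpha_i \lambda_i(r) - \phi^* > 0$ for $i = 1, 2$
and every ordered regime pair $(r, s)$ — $2S^2$ strict inequalities, checked
exhaustively by `validate_params()` and enforced everywhere a parameter
vector enters a computation. The feasible set is open and
parameter-dependent, which shapes several numerical choices below.

## Parameters and defaults

| parameter | meaning | constraint |
|---|---|---|
| `alpha1`, `alpha2` | thinning survival probabilities (serial dependence per component) | $[0, 1)$ |
| `phi` | within-time cross-covariance of the counts | $\ge 0$, bounded by feasibility |
| `lambda1[s]`, `lambda2[s]` | marginal mean (= variance) of each component in regime $s$ | $> 0$ |

A model with $S$ regimes has $2S + 3$ free parameters. `S = 1` is the
stationary bivariate Poisson INAR(1) model, used by the diagnostics as the
natural restricted competitor (its AIC penalty differs by exactly 2 per
dropped regime).

## Estimation

**Yule–Walker (`yw_fit`).** Regime-conditional sample means estimate the
$\lambda_i(s)$ directly. The thinning probabilities are estimated by the
occupancy-weighted lag-ratio
$$\hat\alpha_i = \sum_{r,s} \frac{n_{r,s}}{n - 1}
\frac{\hat\gamma_i(r, s)}{\hat\gamma_{ii,0}(r)},$$
and $\hat\phi = \sum_s (n_s / n)\, \hat\gamma_{12,0}(s)$, where $n_s$ and
$n_{r,s}$ are the occupancy and transition-pair counts. The divisor $n - 1$
in the $\alpha$ weights follows the estimator's printed form; the population
identity it estimates carries $n$, and the difference is $O(1/n)$. In small
samples the moment ratios can leave the parameter box; estimates are then
clipped to the boundary and the clipping is recorded on the fit object —
never silent.

**Conditional maximum likelihood (`cml_fit`).** The conditional
log-likelihood is $L = \sum_{t=2}^{n} \log P(X_t \mid X_{t-1})$ with
transition probability
$$P(x_t \mid x_{t-1}) = \sum_{k=0}^{\min(x_{1,t}, x_{1,t-1})}
\sum_{l=0}^{\min(x_{2,t}, x_{2,t-1})}
b(k; x_{1,t-1}, \alpha_1)\, b(l; x_{2,t-1}, \alpha_2)\,
f(x_{1,t} - k,\, x_{2,t} - l),$$
the double binomial convolution of the thinning survivors against the
innovation BPoi pmf $f$ of the realized regime transition. Two independent
code paths evaluate this: `transition_pmf()` is a direct R implementation
(used as a readable reference and cross-checked in the tests against
brute-force enumeration), while `cubinar_loglik()` calls a compiled kernel
that tabulates $f$ once per regime pair and the binomial rows once per
evaluation, making a full likelihood pass $O(n \cdot \bar{x}_1 \cdot
\bar{x}_2)$ — fast enough that a CML fit at $n = 2100$ takes a fraction of a
second. The per-point BPoi pmf itself (`dbpoi`) accumulates its convolution
series in log space with a running maximum, so isolated large counts (up to
the order of $10^3$) do not overflow; the dense in-likelihood tables use
linear-space Poisson weights $t^j / j!$, which stay far below double
overflow at the low counts this model targets, and any numerically vanished
transition term degrades gracefully to $-\infty$ (rejected by the
optimizer).

Optimization runs on an unconstrained working scale — logit for the
$\alpha_i$, log for $\phi$ and the $\lambda_i(s)$ — because the box
constraints alone do not describe the feasible set: the $2S^2$ inequalities
couple all parameters. They are enforced by an infinite penalty (the
objective returns a large value for infeasible proposals, which the BFGS
line search rejects). The optimizer is BFGS initialized at the Yule–Walker
estimate; when the YW solution sits on a boundary it is pushed inside by
$\varepsilon = 10^{-3}$, and if it is infeasible, $\phi$ (then, if needed,
the $\alpha_i$) is shrunk until all inequalities have slack. On reported
non-convergence the fit restarts once from a perturbed point and then tries
a Nelder–Mead pass; a fit is never returned with a likelihood below its
starting value, and non-convergence is always flagged. Standard errors use
the observed information: a central-difference Hessian on the working scale
(relative step $10^{-5}$), inverted and mapped back by the delta method.
Because the feasible set is open, a maximum can sit arbitrarily close to the
feasibility surface (e.g. for degenerate all-zero data); fits whose smallest
innovation-rate margin has collapsed are flagged `boundary`.

## Diagnostics

All adequacy tools condition on the realized regimes. Pearson residuals use
the exact conditional moments $E[X_{i,t} \mid x_{i,t-1}] = \alpha_i
x_{i,t-1} + \mu_i(s_t, s_{t-1})$ and $\mathrm{Var} = \alpha_i (1 - \alpha_i)
x_{i,t-1} + \mu_i(s_t, s_{t-1})$ (thinning variance plus Poisson innovation
variance). The PIT histogram is the non-randomized count-data version,
computed componentwise from the exact univariate conditional law (binomial
thinning convolved with the Poisson innovation); each observation spreads
its conditional cdf interval linearly across the bins, so the bin heights
average to 1 by construction and the diagnostic is fully reproducible. Ten
bins is the default — a convention, not a reproduction of any particular
display. The mean logarithmic score is $-L / (n - 1)$ exactly, and AIC is
$2(2S + 3) - 2L$. The out-of-sample RMSE refits the model without the last
`holdout` observations (default 10) and predicts them one step ahead using
the *realized* regimes and actual previous counts — appropriate because the
circumstance is observable in the intended applications; the package does
not forecast regimes.

## The scenario generator

`builtin_scenarios()` encodes the standard recovery-study battery: parameter
groups (a)–(c) with three regimes (means spanning 1–6, thinning 0.15–0.5,
$\phi \in \{0.5, 1\}$) crossed with a symmetric and a skewed 3-state chain,
and groups (d)–(e) with two regimes crossed with two 2-state chains; all ten
combinations satisfy the feasibility inequalities, and $\phi^*$ is always
derived from $(\alpha_1, \alpha_2, \phi)$ rather than stored. `run_study()`
regenerates the regime path for every replication, fits by YW and/or CML,
and summarizes Monte-Carlo mean, bias, and dispersion per parameter and
sample size; replications whose fit errors out or fails to converge are
excluded from the summaries and counted separately — averaging in failed
optimizations would corrupt the bias estimates.

What the generator emulates is exactly the model: exogenous Markov regimes,
bivariate Poisson marginals, equidispersion within regime. Real data bring
features it does not produce — overdispersion beyond Poisson, negative
cross-correlation, regime labels that are noisy or latent, covariate-driven
means — so passing recovery tests demonstrates correctness of the machinery
under the model, not robustness to misspecification. The PIT and residual
tools are the instruments for judging the latter on real series.

## Problem sizes and reproducibility

The package's own recovery experiments (test suite and the acceptance
script) run the four sample sizes $n \in \{300, 900, 1500, 2100\}$ at 200
replications for CML targets and 1000 replications for the cheap
Yule-Walker target — sizes chosen so the whole battery runs on a single
desktop core in minutes while keeping the Monte-Carlo error of a mean over
replications an order of magnitude below the tolerances being checked
(e.g. the MC standard error of the mean CML $\hat\alpha_1$ at $n = 2100$,
200 reps, is about $0.002$ against a $\pm 0.02$ band). Dispersion *ratios*
between consecutive sample sizes ($\sqrt{300/900} \approx 0.58$ at the
largest gap) are likewise well separated from their MC noise at 200
replications. All randomness flows from explicit seeds: `run_study()`
derives one sub-seed per replication and sample size from its master seed,
so studies are bit-reproducible, and holding the regime path fixed while
varying innovations is done by passing the same `states` vector to
`simulate_cubinar()` under different seeds.

## Known limitations

- Only nonnegative cross-correlation; no overdispersed (negative-binomial or
  geometric) marginals.
- The regime path must be observed; latent-regime inference is out of scope.
- The likelihood kernel is tuned for low counts (regime means up to the
  tens); series with counts in the thousands make the convolution tables
  large and the exact pmf route is then the wrong tool.
- No estimation of the regime chain's transition matrix — neither estimator
  needs it.
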