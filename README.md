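# cubinar

Circumstance-driven bivariate INAR(1) models for non-stationary count time
series.

Paired low-count series — sales of one product in two stores, accidents on
two road types, cases in two districts — are often cross-correlated and
shift level together when an observable external condition changes (a
promotion, an intervention, a season). `cubinar` models such data as a
bivariate integer-valued autoregression whose marginal means are driven by
an observed categorical regime ("circumstance") sequence
$s_t \in \{1, \dots, S\}$:

$$X_t(s_t) = A \circ X_{t-1}(s_{t-1}) + \epsilon_t(s_t, s_{t-1}),
\qquad A = \mathrm{diag}(\alpha_1, \alpha_2),$$

with $\circ$ the binomial thinning operator applied componentwise. Choosing
bivariate Poisson innovations
$\epsilon_t(s, r) \sim \mathrm{BPoi}(\lambda_1(s) - \alpha_1\lambda_1(r),\,
\lambda_2(s) - \alpha_2\lambda_2(r),\, \phi^*)$ with
$\phi^* = \phi(1 - \alpha_1\alpha_2)$ gives observations that are marginally
$\mathrm{BPoi}(\lambda_1(s_t), \lambda_2(s_t), \phi)$ in every regime:
equidispersed components with regime-wise means $\lambda_i(s_t)$,
within-time cross-covariance $\phi$, and lag-$k$ cross-covariance
$\alpha_1^k \phi$. The regime path is treated as observed; $S = 1$ recovers
the stationary bivariate Poisson INAR(1) model.

The package provides:

- the bivariate Poisson machinery (`dbpoi`, `rbpoi`, `bpoi_pgf`);
- exact simulation (`simulate_cubinar`, `simulate_states`,
  `markov_chain_spec`) with feasibility checking of the $2S^2$ innovation
  positivity constraints (`validate_params`);
- Yule–Walker (`yw_fit`) and conditional maximum likelihood (`cml_fit`)
  estimation, the latter through a compiled transition-likelihood kernel
  with observed-information standard errors;
- adequacy and forecast diagnostics (`diagnose`: Pearson residuals,
  non-randomized PIT histograms, logarithmic score, AIC, in-/out-of-sample
  RMSE);
- a Monte-Carlo recovery-study harness (`builtin_scenarios`, `run_study`)
  and a command-line front-end (`cubinar_cli`; installed script under
  `inst/cli/cubinar.R`).

## Worked example

Simulate a two-regime series (promotion on/off, say), fit by CML
initialized at the Yule–Walker estimate, and check adequacy:

```r
library(cubinar)
p  <- cubinar_params(0.15, 0.2, 0.5, lambda1 = c(1, 3), lambda2 = c(3, 5))
ch <- markov_chain_spec(c(0.5, 0.5), rbind(c(0.4, 0.6), c(0.6, 0.4)))
y  <- simulate_cubinar(p, chain = ch, n = 500, seed = 42)
fit <- cml_fit(y)
fit
#> Poi-CuBINAR(1) fit (CML), n = 500, 2 regimes
#>            estimate std.error
#> alpha1       0.1088    0.0359
#> alpha2       0.1373    0.0388
#> phi          0.5281    0.0927
#> lambda1(1)   0.9865    0.0636
#> lambda1(2)   2.8738    0.1136
#> lambda2(1)   3.2487    0.1176
#> lambda2(2)   4.8762    0.1496
#> logLik = -1809.872, AIC = 3633.7
```

Every estimate sits within about two standard errors of its generating
value ($\alpha = (0.15, 0.2)$, $\phi = 0.5$, $\lambda_1 = (1, 3)$,
$\lambda_2 = (3, 5)$). The diagnostics confirm adequacy under the true
model:

```r
diagnose(y, fit, holdout = 10)
#> CuBINAR(1) adequacy diagnostics (CML fit, n = 500)
#> Pearson residuals: mean (0.005, 0.001), var (0.953, 1.086), lag-0 cross-cor 0.197
#> mean log score: 3.6270, AIC: 3633.74
#> RMSE in-sample: (1.312, 2.074), out-of-sample: (1.100, 2.896)
```

Residual means near 0 and variances near 1 indicate correctly specified
conditional moments; the PIT bin heights (printed with the report) are all
within 12% of uniform. The mean logarithmic score is $-L/(n-1)$ exactly,
and the out-of-sample RMSE refits without the last 10 observations and
predicts them one step ahead using the realized regimes.

The same workflow from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cubinar.R", package = "cubinar"))')
Rscript $CLI simulate --scenario d1 --n 500 --seed 42 --out series.csv
Rscript $CLI fit --in series.csv --method both
Rscript $CLI diagnose --in series.csv --holdout 10
Rscript $CLI simstudy --scenario a1 --reps 200 --seed 1 --out study.csv
```

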