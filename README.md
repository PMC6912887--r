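# cjscorr

Hierarchical Bayesian estimation of the **process correlation** between
adult and juvenile apparent survival from capture–mark–recapture data,
with tools to show how strongly the choice of covariance prior drives the
answer.

## The problem

Annual survival rates of wild populations vary among years, and whether two
rates (say, adult and juvenile survival of a long-lived goose) rise and fall
*together* is biologically meaningful — shared environmental drivers,
life-history trade-offs, demographic buffering. Joint estimation from
mark–recapture data, however, induces sampling correlations between the
estimates, so the process correlation must be separated hierarchically. The
standard machinery is an age-structured Cormack–Jolly–Seber (CJS) model
whose annual survival pair is drawn on the logit scale from a bivariate
normal distribution:

```
(logit φ_ad,t , logit φ_juv,t) ~ N(μ, Σ),
Σ = [ σ²_ad            σ_ad σ_juv ρ ]
    [ σ_ad σ_juv ρ     σ²_juv       ]
```

with detection probability *p* and the likelihood marginalized over latent
alive/dead states via age-structured m-arrays (so fitting cost does not
grow with the number of marked animals). The parameter of interest is ρ.

Two priors for Σ are implemented behind one interface:

* `iw_prior()` — conjugate Wishart(K+1, I) on the precision matrix. It
  implies a scaled inverse chi-square marginal for each variance (median
  ≈ 0.72, essentially no mass below 0.1) and a funnel-shaped joint prior on
  (σ, ρ). Since logit-scale survival variances are typically ~0.1, this
  prior inflates variances and attenuates |ρ|.
* `separated_prior()` — independent hyperpriors placed directly on the
  components: σ_k ~ Uniform(0, 5), ρ ~ Uniform(−1, 1).

The package is aimed at quantitative population ecologists who want to
(1) estimate ρ from their own encounter histories under either prior,
(2) run power analyses before trusting such estimates, and (3) see what each
prior implies before it touches data.

## Worked example

Simulate 20 occasions with 1,000 newly marked birds released per occasion
(half juveniles), true ρ = 0.6, logit-scale variances 0.1, detection 0.5 —
then fit under both priors:

```r
library(cjscorr)
d   <- simulate_cmr(sim_config(T = 20, releases_per_occasion = 1000,
                               rho = 0.6), seed = 1)
m   <- build_marrays(d$histories)
fit <- cjs_corr(m, prior = separated_prior(), seed = 7)
fit
#> Age-structured CJS fit (separated covariance prior)
#>   2 chains x 25000 iterations (burn-in 15000, thin 5): 4000 retained draws
#>   parameter   mean    sd   q2.5    q50  q97.5  rhat
#>       mu_ad  1.056 0.076  0.903  1.057  1.206 1.000
#>      mu_juv -0.985 0.068 -1.114 -0.985 -0.848 1.001
#>   sigma2_ad  0.109 0.045  0.050  0.099  0.219 1.001
#>  sigma2_juv  0.076 0.036  0.030  0.069  0.170 1.001
#>         rho  0.511 0.220  0.003  0.541  0.851 1.000
#>           p  0.507 0.004  0.500  0.507  0.514 1.001
```

The separated-prior fit recovers the design: survival means near 1 and −1
(survival 0.73 / 0.27), variances near 0.1, detection 0.5, and a posterior
mean for ρ of 0.51 with 95% CRI (0.00, 0.85) — the generating value was 0.6
and the *realized* correlation of this replicate's 19 year-effect pairs was
0.55. The same data under the inverse Wishart prior:

```r
coef(cjs_corr(m, prior = iw_prior(), seed = 7))[c("rho", "sigma2_ad", "sigma2_juv")]
#>        rho  sigma2_ad sigma2_juv
#>      0.275      0.147      0.129
```

Both variances are inflated and ρ is attenuated from ~0.5 to 0.28 — the
prior, not the data, made the difference. `implied_prior_report()` shows why
before any fitting; `plot(fit)` gives trace/density panels; `run_study()`
replicates the comparison over a factorial grid of study lengths and release
numbers, scoring mean absolute error and 95% credible-interval coverage of
ρ against the generating truth.

A thin command-line wrapper over the same functions ships in
`inst/cli/cjscorr.R` (subcommands `simulate`, `prior-draws`, `fit`, `study`,
`fixtures`, `brent-ingest`).

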