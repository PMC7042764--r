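# songbirdIPM

An R package for fitting **multi-site integrated population models (IPMs)**
to broad-scale songbird monitoring data: route-level count surveys (BBS-like),
constant-effort mist-netting capture-recapture data with transients
(MAPS-like), and age-ratio (hatch-year vs adult) capture totals, joined in a
single Bayesian model with annual climate covariates of the vital rates and
a transient life table response experiment (LTRE) that attributes variation
in population growth to those rates.

It is aimed at avian population ecologists who want to link continental
monitoring programs to demographic mechanisms — for example, a declining
warbler split into a few genetically distinct breeding strata, with winter
drought, spring temperature and migration tailwind as candidate drivers.

## The model

For stratum *m* and year *t*, the population index is the sum of surviving
adults and recruits, `n[m,t] = s[m,t] + g[m,t]`, with truncated-Gaussian
(moment-matched) approximations of the discrete demographic processes:

    s[m,t] ~ N[0,∞)( n[m,t-1]·φ[m,t-1],  n[m,t-1]·φ[m,t-1]·(1-φ[m,t-1]) )
    g[m,t] ~ N[0,∞)( n[m,t-1]·γ[m,t-1],  n[m,t-1]·γ[m,t-1] )

Recruitment decomposes as `γ = RI × ι` (productivity index × latent
first-year-survival/immigration). Counts are overdispersed Poisson around
`log n` with route-by-observer, novice-observer and overdispersion effects;
adult survival φ is informed by a state-space Cormack-Jolly-Seber model
that marginalizes transients (residency probability π, station-specific
recapture probability p, observed-residency probability ρ); RI is informed
by a binomial model of hatch-year proportions with an effort adjustment.
Vital rates follow logit-linear models, e.g.

    logit(φ[m,t]) = logit(φ0[m]) + β_cmd[m]·cmd[m,t] + β_tw[m]·tw[m,t] + ν[m,t]

where `cmd` is the winter climate-moisture-deficit anomaly, `tw` the mean
spring-migration tailwind, and `temp` (in the productivity model) the spring
temperature anomaly. Derived quantities include the lognormal-corrected
abundance index `N = w·exp(log n + σω²/2 + σε²/2)`, geometric-mean trends,
and per-draw LTRE decompositions of expected growth `λᵉ = φ + RI·ι`.

The joint model is fitted with JAGS (via `rjags`), using a collapsed,
marginalized transient-CJS likelihood for speed; an equivalent R-side joint
log-posterior (`build_joint_model()`) backs the test suite. The methods
vignette (`vignettes/multisite-ipm.Rmd`) documents every modelling
convention and design decision.

## Worked example

Simulate a single-stratum validation dataset (40 routes, 25 banding
stations, 17 years; true `φ0 = 0.47`, `β_cmd = −0.2`, `α_temp = 0.27`,
`η = −0.15`, `π0 = 0.55`, `p0 = 0.3`, `ρ = 0.6`), fit it, and decompose
growth:

```r
library(songbirdIPM)

sim <- simulate_dataset(scenario_reduced(), seed = 42)
fit <- sample_posterior(sim$dataset,
                        mcmc_settings(chains = 2, adapt = 300, burn = 300,
                                      draws = 1200),
                        seed = 7)
s <- summarize_posterior(fit)
s$params[s$params$parameter %in%
           c("phi0", "beta_cmd", "alpha_temp", "eta", "pi0", "p0", "rho"), ]
```

```
  parameter  mean   q2.5  q97.5
       phi0  0.43  0.355  0.524
   beta_cmd -0.21 -0.551  0.106
 alpha_temp  0.32  0.160  0.495
        eta -0.19 -0.350 -0.029
        pi0  0.57  0.481  0.666
         p0  0.37  0.293  0.460
        rho  0.57  0.505  0.651
```

Every 95% credible interval covers its generating value (the covariate
coefficients are reported on the within-stratum z-scored scale;
`fit$meta$standardization` maps them back to anomaly units). The derived
trend and the LTRE variance decomposition:

```r
s$trend
#     stratum mean q2.5  q50 q97.5
#          s1 -3.8 -5.9 -3.8    -2     (true realized trend: -3.59 %/yr)

ltre_decompose(s)$variance
#  stratum parameter   mean   q2.5 q97.5
#       s1       phi 0.0037 -0.025 0.034
#       s1        RI 0.0381 -0.017 0.118
#       s1      iota 0.2889  0.082 0.733
```

The trend estimate brackets the realized decline, and the decomposition
attributes annual variation in growth overwhelmingly to the recruitment
components (RI and especially ι), not adult survival — the structure the
generator was given. This short-chain fit is for illustration;
`mcmc_settings("paper")` holds the full protocol (4 chains, 40k adaptation,
20k burn-in, 80k retained draws).

## The analysis workflow

Numbered drivers under `analysis/` run the full pipeline at survey scale
(3 strata patterned on 148/58/21 routes and 66/26/15 stations over
1992–2008) and write their tables under `results/`:

1. `01_simulate.R` — generate the synthetic survey-scale dataset + truth record
2. `02_covariates.R` — build cmd/temp/tailwind covariates from raw point samples
3. `03_fit.R` — assemble, fit, convergence-check, write posterior summaries
   (`--preset paper` for the full protocol)
4. `04_ltre.R` — LTRE decompositions and climate-change pairings

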