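# crypticpoach

Bayesian estimation of *cryptic poaching* — illegal killing that leaves no
recoverable evidence — in a monitored wildlife population, by combining an
annual census time series with cause-specific mortality priors from
radio-tracking in a hierarchical state-space model.

## The problem

When a radio-collared large carnivore is poached, the transmitter is
usually destroyed and the carcass hidden: the researcher records only a
sudden loss of radio contact. Censoring those animals underestimates
mortality; attributing them all to poaching overestimates it. But the
population's census trajectory constrains what total mortality *must* have
been, and radio-tracking pins down the observable components. Fitting both
jointly lets the unobservable component be estimated with honest
uncertainty. The package was built around a recovering Scandinavian wolf
population monitored over a decade (74 → 263 animals, 13.5% mean annual
growth), for ecologists and conservation analysts facing the same
missing-fate problem.

## The model

For winter season *t*, with true size *N&#8209;t*, census count
*Nobs&#8209;t* and *R&#8209;t* pack reproductions:

* process: &nbsp; μ<sub>t</sub> = (1 − m − v − c)·N<sub>t−1</sub> + l·R<sub>t</sub>,
  &nbsp; log N<sub>t</sub> ~ Normal(log μ<sub>t</sub>, σ²<sub>proc</sub>)
* observation: &nbsp; Nobs<sub>t</sub> ~ NegBin(mean N<sub>t</sub>,
  variance N<sub>t</sub> + σ²<sub>Nobs</sub>) — the analytic marginal of a
  gamma-Poisson hierarchy

where *m*, *v*, *c* are per-capita annual probabilities of non-poaching
death, verified poaching and cryptic poaching, and *l* is per-pack
recruitment. *m*, *v*, *l* get informative moment-matched beta/gamma
priors from telemetry; *c* gets a uniform(0, 1) prior so the census data
alone decide whether an unobserved mortality source is needed. Posterior
sampling is an adaptive Metropolis-within-Gibbs sampler (compiled core),
with Heidelberger–Welch convergence screening, a prior–posterior overlap
statistic τ = ∫ min(prior, posterior), and posterior-predictive
counterfactual projections with poaching terms removed.

The package also ships the surrounding machinery as first-class, tested
modules: a deterministic fate-classification rubric for lost-contact
animals, an Aalen–Johansen competing-risks estimator of annual
cause-specific mortality with bootstrap uncertainty, and a synthetic-data
generator (population trajectories, census error, telemetry histories with
evidence fields) so the whole analysis is testable against known truth.

## Worked example

The original census series is not redistributed;
`synthetic_study_series()` reconstructs a stand-in from the published
anchors (endpoints 74 → 263, posterior medians, recruitment prior):

```r
library(crypticpoach)

census  <- synthetic_study_series()
moments <- study_telemetry_moments()
priors  <- build_prior_set(moments, moments$litter_mean, moments$litter_sd)
priors
#> Prior set:
#>   m          beta(shape1 = 23.66, shape2 = 136.2)
#>   v          beta(shape1 = 8.168, shape2 = 155.2)
#>   c          uniform(min = 0, max = 1)
#>   l          gamma(shape = 6.677, rate = 1.763)
#>   sigma_proc uniform(min = 0, max = 25)
#>   sigma_nobs uniform(min = 0, max = 50)

fit <- run_mcmc(census, priors,
                mcmc_settings("quick", chains = 6, n_keep = 10000,
                              burn_in = 16000), seed = 1)
posterior <- summarize_posterior(fit)
subset(posterior, parameter %in% c("m", "v", "c", "l"))
#>   parameter median    sd   lo95  hi95
#> 1         m  0.144 0.026 0.0977 0.201
#> 2         v  0.047 0.016 0.0215 0.085
#> 3         c  0.162 0.107 0.0072 0.404
#> 4         l  4.356 0.958 2.8549 6.431

overlap_table(fit)
#>    parameter        tau
#> 1          m 95.0615617
#> 2          v 96.3962894
#> 3          c 41.6112775
#> ...
```

Reading the output: the posteriors of the observable rates sit on their
telemetry priors (τ ≈ 95–96%), while the cryptic rate — which started from
a flat prior — concentrates on clearly positive values (τ ≈ 42%): the
census trend cannot be explained by observable mortality alone, and the
residual is the cryptic poaching estimate. Its median is within one
posterior sd of the published 0.103 but depends on reproduction detail the
printed anchors do not contain (see the vignette); on the real series the
published medians 0.142 / 0.046 / 0.103 give the headline arithmetic:

```r
derive_headline_shares(0.142, 0.046, 0.103)
#> poaching_share  cryptic_share
#>             51             69
annual_growth_rate(74, 263, 10)
#> [1] 13.52001
```

— poaching accounts for about half of total mortality and more than
two-thirds of it is cryptic. Counterfactual projections replay the decade
from each posterior draw with poaching removed:

```r
no_poach <- simulate_counterfactual(fit, scenario = "no_poaching", seed = 2)
fitted   <- simulate_counterfactual(fit, scenario = "fitted")
tail(population_deficit(no_poach, fitted), 1)
#>    year median_diff diff_median diff_lo95 diff_hi95
#> 11 2009    1152.042    1154.102  147.6684  6873.105
```

the per-year gap being the animals theoretically lost to poaching. (On the
synthetic reconstruction the wide cryptic-rate posterior inflates this
projection's spread; at the published medians the no-poaching projection
reaches ≈ 900–990 wolves by 2009 against 263 observed.)

The full pipeline — classification, competing-risks rates, priors, fit,
diagnostics, overlap, counterfactuals, report files — runs from one
configuration with `run_pipeline()`, or from the shell via the installed
`inst/scripts/run_pipeline.R` wrapper.

## Documentation

The methods vignette (`vignettes/cryptic-poaching-model.Rmd`) describes
the model and its assumptions, the prior construction, the sampler and its
numerical choices, the counterfactual reproduction-scaling decision, what
the synthetic generator does and does not emulate, and known limitations.
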