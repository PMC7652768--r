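# ehrmix

Bayesian profile regression mixtures for a censored survival outcome and a
handful of highly correlated exposure covariates.

## The problem

Occupational and environmental cohorts often record several exposures that
are strongly correlated because they share a physical source — e.g. uranium
miners exposed simultaneously to radon, external gamma rays and uranium
dust, with pairwise correlations of 0.78–0.90 between the cumulative
exposures. Entering such covariates jointly into a standard excess hazard
ratio (EHR) regression,

    h_i(t) = h0(t) · (1 + βR·XiR + βG·XiG + βD·XiD),

yields unstable, high-variance coefficient estimates: every effect that is
clearly positive in univariate fits can become "non-significant" jointly.
`ehrmix` implements the profile regression mixture (PRM) alternative: a
hierarchical model that clusters subjects on their whole exposure profile
*jointly* with the survival outcome and estimates one excess hazard ratio
per cluster,

    h_i(t) = h0(t) · (1 + β_Ci),      β_c > −1,

with a piecewise-constant baseline hazard h0 on four age intervals (cut at
40, 55, 70 years), lognormal/multinomial cluster distributions for the
covariate profile, and a truncated stick-breaking Dirichlet process prior
over cluster membership, so the number of non-empty clusters is estimated.
Inference is an adaptive Metropolis-within-Gibbs sampler with three
label-switching moves; a restricted variant (RPRM) fixes the number of
clusters; post-treatment selects a best partition from the posterior
similarity matrix and reports cluster-conditional posteriors, DIC and WAIC.

The intended users are biostatisticians and radiation epidemiologists; real
cohorts of this type are access-restricted, so the package ships a
synthetic-cohort generator that emulates their structure (delayed entry at
hire age, ~3% events, competing mortality, correlated exposures) and is
used to validate every stage.

## Worked example

```r
library(ehrmix)

# a well-separated 3-cluster validation cohort (n = 400, ~10% events)
cohort <- simulate_cohort(sim_truth_separated(400, seed = 42))

# restricted PRM with K = 4 clusters (3 exposed + reference), smoke schedule
fit <- fit_rprm(cohort, config = sampler_config(preset = "smoke", K = 4, seed = 5))
print(fit)
#> RPRM fit: n = 400 (359 exposed), 3 mixture components, 500 stored draws
#>   acceptance: beta 0.88, sigma 0.31, alpha 0.81
#>   non-empty clusters (post burn-in): modal 3, range 3-3

bp <- best_partition(fit)
table(truth = cohort$true_label, best = bp$labels)
#>      best
#> truth   0   1   2   3
#>     0  41   0   0   0
#>     1   0 150   0   0
#>     2   0   0   0 122
#>     3   0   0  87   0

round(t(apply(conditional_posteriors(fit, bp$labels, "beta"), 2,
              quantile, c(.025, .5, .975))), 2)
#>    2.5%  50% 97.5%
#> 1 -0.51 0.00  0.71
#> 2  1.39 2.71  4.80
#> 3 -0.47 0.16  1.16
```

The generating excess hazard ratios were 0, 1 and 4: the best partition
reproduces the true clustering exactly (rows/columns are label-permuted, as
mixture labels always are), and each cluster's 95% credible interval covers
its generating value — cluster "2" above is the high-risk group (truth 4),
cluster "3" the middle one (truth 1). `cluster_report(fit, cohort)` turns
this into the significance-flagged cluster characterization table, and
`compute_dic()` / `compute_waic()` compare fits with different K.

The multicollinearity phenomenon itself is reproduced by the no-clustering
EHR model: on a cohort with near-collinear exposures, `fit_ehr()` with one
exposure gives a tight positive interval, while the joint trivariate fit
widens every interval (see `tests/testthat/test-acceptance.R`).

## Command line

A thin wrapper (installed under `exec/`) drives the same functions:

```sh
ehrmix simulate --n 400 --seed 1 --out cohort.csv
ehrmix fit --cohort cohort.csv --config fit.json --out run1
ehrmix postprocess --fit run1 --cohort cohort.csv --out post1
ehrmix compare --fits run1,run2 --cohort cohort.csv --out table.csv
```

## Package layout

- `R/hazard.R` — piecewise-constant baseline hazard, EHR likelihoods
- `R/synthetic.R` — cohort simulator and validation presets
- `R/mixture.R` — exposure sub-model, stick-breaking, joint density
- `R/engine.R` — adaptive Metropolis-within-Gibbs, label-switching moves
- `R/ehr.R` — no-clustering EHR regression
- `R/posttreatment.R` — similarity matrix, best partition, DIC/WAIC, reports
- `R/cli.R`, `exec/ehrmix` — command-line interface
- `vignettes/profile-regression-methods.Rmd` — model, priors, sampler and
  design choices in full
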