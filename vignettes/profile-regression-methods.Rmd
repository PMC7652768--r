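---
title: "Methods: profile regression mixtures for censored survival outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile regression mixtures for censored survival outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrmix)
```

## The model

`ehrmix` estimates disease risk from a few highly correlated exposure
covariates and a right-censored, left-truncated survival outcome. Standard
multiple regression breaks down in this setting: collinear predictors yield
unstable coefficients with inflated variance. The profile regression mixture
(PRM) sidesteps the problem by clustering subjects on their whole covariate
profile *jointly* with the outcome, and attaching one risk parameter to each
cluster. Three linked sub-models define the hierarchy.

**Disease sub-model.** With age (in days) as the time scale, subject $i$'s
hazard of death from the disease of interest is an instantaneous excess
hazard ratio (EHR) model,
$$h_i(t) = h_0(t)\,(1 + \beta_{C_i}), \qquad \beta_c > -1,$$
where $C_i$ is the subject's cluster label and $h_0$ the hazard of the
reference cluster of never-exposed subjects ($\beta \equiv 0$). The baseline
is piecewise constant on four age intervals split at 40, 55 and 70 years,
with rates $\lambda_1,\dots,\lambda_4$ in events/day. The observed outcome
is $(Y_i, \delta_i)$ with $Y_i$ the event or censoring age and $\delta_i$
the event indicator; subjects enter observation at hire age, and the
likelihood conditions on survival to entry (left truncation). Truncation is
on by default and can be disabled (`sampler_config(truncate = FALSE)`); with
age as time scale and adult hire ages, conditioning on survival to entry is
the standard treatment.

**Exposure sub-model.** Conditional on the cluster, the three positive
cumulative exposures — radon (WLM), external gamma rays (mSv), uranium dust
(kBq·m⁻³·h) — and age at first exposure are lognormal, and job type (5
levels), mine group (2 levels: Hérault vs other) and exposure-duration class
(4 levels) are multinomial, all with cluster-specific parameters. Given the
cluster, components are independent: the strong pooled correlations between
exposures are represented through cluster separation, which is exactly what
the mixture can express.

**Attribution sub-model.** Cluster membership follows a truncated
stick-breaking Dirichlet process: $V_c \sim \mathrm{Beta}(1, \alpha)$,
$\phi_c = V_c \prod_{k<c} (1 - V_k)$, with the last of $C_{max}$ components
absorbing the remaining stick. The number of *non-empty* clusters is
estimated, guided by the concentration $\alpha \in [0.3, 10]$. At
$\alpha = 10$ the mean weight of a 50th component is below $10^{-3}$, so
`C_max = 50` is the default truncation. The restricted variant (RPRM,
`fit_rprm()`) fixes the number of clusters at $K$ (counting the reference),
which simply truncates the mixture at $K - 1$ exposed components; emptiness
is still possible and is reported per iteration rather than forbidden, and
$\alpha$ is still sampled (both points were genuinely open; truncation
without an occupancy constraint is the minimal reading, and sampling
$\alpha$ keeps the two variants' code paths identical).

**Reference cluster.** Membership of the never-exposed cluster is not a
latent variable: subjects with all three exposures equal to zero are
deterministically assigned the reserved label 0, contribute only survival
likelihood at $\beta = 0$, and their profile covariates are ignored. Real
cohorts contain subjects exposed to some but not all sources; lognormal
support forces a choice, and the default (`zero_policy = "halfmin"`)
replaces a zero component by half the smallest positive observed value of
that exposure, with `"reference"` available to route such subjects out of
the mixture instead.

## Priors

Defaults of `prior_spec()`, normal priors read as (mean, variance):

| block | prior |
|---|---|
| $\beta_c$, $\mu_c^A$ | $N(0, 10^6)$ |
| $\mu_c^G$, $\mu_c^R$, $\mu_c^P$ | $N(0.10, 2.25)$, $N(-2.3, 8.08)$, $N(1.01, 11.79)$ |
| $\sigma_c^{\cdot}$ | $U[0, 100]$ |
| $p_c^J, p_c^M, p_c^T$ | Dirichlet$(1/2,\dots,1/2)$ |
| $\lambda_{1..4}$ | $G(23.7, 4.9{\cdot}10^8)$, $G(35.5, 2.6{\cdot}10^7)$, $G(88.1, 1.6{\cdot}10^7)$, $G(29.7, 3.2{\cdot}10^6)$ |
| $\alpha$ | $U[0.3, 10]$ |

Two dialect choices deserve a note. The exposure-mean variances include
$2.25 = 1.5^2$, which strongly suggests a variance parametrization; a
`normal_dialect = "sd"` override exists. The gamma parameters are read as
(shape, rate) with time in days: $G(23.7, 4.9\cdot 10^8)$ then has mean
$\approx 4.8\cdot10^{-8}$/day $\approx 1.8\cdot10^{-5}$/yr, a plausible
pre-40 lung-cancer mortality, whereas a scale reading would be absurd by
many orders of magnitude. A `gamma_dialect` override exists too.

## Inference

`fit_prm()`/`fit_rprm()` run a Metropolis-within-Gibbs sampler in which
every full conditional that is tractable is drawn exactly:

* allocations $C_i$: categorical full conditional
  $\propto \phi_c \cdot f_{exposure} \cdot f_{survival}$, sampled exactly
  row-wise by the Gumbel-max trick;
* stick fractions: $V_c \sim \mathrm{Beta}(1 + n_c, \alpha + \sum_{l>c} n_l)$;
* baseline rates: $\lambda_j \sim G(a_j + d_j,\; b_j + \sum_i (1 +
  \beta_{C_i}) e_{ij})$ with $d_j$ the events and $e_{ij}$ the person-time
  in age interval $j$;
* lognormal locations: conjugate normal given $\sigma$;
* category probabilities: Dirichlet$(1/2 + \text{counts})$.

Random-walk Metropolis handles the rest: each $\beta_c$ (restricted to
$\beta > -1$ by rejection), each lognormal scale (within its uniform
bounds), and $\alpha$. The adaptive phase — 100 batches of 100 iterations by
default — moves each block's log proposal scale by $\min(0.05, b^{-1/2})$
per batch towards a 40% acceptance target for scalar blocks and 20% for
vector blocks, then freezes the scales. The only vector block in the
package is the joint coefficient update of the no-clustering EHR regression
(`fit_ehr()`), which is the model used to demonstrate the multicollinearity
problem: univariate fits per exposure versus a joint trivariate fit on the
same data. The production schedule is 10,000 burn-in iterations plus
150,000 retained iterations thinned by 20 (7,500 stored values per
unknown); `preset = "smoke"` scales this to 10×50 / 500 / 5,000 / thin 10
for validation experiments.

Blocking was an open choice (only the two targets are prescribed): all
scalar parameters are adapted to 40%, and conjugate draws bypass Metropolis
wherever exact, since exactness dominates an approximate tuned step.

**Initialization** is seed-controlled and reproducible: allocations by
k-means on the standardized log-exposures (at most 5 initial groups),
cluster lognormal parameters at the k-means groups' empirical moments,
$\beta = 0$, baseline rates at their prior means, $\alpha = 1$. Empirical
moments replace prior means for the lognormal blocks because a scale
starting at the prior mid-range (50 on the log scale) is numerically
terrible and the conjugate updates would overwrite it after one sweep
anyway.

## Label-switching moves

Component labels are only weakly identified, so the posterior is highly
multimodal in label space. After every sweep the sampler attempts three
moves:

1. swap the parameters and allocations of a uniformly chosen pair $(j, k)$,
   leaving weights untouched; acceptance ratio
   $(\phi_j/\phi_k)^{n_k - n_j}$;
2. swap an adjacent pair $(j, j+1)$ *including* its stick fractions;
   acceptance ratio $(1 - V_{j+1})^{n_j} / (1 - V_j)^{n_{j+1}}$;
3. swap an adjacent pair and redraw $(V_j, V_{j+1})$ from their exact Beta
   full conditionals under the swapped occupancy counts, so the implied
   weights land near their conditional expectations given the new labels.

Move 3's acceptance ratio is derived from first principles rather than
transcribed: with full-conditional proposals the Metropolis ratio collapses
to a ratio of Beta normalizing constants,
$$r_3 = \frac{B(1{+}n_{j+1}, \alpha{+}n_j{+}T)\; B(1{+}n_j, \alpha{+}T)}
            {B(1{+}n_j, \alpha{+}n_{j+1}{+}T)\; B(1{+}n_{j+1}, \alpha{+}T)},
  \qquad T = \textstyle\sum_{l>j+1} n_l,$$
independent of the sampled fractions. A deterministic
conditional-expectation proposal would not be a valid Metropolis move (it
is not an involution and has a point-mass proposal), whereas this
construction provably leaves the posterior invariant; the test suite checks
both the closed form against numerical integration and, distributionally,
that chains with and without the moves deliver the same sorted-weight
marginals. Moves 1–2 are validated against brute-force posterior ratios
computed from the joint density. Scheduling (one attempt of each move per
sweep) was unspecified and is a package choice.

## Post-treatment

Mixture draws are label-ambiguous, so reporting conditions on a single
partition. From the allocation trace the posterior similarity matrix
$S(i,j)$ — the proportion of draws in which $i$ and $j$ co-cluster — is
accumulated draw by draw, and the *best partition* is the sampled partition
minimizing $\sum_{i<j} (S_k(i,j) - S(i,j))^2$ (ties to the earliest draw;
unordered pairs only, the diagonal being constant; a MAP partition is
deliberately not offered, being more sensitive to Monte Carlo error).
Reference subjects form a fixed block of the partition. Conditional on the
best partition, the draw-$k$ sample of any cluster-indexed parameter for
best cluster $c$ averages the parameter over the cluster's members,
$\bar\theta_{c,k} = n_c^{-1} \sum_{i:\,c_i^{best}=c} \theta_{C_{ik}},$
applied uniformly to $\beta$, all lognormal pairs, all category
probabilities and the weights $\phi$. `cluster_report()` then flags each
cluster's risk (95% interval above/below/straddling zero) and positions
each covariate's interval against the all-subject median.

For model comparison, per-subject likelihoods marginalize allocations
through the mixture form $\sum_c \phi_c f_c$ (survival only, $\beta = 0$,
for reference subjects). DIC needs a plug-in deviance whose point estimate
is not prescribed anywhere; the package evaluates it at the posterior means
of the continuous parameters with allocations marginalized, and WAIC uses
the same pointwise likelihoods, so the two criteria are directly
comparable.

## The synthetic cohort generator

Real occupational cohorts of this kind are access-restricted, so
`simulate_cohort()` generates cohorts with the structure the model assumes,
and every downstream stage is tested against it. The default `sim_truth()`
emulates a post-1955 uranium-miner cohort: n = 3,377; entry (hire) age
lognormal with median 27 y; administrative censoring at entry +
U(15, 51) years, capped at age 85; constant-rate exponential competing
mortality ($2.2\cdot10^{-5}$/day, ≈23% competing deaths); ~4% never-exposed
subjects; four exposed clusters whose ordered separation in all three
exposures induces pooled log-exposure correlations around 0.75–0.85; and
baseline rates at the prior means, giving ≈2.7% disease deaths. Event times
are drawn by exact inverse-CDF inversion of the piecewise-exponential
distribution conditioned on survival past entry. Time arithmetic is in days
throughout, with 365.25 days/year fixed for all conversions.

What the generator does **not** emulate: calendar-period effects and
exposure time-series (exposures are career cumulative sums, duration class
is drawn directly as a categorical rather than derived from a career
history), within-cluster exposure correlation (independence given the
cluster — exactly the PRM's own assumption, so tests cannot detect
misspecification of it), cause-specific competing-mortality age curves, and
measurement error. Passing recovery tests therefore show the inference
machinery is correct under the model's own assumptions, not that the model
is correct for any particular real cohort.

`sim_truth_separated()` is the validation preset: three well-separated
exposed clusters with $\beta = (0, 1, 4)$ and an older, longer-followed
cohort (entry median 45 y, 30–40 y follow-up) so that ≈10% of subjects have
events and the survival signal is strong enough for recovery experiments at
n = 400 — the emulated 3% event fraction leaves $\beta$ mostly
prior-dominated at desk scale, which is a faithful property of the real
problem but useless for validating samplers.

## Numerical choices

* Age intervals are half-open $[l, u)$ in days; an age exactly at a
  cutpoint belongs to the older interval.
* Inadmissible parameter points ($\beta \le -1$, a nonpositive regression
  multiplier, out-of-bounds scales) are `-Inf` in the joint log-density and
  rejected by the sampler, never raised as errors mid-chain.
* Stick fractions are clamped to $[10^{-12}, 1 - 10^{-12}]$ after conjugate
  draws; degenerate move-3 proposals auto-reject.
* Allocation sampling uses log-sum-exp / Gumbel-max arithmetic throughout;
  ties in the argmax break to the first index, keeping runs bit-reproducible
  under a fixed seed.
* `best_partition()` ties break to the earliest draw.

## Problem sizes used in the test suite

Unit oracles (quadrature, enumeration, closed forms) run on toy states in
milliseconds. Distributional checks use: conjugacy KS tests at 3,000 draws;
the with/without-moves equivalence on an n = 80 two-cluster cohort with six
chains of 4,000 retained iterations per arm, compared at chain level
(chain-level summaries are the correct sampling unit: single pooled chains
carry slow regime noise that a pointwise two-sample test mistakes for bias);
parameter recovery on 20 replicate
n = 400 cohorts under the smoke schedule (coverage threshold 90%, partition
agreement threshold 0.90, both frozen after a pilot run); and the
multicollinearity contrast on one n = 400 cohort with a noisy-copy exposure
pair. The calibration script measures post-adaptation acceptance over 5,000
iterations after the full 100×100 adaptive phase on an n = 200 cohort.

## Known limitations

* The full PRM on weak-signal cohorts (the realistic ~3% event fraction)
  can lock into local modes in the number of non-empty clusters even with
  the label-switching moves — the phenomenon that motivates the restricted
  variant; the per-iteration non-empty-cluster trace is logged precisely to
  diagnose this, and fits from several seeds are recommended.
* No time-varying exposures or calendar effects; no Weibull or spline
  baselines; no Hamiltonian Monte Carlo.
* The sampler is pure R; it is vectorized across subjects and components
  and comfortably handles desk-scale cohorts (minutes for smoke schedules),
  but the full production schedule on a 3,000-subject cohort is an
  overnight job.
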