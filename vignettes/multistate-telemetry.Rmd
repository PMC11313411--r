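---
title: "Multistate hidden Markov models for river-pool telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate hidden Markov models for river-pool telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolstate)
```

## The problem

Acoustic telemetry arrays in large impounded rivers record when a tagged
fish passes within range of a stationary receiver. Managers of invasive
carp populations want monthly probabilities that a fish stays in its
current navigation pool, moves to a pool downstream, or passes a lock and
dam upstream — and, just as importantly, an honest account of how well the
receiver array can observe those movements. Raw detection streams are a
biased record of movement: pools differ enormously in receiver coverage,
tags have finite battery lives, fish die, and tags are sometimes shed and
keep pinging from the river bed.

`poolstate` implements the full chain from raw streams to posterior
movement estimates: suspect-tag screening, reduction to monthly pool
residencies and receiver-effort covariates, and a Bayesian multistate
hidden Markov model fitted by MCMC. A synthetic-telemetry generator built
on the model's own generative assumptions makes every stage testable
without access to a real array.

## The model

Time advances in calendar months. The latent state of a fish combines
location with a vital/technical status: alive with operable battery in
pool $j$ (A/O, $j = 1, \dots, 6$, pool 1 most downstream), dead with
operable battery (D/O), alive with expired battery (A/E), and the
absorbing dead/expired state (D/E). With monthly survival $\phi$, monthly
battery retention $\delta$, and a column-stochastic pool transition matrix
$\psi$ (destination rows, origin columns), the transition matrix from
month $t$ (columns) to $t+1$ (rows) has the block form

| | A/O ($j$) | D/O | A/E | D/E |
|---|---|---|---|---|
| **A/O** ($i$) | $\phi\,\delta\,\psi_{i,j}$ | 0 | 0 | 0 |
| **D/O** | $(1-\phi)\,\delta$ | $\delta$ | 0 | 0 |
| **A/E** | $\phi\,(1-\delta)$ | 0 | $\phi$ | 0 |
| **D/E** | $(1-\phi)(1-\delta)$ | $1-\delta$ | $1-\phi$ | 1 |

Every column sums to one. Survival is constant across pools — a deliberate
simplification for sparsely tagged pools — and the system is treated as
closed: downstream emigration from pool 1 is not separable from mortality.

A fish is observable only in state A/O. The monthly probability of at
least one detection in pool $j$ is a logistic function of the mean number
of receivers deployed per day ("receiver-days", $x_{j,t}$):

$$\rho_{j,t} = \mathrm{logit}^{-1}(-5 + \beta_j x_{j,t}), \qquad
\beta_j \sim N(\theta, \sigma).$$

The intercept is pinned at $-5$ so that the detection curve passes through
(effectively) zero when no receivers are in the water; $\rho$ is never
hard-set to zero, a pool-month without receivers simply has
$\rho = \mathrm{logit}^{-1}(-5) \approx 0.0067$. Pool effects $\beta_j$
are hierarchical with mean $\theta$ and spread $\sigma$; negative
$\beta_j$ is allowed by the prior and produces a decreasing curve, which
the reporting functions flag rather than forbid.

The observation symbol each month is one of: detected in pool $k$ (only
possible from A/O in $k$, probability $\rho_{k,t}$), not detected (A/O
with probability $1-\rho$, or D/O with certainty), or battery expired.
Expiration is *asserted*: from the projected battery-expiration month
onward the data carry the expired symbol and any later detections are
discarded. Priors follow convention for this model family: $\phi, \delta
\sim U(0,1)$, $\theta \sim N(0,1)$, $\sigma \sim U(0,5)$, and each
$\psi$ column symmetric Dirichlet. We use Dirichlet(1) — flat over the
simplex — since only "Dirichlet" is conventionally specified; the
concentration is a `log_prior()` argument.

### Likelihood and sampler

The observation sequence of each fish, anchored at its asserted release
pool, is a hidden Markov model; `forward_loglik()` computes the marginal
likelihood by the scaled forward recursion, summing over all latent
paths. We marginalize the latent states rather than sampling them: the
posterior over parameters is identical, the per-iteration cost is far
lower, and the equivalence is verified in the test suite by comparing the
MCMC posterior of a collapsed single-pool model against a dense-grid
numerical posterior (`grid_posterior_1pool()`), and the recursion itself
against brute-force path enumeration.

`fit_mcmc()` runs an adaptive Metropolis-within-Gibbs sampler:

* $(\mathrm{logit}\,\phi, \mathrm{logit}\,\delta)$ — joint random walk;
* each $\psi$ column through an anchored-softmax transform with its exact
  Jacobian (so the Dirichlet prior is preserved), mixing random-walk
  moves with occasional independence proposals from the prior. The
  independence moves matter: transition columns of pools where detection
  is rare are nearly likelihood-flat, and a pure random walk traverses
  the heavy tails of the induced logistic-normal geometry very slowly;
* each $\beta_j$ — scalar random walk with its own adapted scale, since
  the data constrain the effects very unevenly across pools (random-walk
  increments are t-distributed with 3 degrees of freedom, again for tail
  mobility);
* $\theta$ — exact conjugate normal draw; $\sigma$ — griddy-Gibbs draw on
  (0, 5].

Proposal scales adapt only during warm-up (Robbins–Monro toward standard
acceptance targets) and are frozen afterwards, so the retained chain is a
valid Markov chain. Chain $c$ is seeded `seed + c`. The package default
budget is 3 chains × (2,000 warm-up + 6,000 draws); `mcmc_config_full()`
provides the production-scale preset (10,000 + 100,000 thinned by 3).
Convergence is summarised by the classic Gelman–Rubin statistic per
parameter with the `< 1.1` rule; `gelman_rubin()` returns 1 by convention
when total variance is zero, and `Inf` for constant-but-unequal chains.
The thinning count is interpreted as *pre*-thinning iterations (`iter /
thin` draws are retained); both readings circulate, so the bookkeeping is
explicit in `mcmc_config()`.

### Derived quantities

`derive_outputs()` reports the monthly movement matrix as the posterior
mean of the *product* $\phi\,\delta\,\psi_{i,j}$, averaged draw by draw —
not the product of posterior means, which differs under correlation (the
alternative is one line of user code on the returned draws).
`summarize_movement_matrix()` reduces any six-pool movement matrix to
staying probabilities (diagonal), total downstream (above-diagonal column
sums) and total upstream (below-diagonal) probabilities, cross-pool means
and ranges. Cross-pool means use unrounded inputs; when the input is a
published matrix printed to three decimals, the reduction reproduces the
printed totals exactly but cross-pool means can differ from published
ones in the last digit (a mean of rounded cells is not the rounded mean
of unrounded posteriors).

## Preprocessing rules

* **Effort.** Mean receivers per day per pool-month, by exact day-count
  arithmetic over half-open deployment intervals $[\mathrm{deploy},
  \mathrm{retrieve})$ — half-open so a same-day handover between two
  receivers never counts twice. Deployments outside the calendar are
  clipped with a warning; overlapping intervals for one receiver id are
  rejected.
* **Suspect tags.** A fish is removed if its only detections fall within
  the first 30 days after tagging (early death or tag shedding), or if
  the tag *kept on* being detected but was stationary: at least two of
  (1) the whole record is a single continuous detection event on one
  receiver or on simultaneously heard receivers in proximity, (2) all
  detection receivers lie within 1,000 m of each other, (3) the only
  pool of detection is the release pool. "Continuous" means
  inter-detection gaps of at most 7 days (configurable); "in proximity"
  reuses the 1,000 m threshold; distances are river distances from
  receiver positions. Because the stationary rules target persistent
  records, they are evaluated only when the record spans more than 30
  days — without that guard, a perfectly ordinary fish detected on a
  single day (one ping on one receiver in its release pool) would
  trivially satisfy conditions (2) and (3). Fish never detected at all
  are retained: absence of evidence is not evidence of a dropped tag.
* **Monthly residency.** Lock receivers are excluded first (a signal at
  a lock cannot be attributed to one pool). The residency pool is the
  pool with the most distinct detection-days in the month; ties break by
  detection count, double ties by the previous month's residency and
  then the lower pool index (logged choice; double ties are rare and the
  convention is arbitrary but fixed).
* **Histories.** From release month (asserted at the release pool, for
  the whole month, regardless of release day) to the calendar end;
  months with no residency are "not detected"; every month from the
  projected expiration month on carries the asserted expired symbol and
  later residencies are discarded.

## The synthetic-telemetry generator

`simulate_cohort()` draws latent trajectories month by month from the
exact transition structure above, detects alive/operable fish-months with
probability $\rho_{j,t}$, and expands each detected fish-month into raw
detection events. Its defaults define the package's reference study,
chosen to resemble a multi-agency river array at a size that keeps
simulation studies fast:

* 6 pools over 36 calendar months; 200 fish released across all pools in
  two waves (months 1 and 13);
* true $\phi = 0.96$, $\delta = 0.97$ per month; a diagonally dominant
  $\psi$ with downstream bias (`default_psi()`: roughly 0.78–0.94 staying
  probability, one-pool downstream moves about twice as likely as
  one-pool upstream);
* pool detection effects $\beta$ spanning 0.3–3 against a full-span array
  of 8/4/4/3/3/3 receivers per pool, giving monthly detection
  probabilities from about 0.07 (most downstream pool) to above 0.9 —
  the strong downstream-to-upstream detectability gradient characteristic
  of such arrays;
* one flagged lock receiver at each internal pool boundary.

Design choices worth knowing:

* **Calendar months, not 30-day blocks.** Raw events get uniform
  timestamps within real calendar months and deployments run month
  boundaries, so generated streams round-trip through the calendar-based
  preprocessing with no special casing (the monthly model itself is
  indifferent to day counts).
* **Projected expiration equals realized expiration.** The model asserts
  battery expiration at the projected date; the self-consistent
  generative reading is that the projected date is correct. By default
  battery life is drawn geometric with retention $\delta$ and written to
  the tag table as the projected expiration (`battery_mode =
  "stochastic"`); a `"fixed"` mode expires tags at the nominal plan
  lifetime instead. This matters for inference: because expiration is
  asserted in the data, $\delta$ is identified through the distribution
  of (projected) battery lifetimes, and a premature real-world battery
  failure cannot be expressed as "not detected" under the printed
  observation process. The model is implemented exactly as specified,
  and the tension is a known property, not a bug.
* **Release-month events.** Fish are released on day 1 and the generator
  emits events only from the first full month after release. Release-month
  residency is asserted from the tag record downstream, so such events
  carry no information — and their absence keeps the first-30-day
  filter's ground truth unambiguous for the filter-fidelity checks.
* **Event counts.** A detected fish-month yields a shifted-geometric
  number of events (mean `daily_detection_rate` × days in month, default
  2/day) at uniform times on random non-lock receivers of the occupied
  pool. Only monthly presence matters downstream; the within-month event
  process is a stand-in, not a claim about receiver physics.
* **Artifacts.** `plant_artifacts()` injects ground-truth-labelled
  suspect fish — early-only detections, and stationary tags as a single
  receiver, a planted pair of receivers 300 m apart, or two gapped
  clusters — with labels kept in a side table so the filter must
  rediscover them.

What the generator does *not* emulate: within-month excursions (the
latent chain is monthly, so every event of a detected month falls in one
pool and the all-detections and monthly movement-class tables coincide on
synthetic data — the collapse they quantify on real data is exercised
with hand-built fixtures instead), seasonal or flow-dependent movement,
pool-to-pool differences in survival, harvest reporting, receiver
outages within deployments, range variation, or emigration past the
array. Passing tests therefore demonstrate correctness of the
machinery under the model's own assumptions, not robustness of the model
to real-data violations of them.

## Verification strategy and numerical choices

* `forward_loglik()` agrees with brute-force path enumeration to 1e-10
  over random parameter draws and history shapes, including asserted
  expiration; months after the first expired symbol contribute exactly
  zero log-likelihood, so the compiled likelihood truncates them.
* Transition-matrix columns sum to 1 to 1e-10 over 1,000 random draws.
* With a release-only history (likelihood constant), the sampler
  reproduces its priors — an end-to-end check of the logit and softmax
  Jacobians.
* The collapsed single-pool posterior from MCMC matches dense-grid
  numerical integration (grid ranges are a numerical choice; means agree
  to a few multiples of the Monte-Carlo error).
* Parameter recovery: 20 replicates of the reference scenario at a
  reduced budget (2 chains × (800 + 1,200) iterations; the test suite's
  problem sizes are chosen so the whole suite runs in minutes on one
  core). Coverage is summarised *pooled* over the tracked parameters
  ($\phi$, $\delta$, $\theta$, the six $\psi$ diagonals) × replicates,
  with a 90% pass line for nominally-95% intervals: per-parameter or
  all-parameters-jointly coverage at 20 replicates would be dominated by
  binomial noise rather than calibration.
* An impossible observation (e.g. a detection in an asserted-expired
  month) yields `-Inf` with a diagnostic rather than an error; fish whose
  entire history is the release month contribute likelihood one and are
  retained.
* Degenerate Gelman–Rubin cases are pinned: zero total variance gives 1,
  zero within-chain variance with separated chains gives `Inf`.

## Limitations

Survival and mortality are confounded with permanent emigration at the
downstream boundary; $\delta$ is informative only through the asserted
expiration bookkeeping; the monthly timestep hides within-month
round-trip excursions (the movement-class tables on the two bases
quantify exactly this collapse); and the GLMM-based comparisons of
detection frequency and period across release pools are out of scope —
`detection_frequency()` and `detection_period()` compute the raw metrics
that would feed such an analysis.
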