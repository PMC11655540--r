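---
title: "A multistate capture-recapture model for register over-coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multistate capture-recapture model for register over-coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Countries that document their population through administrative registers
face *over-coverage*: people who emigrated (or died abroad) without the
event being recorded remain officially registered, so the registered
population overstates the resident population. Over-coverage distorts the
denominators of demographic rates, most severely for migrant groups, who
are both more mobile and have weak incentives to de-register when leaving.

The deterministic *register-trace* rule counts a person as present in a
year if and only if they appear in at least one administrative list that
year. It treats every undetected year as absence, so it necessarily
overstates over-coverage — most strongly for newly arrived people, who are
the least likely to show up in income, employment or education registers
while they are still settling in.

`crcover` instead fits a longitudinal multistate capture-recapture model
to the whole register panel of each individual, yielding a smoothed
probability of presence for every undetected person-year and model-based
over-coverage estimates with credible intervals.

## The model

Individuals $i$ register on arrival in year $r_i$ and are followed over
years $y = r_i, \dots, Y$ across $L$ detection lists (socioeconomic
registers: income, employment, education, internal moves, ...). The yearly
latent state is present, absent (alive, abroad) or dead; dead is
absorbing, and everyone is present in their registration year.

Writing $x_{iy}$ for the covariate vector (intercept, sex, standardized
age, six reference-coded country-of-birth groups, time since first
migration in years), each yearly probability gets a logistic regression:

* survival $\phi_{iy}$: $\operatorname{logit}(\phi_{iy}) = x_{iy}^\top \beta_\phi$,
* staying given presence $\psi_{iy}$, and returning given absence
  $\eta_{iy}$, analogously, so that alive individuals follow
  $Z_{iy} \mid Z_{iy-1} \sim \mathrm{Ber}\!\left(Z_{iy-1}\psi_{iy} + (1 - Z_{iy-1})\eta_{iy}\right),$
* de-registering when leaving, $\lambda_{iy}$: a departure is notified to
  the authorities with this probability, after which absence is observed
  until the (certain) re-registration upon return,
* detection in list $l$ while present, $\theta_{iyl}$.

The transition factorizes as survival first, then movement, so from
presence the year-$y$ state distribution is
$\{1-\phi,\; \phi\psi,\; \phi(1-\psi)\}$ over dead/present/absent, and from
absence $\{1-\phi,\; \phi\eta,\; \phi(1-\eta)\}$. Deaths in the country
are recorded with probability one; deaths of absent individuals are
unrecorded, so the record simply goes silent.

Every coefficient receives an independent $N(0, \delta)$ prior with
variance $\delta = 2$.

### What the data pin down

Detection in at least one list forces presence; the registration year
forces presence; a recorded death forces the dead state from the death
year onward (and presence the year before, since only in-country deaths
are recorded); a de-registration forces non-presence from that year until
the recorded re-registration (and presence the year before). We read
"non-presence" literally: in the de-registration year the individual is
certainly absent-alive (the notification itself implies a live departure),
but later in the span they may die abroad unrecorded, so the dead state
stays admissible there. Treating those years as forced-alive instead
measurably biases the survival coefficients in recovery experiments,
because de-registered individuals who die abroad would be forced to
survive. Presence probabilities on such years are exactly zero either way.

### Marginal likelihood instead of latent-state sampling

Sampling one latent indicator per undetected person-year is the textbook
approach but scales badly — it is the reason analyses of this kind resort
to small subsamples. Here the latent trajectory is summed out exactly by a
forward recursion over the three states (a hidden-Markov marginal
likelihood, computed in C++ with per-year normalization to avoid
underflow), so the posterior involves only the $(L+4) \times 10$
regression coefficients. Smoothed presence probabilities
$\hat{Z}_{iy} = P(\text{present} \mid \text{whole record}, \beta)$ are
recovered by forward-backward smoothing, averaged over the retained
posterior draws. An exhaustive path-enumeration oracle
(`enumerate_loglik()`, `enumerate_state_posterior()`) verifies both
computations to $10^{-10}$ in the test suite; it is exponential in the
number of free years and exists only for verification.

### The sampler

`mcmc_sample()` runs a blocked adaptive random-walk Metropolis on the
marginalized posterior, one block per linear predictor. During burn-in
each block adapts (i) a scalar step size towards an acceptance rate of
0.234 and (ii) an empirical proposal covariance (initialized from the
design-based metric $(X^\top X / n)^{-1}$); both are frozen after burn-in
so the retained chain is a valid Metropolis sampler. Chains are
initialized from logistic regressions on a deterministic register-trace
imputation of the latent states (present between detections, absent after
the last detection, events as recorded), shrunk towards zero and capped at
$\pm 3$ so separation in sparse subgroups cannot produce extreme starts;
each chain adds $N(0, 0.1^2)$ jitter. A plain near-zero start is also
possible but wastes most of a short burn-in diffusing towards the
posterior mode. Each iteration performs `sweeps` (default 2) Metropolis
updates of every block; raising it buys effective sample size per retained
draw at proportional cost.

The default chain protocol is 15,000 iterations, 5,000 discarded as
burn-in and every 10th value kept, with two chains whose split
Gelman–Rubin statistics (`gelman_rubin()`) should be close to one.
Prior-only sampling (`prior_only = TRUE`) must — and does, in the tests —
reproduce the $N(0, 2)$ prior moments, a standard end-to-end sampler
check.

## Over-coverage estimation

For year $y$ and any subgroup, the denominator $D_y$ contains everyone
administratively registered: arrived by $y$, no recorded death, no
de-registration left unresolved by a re-registration. Silent emigrants
stay in $D_y$ — they *are* the over-coverage; removing them would force
the estimate to zero by construction. Unrecorded deaths abroad likewise
remain, consistent with a registration-based denominator. Then

$$\mathrm{OC}_y \;=\; 1 - \frac{\sum_{i \in D_y} \hat{Z}_{iy}}{|D_y|},$$

with $\hat{Z}_{iy} = 1$ for detected years. The default credible interval
is formed from the per-draw values $1 - \overline{\hat{Z}^{(m)}_{iy}}$,
using per-draw smoothed probabilities rather than sampled indicators: the
expectation is identical and the Monte-Carlo variance lower. That interval
quantifies parameter uncertainty about the *expected* over-coverage. When
the target is instead the realized over-coverage of one finite cohort —
as when validating against a simulator's ground truth — the realization
noise of the latent indicators dominates at these cohort sizes, so
`oc_estimate(..., interval = "predictive")` adds the conditional Bernoulli
variance $\sum_i \hat{Z}^{(m)}_{iy}(1-\hat{Z}^{(m)}_{iy})$ per draw (a
normal approximation to the conditional sum), giving a posterior-predictive
interval with the correct year-wise coverage for realized quantities. The
register-trace estimate replaces $\hat{Z}_{iy}$ by the detection
indicator, so the model estimate can never exceed it — a dominance
property asserted in the tests on every dataset. `gap_summary()`
tabulates smoothed presence probabilities by the number of consecutive
undetected years, time since migration, and whether the person reappears
the following year; the probability after a 3–4-year silent gap collapses
towards zero while a single silent year retains substantial presence
probability.

## The simulator and what the tests show

`simulate_cohort()` draws cohorts from the exact generative model with
ground-truth trajectories: arrivals uniform over 2003–2015 by default with
final observation year 2016 (configurable), 48% women, age at arrival
$18 + \Gamma(2.2, 6)$ years, and country-group shares dominated by Eastern
Europe and MENA (0.25 each), with Western Europe (0.12, the reference
level), Rest of World (0.15), and the remaining groups at 0.07–0.08 —
round values chosen once to mimic a European migrant cohort. The reference
coefficient set (`default_coefficients()`) fixes the signs a register
analyst would expect (staying and de-registering increase with time since
migration, women return and de-register more, Eastern Europe/MENA stay
more and de-register less, Nordic/USA groups the reverse) with all values
in $[-1.5, 1.5]$ and detection intercepts spanning high- to low-coverage
lists.

The recovery experiments in `tests/testthat/test-acceptance.R` use 20
replicate cohorts of $n = 2000$ over six years with four lists, fitted
with a reduced protocol (4,000 iterations, 1,000 burn-in, thin 5, two
chains) — sizes chosen so the full study runs comfortably on one CPU —
and check pooled 95% interval coverage of at least 0.90 and a mean
absolute error below 0.2. Over-coverage recovery uses one cohort of
$n = 5000$ over 2003–2016 and requires the simulator's true over-coverage
to fall inside the model's 95% interval in at least 11 of 13 years.
`scripts/acceptance.R` reruns the same quantities from scratch at reduced
replicate counts.

The simulator matches the model exactly, so these tests demonstrate
correctness of likelihood, sampler and estimators — not robustness to
real-data features the model lacks: covariates are complete and exact,
marginal covariate distributions are independent, detection is
conditionally independent across lists given presence, and there are no
individual random effects, no within-year timing, and no misclassified
events. On real registers the model's presence probabilities inherit any
violation of those assumptions.

## Numerical and degenerate-case choices

* The forward recursion runs on the probability scale with per-year
  normalization; records that are impossible under the known-state mask
  return `-Inf` with a data-inconsistency warning, and the sampler
  refuses to start on such data, listing the offending individuals.
* The logistic link is evaluated stably for linear predictors beyond
  $\pm 500$; probabilities saturate at machine precision rather than
  overflowing.
* Individuals registering in the final observation year contribute only
  their (forced-present) registration-year detection terms.
* Probability vectors in simulation specifications must sum to one within
  $10^{-9}$; validation failures name the file, row and rule and never
  repair silently.
* Identical duplicated individuals could in principle share one
  likelihood evaluation; with a continuous age covariate exact duplicates
  are rare, so no such collapsing is implemented.

## Known limitations

Emigration and return are modelled as at most one move per year; the
covariate effects are shared across individuals (no frailty); the
arrival-year composition of real cohorts is richer than the configurable
marginals; and the register-trace imputation used only for starting
values is, deliberately, the crude rule the model itself improves upon.
For cohorts far larger than the tested sizes the forward recursion stays
linear in person-years, so the practical ceiling is the number of MCMC
iterations, not the latent-state bookkeeping.
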