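# crcover

Bayesian capture-recapture estimation of **over-coverage** in population
registers.

When a country documents its residents through administrative registers,
people who emigrate (or die abroad) without the event being recorded stay
on the books. The registered population then overstates the resident one —
*over-coverage* — which corrupts the denominators of mortality, fertility
and employment rates, most severely for migrant groups. The common
deterministic fix, the *register-trace* rule ("present in a year iff seen
in at least one register that year"), systematically overstates
over-coverage because newly arrived and loosely attached people are often
present yet undetected.

`crcover` fits a longitudinal multistate capture-recapture model to the
full register panel of every individual. Each person-year has a latent
state (present / absent / dead, with dead absorbing and presence forced in
the registration year), and all probabilities are covariate-linked through
logistic regressions on sex, age, country-of-birth group and time since
first migration:

- survival: logit φ_iy = xᵀβ_φ,
- staying given presence ψ_iy and returning given absence η_iy, so alive
  individuals follow Z_iy | Z_iy−1 ~ Ber(Z_iy−1 ψ_iy + (1 − Z_iy−1) η_iy),
- de-registering upon departure: λ_iy (after which absence is observed
  until the recorded re-registration),
- detection in list l while present: θ_iyl.

Coefficients get independent N(0, 2) priors. The latent trajectories are
marginalized exactly by a forward recursion (no latent-state sampling), the
coefficients are sampled by a blocked adaptive random-walk Metropolis
written in C++, and forward–backward smoothing yields the presence
probability Ẑ_iy of every undetected person-year. Over-coverage for any
year and subgroup D_y is

    OC_y = 1 − Σ_{i ∈ D_y} Ẑ_iy / |D_y|,

with Ẑ_iy = 1 on detected years, |D_y| the administratively registered set
(no recorded death, no unresolved de-registration), and credible intervals
from the per-draw smoothed probabilities. Because real register extracts
are access-restricted, the package ships a full generative simulator with
ground-truth latent trajectories, so the whole pipeline is testable by
parameter- and over-coverage-recovery experiments.

## Worked example

```r
library(crcover)

cfg    <- model_config(n_lists = 4, first_year = 2010, last_year = 2016)
spec   <- simulation_spec(1000, cfg)          # defaults emulate a migrant cohort
cohort <- simulate_cohort(spec, seed = 1)
cohort
#> Register cohort: 1000 individuals, 2010 - 2016 , 4 lists
#>    8044 positive list records, 305 events (ground truth attached)

fit <- mcmc_sample(cohort, n_iter = 4000, burnin = 1000, thin = 5,
                   n_chains = 2, seed = 2)
max(gelman_rubin(fit))
#> [1] 1.031

tab <- oc_table(cohort, fit)
subset(tab, year >= 2014)
#>    year subgroup         method estimate  lower  upper n_registered
#> 4  2014      all          model   0.0813 0.0795 0.0831          726
#> 5  2015      all          model   0.0906 0.0892 0.0920          837
#> 6  2016      all          model   0.1152 0.1130 0.1171          785
#> 10 2014      all register_trace   0.0992     NA     NA          726
#> 11 2015      all register_trace   0.1063     NA     NA          837
#> 12 2016      all register_trace   0.1248     NA     NA          785

true_overcoverage(cohort, 2016)
#> [1] 0.1172
```

Reading the output: in 2016, 785 people are administratively registered;
the model estimates that 11.5% of them (CrI 11.3–11.7%) had actually left,
very close to the simulator's ground truth of 11.7%, while the
register-trace rule claims 12.5%. The register-trace estimate is provably
never below the model's; the gap is widest for newly arrived cohorts, whose
undetected members are mostly still present.

Per-year presence probabilities for undetected person-years come from
`presence_posterior()`, summarized by detection-gap length via
`gap_summary()`: one silent year after a detection retains substantial
presence probability (~0.57 mean when the person reappears the next year,
in the cohort above), while 3–4 silent years push it towards zero.

A thin command line sits on top of the same functions
(`system.file("cli", "crcover.R", package = "crcover")`):

```sh
Rscript crcover.R simulate    --spec spec.yaml --out data/ --seed 7
Rscript crcover.R fit         --data data/ --out draws/ --chains 2 --seed 5
Rscript crcover.R estimate-oc --data data/ --draws draws/ --by sex --out oc.csv
Rscript crcover.R diagnose    --draws draws/
```

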