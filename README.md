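# basketadd

Design and analysis of Bayesian basket trials with a binary endpoint in
which **new baskets are added part-way through the study**.

A basket trial tests one treatment across several disease sub-populations
("baskets") sharing a molecular target. Each basket contributes
`Y_k ~ Binomial(n_k, p_k)` responders and tests `H0: p_k <= q0` against
`Ha: p_k > q0`; the treatment is declared effective in basket `k` when the
posterior probability `P(p_k > q0 | data)` strictly exceeds a calibrated
cut-off `Δ_k`. Borrowing between baskets uses the
exchangeability–nonexchangeability (EXNEX) mixture on the logit scale:

    θ_k = δ_k·M1_k + (1 − δ_k)·M2_k,   δ_k ~ Bernoulli(π_k)
    M1_k ~ N(μ, σ²)            (EX: shared hierarchical component)
    M2_k ~ N(m_k, ν_k²)        (NEX: basket-specific prior)
    μ ~ N(logit(q0), 10²),  σ ~ half-normal(0, 1)
    m_k = logit(ρ_k),  ν_k² = 1/ρ_k + 1/(1 − ρ_k)

The package provides:

* **`fit_exnex()` / `fit_independent()`** — posterior inference via a
  Metropolis-within-Gibbs sampler in C++ (exact Gibbs draws of the mixture
  indicators and hierarchical mean; Laplace-approximation independence
  Metropolis for each `θ_k`; adaptive random-walk for `log σ`), with
  exceedance probabilities, summaries and convergence diagnostics.
* **Four approaches for an added basket** (`analyse_trial()`,
  `calibrate_approach()`): IND (new baskets analysed independently), UNPL
  (unplanned addition: borrow at analysis, inherit the cut-off of the
  closest-sized existing basket), PL1a (one EXNEX model over all baskets
  for both calibration and analysis) and PL2a (separate EXNEX models for
  existing- and all-basket decisions).
* **Cut-off calibration** (`calibrate_global_null()`, `rcap_calibrate()`)
  — classical global-null calibration, and robust calibration across
  several weighted scenarios so the basket-wise type I error is controlled
  at the nominal level *on average* over plausible trial outcomes rather
  than only under the global null.
* **Simulators** (`run_fixed_study()`, `run_random_study()`) — fixed- and
  random-scenario operating characteristics (rejection rates, type I
  error, power, FWER, estimation summaries, pairwise decision
  discrepancies), with per-replicate seed substreams and common random
  numbers across approaches.

## Worked example

Four existing baskets of 24 patients; one new basket of 14 added
mid-trial. Analyse under the planned-addition approach PL2a with robustly
calibrated cut-offs:

```r
library(basketadd)

dat <- basket_data(y = c(7, 4, 5, 9, 3), n = c(24, 24, 24, 24, 14))
st  <- trial_structure(n_existing = rep(24, 4), n_new = 14)
cut <- cutoff_set(delta_existing = rep(0.903, 4), delta_new = 0.902)

analyse_trial("PL2a", dat, st, exnex_config(q0 = 0.2, q1 = 0.4), cut,
              mcmc_settings(n_chains = 1, n_warmup = 500,
                            n_samples = 2000, seed = 5))
#> Approach: PL2a 
#>  exceed_prob cutoff reject
#>       0.8775  0.903  FALSE
#>       0.5390  0.903  FALSE
#>       0.6450  0.903  FALSE
#>       0.9725  0.903   TRUE
#>       0.5800  0.902  FALSE
```

Only basket 4 (9/24 responders) clears its cut-off: its posterior
probability of exceeding the 20% null response rate is 0.9725 > 0.903.
Basket 1 (7/24) reaches 0.8775 — not enough under cut-offs calibrated to
hold a 10% error rate on average across heterogeneous scenarios. The new
basket's decision comes from the all-basket EXNEX fit (borrowing), while
existing-basket decisions deliberately ignore the new basket.

Calibrating those cut-offs yourself, at desk scale:

```r
fx <- make_fixture("reference")   # the 4+1 design and scenario tables
calibrate_approach("IND", fx$structure, fx$rcap_scenarios, R = 2000,
                   alpha = 0.10, config = fx$config,
                   mcmc = mcmc_settings(n_chains = 1, n_warmup = 500,
                                        n_samples = 2500),
                   method = "rcap", seed = 11)
#> scenario 'scenario3' has no basket at the null rate; it contributes
#> nothing to type I error calibration and is skipped
#> Efficacy cut-offs
#>   existing: 0.8932 0.8932 0.8932 0.8932 
#>   new:      0.898 
#>   calibrated by: rcap (R = 2000 , seed = 11 )
```

(Scenario 3 nulls only the new basket, which the IND approach calibrates
with the independent model, so it cannot contribute to the
existing-basket calibration and the procedure says so.) The reference
values at 10,000 replicates are 0.903 and 0.890; at `R = 2000` the
reproduction is within ±0.02.

A command-line front end wrapping these functions (subcommands
`calibrate`, `analyze`, `simulate`, `discrepancy`) is installed at
`system.file("cli", "basketadd", package = "basketadd")`.

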