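---
title: "Adding baskets to an ongoing basket trial: models, calibration and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adding baskets to an ongoing basket trial: models, calibration and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A basket trial tests one treatment across several disease sub-populations
("baskets") that share a molecular target. With a binary response endpoint,
basket $k$ contributes $Y_k \sim \mathrm{Binomial}(n_k, p_k)$ responders,
and the trial tests, per basket,
$$H_0\colon p_k \le q_0 \quad\text{vs.}\quad H_a\colon p_k > q_0,$$
declaring the treatment effective in basket $k$ when the posterior
probability $P(p_k > q_0 \mid \text{data})$ strictly exceeds a cut-off
$\Delta_k$. Because baskets are small, Bayesian information borrowing
between baskets is attractive; because borrowing couples the baskets, the
cut-offs must be calibrated by simulation to control the basket-wise type
I error rate.

This package addresses the situation where a *new* basket joins the trial
part-way through, typically with a smaller sample size than the baskets
that opened the trial. Two questions arise: which analysis model should
feed decisions for new and existing baskets, and under which simulation
scenarios should the cut-offs be calibrated.

## The EXNEX model

The exchangeability–nonexchangeability (EXNEX) mixture is the borrowing
model used throughout. On the logit scale $\theta_k = \mathrm{logit}(p_k)$,

$$\theta_k = \delta_k M_{1k} + (1-\delta_k) M_{2k}, \qquad
\delta_k \sim \mathrm{Bernoulli}(\pi_k),$$

with an exchangeable component $M_{1k} \sim N(\mu, \sigma^2)$ shared
across baskets (borrowing, with shrinkage controlled by $\sigma$) and a
nonexchangeable component $M_{2k} \sim N(m_k, \nu_k^2)$ specific to basket
$k$. The NEX hyperparameters come from a plausible response rate
$\rho_k$: $m_k = \mathrm{logit}(\rho_k)$ and
$\nu_k^2 = 1/\rho_k + 1/(1-\rho_k)$, roughly one observation's worth of
information. Priors are $\mu \sim N(\mathrm{logit}(q_0), 10^2)$ and
$\sigma \sim \text{half-normal}(0, 1)$, a deliberately conservative choice
for the borrowing strength. The *independent* analysis model used for new
baskets under the IND approach places
$\theta_k \sim N(\mathrm{logit}(q_0), 10^2)$ with no cross-basket terms.

Defaults mirror the reference design this package is organised around:
$q_0 = 0.2$, $q_1 = 0.4$, $\pi_k = 0.5$ (no prior preference for
exchangeability), $\rho_k = 0.3$ (a marginally effective rate between
null and target).

### Sampling

`fit_exnex()` runs a Metropolis-within-Gibbs sampler written in C++:

* $\delta_k$ and $\mu$ have conjugate full conditionals and are drawn
  exactly (the mixture indicator's conditional odds are
  $\pi_k N(\theta_k;\mu,\sigma) : (1-\pi_k) N(\theta_k; m_k,\nu_k)$);
* each $\theta_k$ uses an independence Metropolis step whose proposal is
  the Laplace (normal) approximation of its log-concave conditional
  posterior, recomputed by a short damped Newton iteration every sweep
  and inflated by 30% so the proposal dominates the target's tails;
  acceptance rates are typically above 0.85 and the draws are close to
  independent;
* $\log\sigma$ uses a Gaussian random-walk step whose scale adapts during
  warmup only (Robbins–Monro targeting 44% acceptance), so the
  post-warmup chain is a fixed-kernel Markov chain;
* the half-normal prior on $\sigma$ enters through its log-density with
  the Jacobian of the log transform.

The sampler uses R's RNG, so a seed gives bit-identical draws. Defaults
for a single interactive analysis are 4 chains of 2,500 warmup and 2,500
kept iterations; simulation loops use 1 chain of 500 warmup and 2,500
kept draws per fit, which resolves exceedance probabilities to roughly
±0.01 and keeps tens of thousands of fits tractable. Split R-hat is
always computed; R-hat > 1.05 or effective sample size < 400 is recorded
as a warning in the fit's diagnostics and never alters results. Logit
densities are evaluated with `log1pexp`-style guards; reported draws are
never clamped.

Degenerate settings are exact special cases rather than separate code
paths: $\pi_k = 0$ reproduces independent fits under the NEX priors,
$\pi_k = 1$ a fully exchangeable hierarchical model.

## Four approaches for an added basket

With $K_0$ existing baskets and $K' = K - K_0$ new ones:

| Approach | Calibration (existing / new) | Analysis (existing / new) |
|----------|------------------------------|---------------------------|
| IND  | EXNEX on existing / independent | EXNEX on existing / independent |
| UNPL | EXNEX on existing / inherited by sample-size match | EXNEX on all baskets |
| PL1a | EXNEX on all baskets (one calibration) | EXNEX on all baskets |
| PL2a | EXNEX on existing / EXNEX on all | EXNEX on existing / EXNEX on all |

UNPL models an *unplanned* addition: the trial was calibrated for the
existing baskets only, and the new basket inherits the cut-off of the
existing basket with the closest sample size (ties go to the smallest
basket index — the rule needs a deterministic tie-break and the smallest
index is the natural one). PL1a and PL2a are *planned* additions with the
timing (hence all sample sizes) known at calibration. Under IND, several
new baskets are analysed with no borrowing among themselves either; the
independent model has no cross-basket terms, so fitting them jointly or
one at a time is the same model.

Because UNPL and PL1a share their analysis model, and IND and PL2a share
their existing-basket model, `run_fixed_study()` fits each distinct model
once per simulated dataset and shares draws across approaches (common
random numbers). This is what makes pairwise comparisons between
approaches meaningful at moderate replication counts. When PL2a is
analysed, the all-basket fit's existing-basket posteriors are kept in the
returned object but never feed decisions.

## Calibrating the cut-offs

`calibrate_global_null()` is the classical procedure: simulate the global
null (every $p_k = q_0$), collect each basket's exceedance probabilities,
and set $\Delta$ at their empirical $(1-\alpha)$-quantile. Borrowing
models calibrated this way can badly inflate type I error when some
baskets respond: posterior probabilities of truly null baskets are pulled
up toward the effective ones.

`rcap_calibrate()` implements robust calibration across $M$ scenarios
$p_1,\dots,p_M$ with positive integer weights $\omega_m$: for each
scenario, $R$ datasets are simulated and fitted; for each basket whose
true rate is $q_0$ (the only baskets where a type I error exists),
$\omega_m$ copies of its exceedance probability are appended to that
basket's store; stores of baskets with equal sample size are pooled; and
each sample-size class takes the empirical $(1-\alpha)$-quantile of its
pooled store. Type I error is then controlled at $\alpha$ *on weighted
average* across the scenarios. Scenarios with no null basket cannot
contribute and are skipped with a message; a sample-size class that no
scenario nulls is an error, because its cut-off would be undefined.

Numerical conventions, chosen once and used everywhere:

* **Quantile.** The order statistic at index
  $\lceil (1-\alpha) N \rceil$, without interpolation. With the strict
  rejection rule `prob > delta`, at most $\alpha N$ of the stored values
  would reject — a conservative and exactly reproducible convention. An
  interpolated quantile could differ in the third decimal.
* **Equal-$n$ pooling.** Stores are concatenated before the quantile
  rather than averaging per-basket quantiles afterwards; this guarantees
  identical cut-offs for equal-sized baskets and uses the draws
  symmetrically.
* **Weights as replication.** $R$ is the number of replicates per
  scenario per *unit* weight; weight $\omega_m$ stores $\omega_m$ copies
  of each replicate's value rather than simulating $\omega_m R$ fresh
  datasets.
* **Seed substreams.** Each (scenario, replicate) pair runs under a seed
  derived from the master seed, a content hash of the scenario and the
  replicate index. Deriving from content rather than list position makes
  a weight of 2 *exactly* equivalent to listing the scenario twice, and
  lets any single replicate be replayed in isolation.

The condition selecting which posterior quantities enter the store, and
the quantity itself, generalise to other metrics (the procedure is not
specific to type I error); only the type I error metric is shipped and
tested here.

## The simulators and what the generator emulates

`generate_trial()` draws independent binomial counts per basket — exactly
the sampling model assumed by the analysis. The packaged `"reference"`
fixture is the 4+1 design the package's results are organised around:
four existing baskets of 24 patients, one new basket of 14 (sample sizes
from a two-stage design targeting 10% error and 80% power), $q_0 = 0.2$,
$q_1 = 0.4$, ten fixed scenarios crossing effective (0.4) and
ineffective (0.2) rates, robust calibration over scenarios 1, 2, 3, 7, 8
for IND/PL1a/PL2a, and four existing-basket scenarios for UNPL.

`run_fixed_study()` estimates per-basket rejection rates, type I error,
power, family-wise error, the all-correct rate and estimation summaries,
with Monte Carlo standard errors. `run_random_study()` draws the new
basket's true rate uniformly from an interval (one dataset per drawn
scenario, reading the study description literally), analyses every
approach on the same data, and tabulates basket-level decision
disagreements per approach pair together with which side was correct. A
basket's correct decision is "reject" precisely when its true rate
exceeds $q_0$; this is the only labelling consistent with the hypotheses,
and it applies equally to rates drawn between $q_0$ and the target (the
"marginally effective" interval). Under binary truth a disagreement has
exactly one correct side, so the exclusion of both-wrong records is
implemented but vacuous.

What the generator does **not** emulate: over-dispersion between patients
within a basket, drift in response rates over calendar time, unequal or
random accrual (sample sizes are fixed at analysis), interim looks, and
multi-arm structure. Passing tests therefore demonstrate correctness of
the inference and calibration machinery under the stated binomial model,
not robustness of the design to violations of it.

## Problem sizes and reproduction

The package's own reproduction checks (the test suite and
`scripts/acceptance.R`) run at desk scale: calibrations use
$R = 2{,}000$ replicates per scenario and operating characteristics
2,000 datasets per scenario, with single-chain fits of 500 warmup and
2,500 kept draws. At these sizes a rejection proportion near 10% carries
a Monte Carlo standard error of about 0.7 percentage points, and
calibrated cut-offs reproduce their 10,000-replicate reference values to
within ±0.02. One deliberately fragile quantity is the IND approach's
new-basket power when every basket is effective: with $n = 14$ and
cut-off 0.890 the decision sits on the discreteness of the binomial — at
$y_5 = 5$ the exact exceedance probability is 0.9005, so the rejection
rate depends on posterior Monte Carlo noise at the third decimal, and
reproductions should be read with that in mind.

The random-scenario discrepancy study is the one place that demands much
higher per-fit precision (20,000 kept draws rather than 2,500). Its
metric counts baskets where two approaches' exceedance probabilities fall
on opposite sides of their cut-offs, so it is sensitive to posterior
Monte Carlo noise near the cut-offs: spurious disagreements dilute or
skew the directional difference in correct conclusions depending on which
approach sits closer to its threshold. When the new basket is effective
the estimate converges cleanly as draws increase; when every basket is
ineffective, discrepancies are rare (under a tenth of trials) and the
metric remains sensitive to the per-fit noise level even at high
precision, so reproductions of that setting are inherently softer than
the rest.

## Known limitations

* Binary endpoints only; no continuous, count or time-to-event outcomes.
* No interim analyses or futility stopping; decisions are terminal.
* Calibration is simulation-based throughout; no analytic shortcuts.
* The random-walk sampler is tuned for the small-to-moderate basket
  counts typical of these designs (tested to $K = 5$); very many baskets
  would warrant a gradient-based sampler.
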