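---
title: "A Markov cohort cost-utility model of castration therapy in prostate cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model of castration therapy in prostate cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcacea)
```

## The modelling problem

Medical castration for prostate cancer can be achieved with a GnRH agonist
(leuprorelin, which requires anti-androgen cover against the initial
testosterone flare) or a GnRH antagonist (degarelix, which does not). The
antagonist delays PSA recurrence but costs more per cycle. Whether it is
worth the premium is a cost-utility question: over a 30-year horizon, does
the extra time spent on first-line therapy — at higher utility and before
the expensive second-line cascade — buy enough quality-adjusted life years
(QALYs) to justify the incremental cost at the payer's willingness-to-pay
(WTP) threshold?

`pcacea` implements this comparison as a cohort-level Markov model from a
healthcare-system perspective, with costs in yuan and a WTP threshold of
three times GDP per capita (80,976 yuan in 2021, so 242,928 yuan/QALY).

## Model structure

Nine mutually exclusive health states form a forward-only treatment
cascade:

1. `first_line` — castration therapy (the compared arms differ only here in
   drug cost and in their PSA-progression curves);
2. `aa_addition` — anti-androgen added on PSA recurrence;
3. `aa_withdrawal` — anti-androgen withdrawn after failure;
4. `docetaxel` / `abiraterone` — on exit from withdrawal, a configurable
   fraction (0.35 by default) skips chemotherapy and goes directly to
   abiraterone; the rest receive docetaxel, whose failures proceed to
   abiraterone;
5. `post_abiraterone` — continued treatment after abiraterone failure;
6. `supportive_care`, then `palliative_care`;
7. `death` — absorbing, reachable from every state.

The cycle length is 28 days (one dosing interval) and the horizon 30 years,
giving `floor(30 * 365.25 / 28) = 391` transition cycles after the initial
state. The cohort starts at age 68 entirely in `first_line`.

Transitions out of each state combine three probability rules:

* **per-cycle-from-survival**: first-line exit uses the conditional
  progression probability `p_i = 1 - S((i+1)c)/S(ic)` derived from the
  arm's parametric PSA-progression curve, so the per-cycle probabilities
  telescope back to the curve exactly;
* **response-persistence**: each second-line state keeps its occupants with
  the per-cycle response rate (0.83 anti-androgen addition, 0.83
  withdrawal, 0.91 docetaxel, 0.84 abiraterone) and releases the rest to
  the next state in the cascade;
* **competing mortality**: every non-death state has a death edge with the
  background per-cycle probability at the cohort's attained age, scaled by
  a state-specific hazard ratio; the non-death destinations are rescaled by
  `1 - p_death` so rows stay stochastic.

Two readings of the source material were genuinely open and are resolved as
configuration defaults rather than hard-coded choices. First, the mortality
hazard ratio of 2.39 attached to "PSA progression/metastatic" disease is
applied to *every* post-progression state (a per-state map
`mortality.state_hr` lets users restrict it to metastatic states only).
Second, all docetaxel non-responders are routed to abiraterone rather than
directly to supportive care; the transition map is parameter-driven, so the
alternative reading is runnable by editing the response-rate chain. Source
tables also report a mean duration of response alongside the per-cycle
rates, and the two are mutually inconsistent under any single cycle-length
convention (12 months of response does not square with a 0.91 per-cycle
continuation); the per-cycle rates are taken as authoritative because the
engine consumes per-cycle probabilities directly.

Palliative care exits only to death. Its default death probability is
background mortality times the post-progression hazard ratio, which keeps
the parameterization honest (no invented excess rate) at the price of
comparatively long palliative stays; a larger state-specific hazard ratio
can be configured.

No half-cycle correction is applied by default, because the source model
does not mention one; `settings.half_cycle_correction = TRUE` enables the
standard start/end-of-cycle average for comparison.

## Survival extrapolation

The trial window for PSA progression was 12 months, so the 30-year model
needs parametric extrapolation. Five families are supported, with fixed
parameterizations (time in days):

| family      | S(t)                                  |
|-------------|---------------------------------------|
| exponential | `exp(-λt)`                            |
| Weibull     | `exp(-λt^γ)`                          |
| log-logistic| `1/(1 + λt^γ)`                        |
| lognormal   | `1 - Φ((ln t - μ)/σ)`                 |
| Gompertz    | `exp(-(λ/γ)(e^{γt} - 1))`             |

Fitting maximizes the right-censored log-likelihood
`Σ d_i log h(t_i) + Σ log S(t_i)` by Nelder–Mead on log-transformed
parameters (the Gompertz shape stays untransformed and may be negative, in
which case the curve plateaus — documented, and relevant only if a user
fits their own data). Three starting points guard against local optima;
convergence tolerance is `1e-10` on the relative objective;
non-convergence raises an error rather than returning silently. The
exponential rate uses its closed form, events divided by total follow-up.
Model selection is by AIC (`2k - 2 log L`), with ties broken first by
fewest parameters and then by a fixed family order.

The treatment effect enters as a hazard ratio applied on the
cumulative-hazard scale, `S_treated = S_ref^HR` — the conventional
proportional-hazards reading; the reference (leuprorelin) curve is the one
fitted, mirroring the source analysis. Setting `survival.mode =
"independent"` instead uses separately configured per-arm parameters, for
users with arm-level data.

## Background mortality

An age-specific life table is smoothed by least squares with a
three-parameter logistic `q(a) = L/(1 + exp(-k(a - a0)))` — the simplest
reading of fitting mortality "by logistic curve" — via `nlsLM`, with a flat
fallback for degenerate (constant) tables. A raw table with linear
interpolation and flat extrapolation beyond its last age is available as
`mortality.model = "table"`. Annual probabilities convert to per-cycle ones
under a constant hazard within the year,
`p = 1 - exp(-hr · (-ln(1-q)) · c/365.25)`, with hazard ratios multiplying
the hazard (a probability-scale multiplier could exceed 1). Compounding
`365.25/c` cycles at `hr = 1` recovers the annual probability exactly; the
test suite asserts this to `1e-9`.

The default logistic parameters (`L = 0.7`, `k = 0.09`, `a0 = 97`) give an
annual death probability of about 4.8% at age 68 rising steeply through the
90s — a plausible elderly-male profile for the generator's purposes, chosen
once as the synthetic stand-in for a census life table.

## Economics

Costs accrue per state per cycle from four components: first-line drug cost
(degarelix 8,900 yuan in cycle 0 and 3,200 thereafter; leuprorelin 1,389.29
per cycle plus 28 days of anti-androgen flare cover at 169.37/day in cycle
0 only), second-line drug costs charged as the quoted daily price times 28
(with dexamethasone co-medication for docetaxel and abiraterone),
state-level management costs (the printed per-cycle figures for
post-abiraterone continuation, supportive and palliative care), and
administration costs attached through a per-state frequency map over GP
visits, scans and blood tests. Adverse events contribute an expected
per-cycle cost — incidence times a severity-mixed event cost — and an
expected utility decrement applied for one cycle per event, while the
cohort is on first-line therapy.

Both costs and QALYs discount at 5% per year, converted per cycle as
`(1+r)^(-cycle · c/365.25)`; the two rates are separately configurable
because one-way analysis varies the cost rate alone. Accrual uses
start-of-cycle occupancy over the 391 cycles.

The comparison reports incremental cost, incremental QALYs, the ICER
`ΔC/ΔE` (labelled `dominant`/`dominated`/`undefined` in the degenerate
quadrants rather than raising), the incremental net benefit
`INB = wtp·ΔE − ΔC`, and the ICER as a GDP-per-capita multiple. Reported
yuan values round to the nearest integer and QALYs to three decimals,
matching the source's table formatting.

## Sensitivity battery

* **One-way (tornado)**: each parameter is set to its low and high value
  with everything else at base and the full model re-run twice; rows sort
  by descending ICER range (stable sort). Default ranges follow convention:
  ±20% for costs, ±10% for efficacy parameters and utilities, 0–8% for the
  cost discount rate.
* **Scenarios**: pure path-edit re-runs (`scenario_run()` never mutates its
  input), with a standard battery of the maintenance price at its 1×-GDP
  threshold, a 10-year horizon, and a double-dose comparator.
* **Threshold price**: bisection on the addressed price until the ICER is
  within 1 yuan/QALY of target or the bracket is narrower than 0.01 yuan;
  requires the target to be bracketed and relies on the ICER being affine
  in any single price (the incremental QALYs do not depend on prices).
* **Probabilistic (PSA)**: 5,000 Monte-Carlo iterations by default. The
  source does not state its distribution choices, so the standard
  cost-effectiveness conventions are used: gamma for costs and prices, beta
  for utilities and probabilities, log-normal for hazard ratios, each
  moment-matched to the base value with a 20% relative standard error
  (configurable). Draws are parameter-major under one root seed, so adding
  a parameter to the list never scrambles the draws of earlier ones;
  out-of-domain draws are rejected and redrawn with a hard cap. The
  acceptability curve is `CEAC(wtp) = mean(INB > 0)` over a 0–300,000 yuan
  grid covering 1×–3× GDP.

Because the PSA distributions and several base-case inputs are synthetic
defaults, the published probabilities of cost-effectiveness (53%/62%/81%)
are illustrative context, not reproduction targets.

## The synthetic-data generators

`gen_survival()` draws two-arm right-censored progression times by inverse
CDF from any of the five families (`T = ((1-U)/(λU))^{1/γ}` for the
log-logistic), with the treated arm sampled from `S_ref^HR`, administrative
censoring at 364 days (a 12-month window of thirteen 28-day cycles) and
optional uniform dropout. `gen_life_table()` evaluates the logistic
mortality curve on integer ages. `gen_fixture()` returns the complete
parameter set with a machine-readable provenance tag per leaf: `printed`
for values carried verbatim from the source tables, `synthetic` for the
documented defaults filling the gaps. Tests assert published values only
against `printed` fields.

What the generators emulate: the censoring pattern of a fixed-window trial,
a proportional-hazards treatment effect, and the sigmoid age-profile of
elderly mortality. What they do not: PSA-level trajectories and the
50%-rise recurrence definition (events exist only as times), covariate
heterogeneity, informative censoring, and calendar effects. Passing tests
therefore demonstrate internal correctness of the pipeline — likelihoods,
transition algebra, accounting identities, Monte-Carlo plumbing — not
agreement with any real cohort.

## Numerical choices and degenerate inputs

* Mass conservation is enforced at `1e-9` per row; the engine raises on
  any out-of-range probability rather than clipping silently.
* `per_cycle_progression_prob()` errors when survival at the cycle start
  is zero (the cohort has fully progressed) instead of returning 0/0.
* The fixture's synthetic log-logistic parameters (`λ = 1e-4`, `γ = 1.3`)
  put the median time to PSA progression near 3.3 years; the synthetic
  PSA-recurrence hazard ratio is 0.70 in favour of the antagonist. Both are
  provenance-tagged and chosen once as plausible magnitudes.
* Degenerate PSA distributions (zero RSE) reproduce the deterministic
  result bit-for-bit; beta variance requests near the feasibility boundary
  are capped at 95% of the maximum for the given mean.
* Test problem sizes: parameter recovery at n = 2,000 over 20 seeds
  (median relative error under 10%), AIC family recovery at n = 5,000 over
  20 seeds (at least 18 recoveries), trace-versus-microsimulation
  validation with 100,000 simulated patients against the 9-state trace at
  three-sigma binomial bands, and short-horizon (3–5 year) fixtures for
  the fast identity checks.

## Known limitations

* The model is cohort-level; patient heterogeneity appears only in the
  microsimulation used as a validation oracle.
* Second-line "response" is a single per-cycle persistence probability;
  re-challenge, treatment holidays and switching are out of scope.
* Costs are healthcare-system only (no productivity or transport costs,
  no price-year inflation adjustment).
* Utilities are state-constant; adverse-event decrements last one cycle.
* The base-case totals depend on synthetic defaults wherever the source
  did not print a value, so absolute fixture outputs are demonstrations of
  the machinery, not re-estimates of the published totals.

## A worked run

```{r}
params <- gen_fixture()
res <- run_cea(params)
res
result_table(res)
```

```{r}
thr <- threshold_price(params, "prices.degarelix_maintenance",
                       params$economics$gdp_per_capita)
sprintf("maintenance price at 1x GDP: %.2f yuan (%.2f%%)",
        thr$price, thr$pct_change)
```
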