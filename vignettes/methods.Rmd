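---
title: "Model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`esccea` compares two strategies for locally advanced esophageal squamous
cell carcinoma — definitive chemoradiation (CRT) and chemoradiation
followed by esophagectomy (CRT+S) — with a decision-tree treatment phase,
a monthly Markov cohort model, phase-of-care costing, and deterministic
and probabilistic sensitivity analysis. This vignette records the model
structure, the choices we made where the published description is silent,
and what the synthetic fixtures do and do not emulate.

## Cohort and horizon

The cohort is 57-year-old men at diagnosis, followed for 25 years in
monthly cycles (300 cycles). Costs (2017 USD) and QALYs are both
discounted at 3% per year. The discount factor of cycle $t$ is
$(1+r)^{-(t-1)/12}$ — annual-rate compounding rather than $r/12$, the
standard convention in cost-effectiveness practice — so the first cycle
is undiscounted.

## Treatment phase

Cycles 1–3 form the treatment phase. The only event is treatment-related
mortality (TRM): the published 3-month probabilities (0.0052 CRT, 0.0926
CRT+S) are converted to monthly probabilities via
$1-(1-p)^{1/3}$ and applied in each phase cycle, *replacing* background
mortality rather than adding to it — the treatment-phase decision tree
shows TRM as the only death mechanism in the first 90 days, and the trial
survival targets used to calibrate the fixtures already include these
deaths. Survivors enter the Markov model healthy. During the phase every
alive state carries the arm's treatment utility (0.770 CRT, 0.300 CRT+S)
regardless of health state.

## Markov structure

Seven states: healthy, local recurrence, distant recurrence — each with
and without chronic side effects — and absorbing death. Within a cycle,
events apply in a fixed order as products of conditional probabilities,
which keeps every transition row summing to one by construction:

1. **Death**, with a state-independent, arm-dependent probability (the
   trial evidence is overall survival, not state-specific survival).
2. **Recurrence** among survivors: from healthy, distant recurrence with
   probability $p_{DR}$, *else* local recurrence with $p_{LR}$ (distant
   takes clinical precedence when both could fire in one month); from
   local recurrence, distant recurrence with the same $p_{DR}$; distant
   recurrence is absorbing apart from death. The published figure does
   not legibly pin down every permitted arrow; allowing local→distant at
   the common monthly rate is our choice, and the sensitivity machinery
   can vary the recurrence probabilities that drive it.
3. **Side-effect onset** with probability $p_{SE}$ from any alive state
   without side effects. Side effects are chronic, hence permanent, and
   orthogonal to the recurrence transition in the same cycle.

There is no half-cycle correction (the source analysis never mentions
one); state membership is read at cycle end for both costs and QALYs.

Local recurrence follows the published year bands (CRT: 0.0237/month in
years 1–4; CRT+S: 0.0208/month in years 1–2; zero afterwards), with
"year $k$" meaning post-diagnosis cycles $12(k-1)+1$ to $12k$, treatment
phase included in year 1. The monthly distant-recurrence probabilities
are stored at full precision as $1-(1-p_{2yr})^{1/24}$ from the
published two-year probabilities (0.291 CRT, 0.391 CRT+S), so they print
as 0.0142 and 0.0205 at four decimals and compound back to the two-year
values exactly. Death in years 1–4 comes from the fixture vectors
(below); from year 5 the annual life-table probability at the attained
age (57 + completed years, constant within a year) is converted to
monthly form.

## Utilities

State utilities (healthy 0.770, local recurrence 0.460, distant
recurrence 0.150) apply to the CRT arm; the CRT+S arm subtracts the
long-term esophagectomy decrement 0.043 (giving 0.727/0.417/0.107),
clamped to $[0,1]$. After month 12 the arms equalize: both use the
per-state maximum across arms, implementing the published
max-over-arms footnote, from cycle 13 onward. Side effects subtract
0.350 from the underlying state utility with a floor at zero — the
distant-recurrence value would otherwise go negative, and states worse
than death are not modelled. Death is worth zero.

## Phase-of-care costs

Annual phase costs divide by 12 into monthly accruals. Given a death
cycle $\tau$, the last 12 months of life are end-of-life; months
$\le 12$ not claimed by end-of-life are initial (so anyone dying within
the first year accrues only end-of-life months); the remainder are
continuing. A patient dying in cycle $\tau$ accrues months $1..\tau$;
horizon survivors accrue 12 initial + 288 continuing months and never
receive end-of-life costs (no terminal correction beyond the horizon).
End-of-life costs accrue monthly rather than as a lump at death; the two
coincide undiscounted and differ only slightly under discounting. Costs
are phase-based only — the published table has no per-state costs — so
recurrence affects cost solely through survival; this is a limitation
inherited from the source data. The expected cost decomposes the cohort
by death cycle using the per-cycle death incidence and is evaluated in
closed form from cumulative discount sums.

## Synthetic fixtures

Two inputs were never published and are generated, flagged `FIXTURE`,
and serialized with provenance into every output:

* **Years 1–4 monthly death rates.** A mortality spec targets cumulative
  overall survival at months 24 and 48 per arm. Defaults emulate the
  randomized trial the published death rates are drawn from: 0.40 (CRT)
  versus 0.34 (CRT+S) at two years, equal conditional survival (~0.675)
  over years 3–4. Two constant segments per arm are calibrated with the
  exact closed form $q = 1 - S^{1/m}$, composed so that realized model
  survival — TRM replacing background death in cycles 1–3 — hits both
  targets exactly.
* **Life table.** A Gompertz hazard $h(a) = \ell e^{ba}$ with
  $\ell = 6.59\times10^{-5}$, $b = 0.085$, giving annual mortality
  around 0.0117 at age 61 rising to about 0.06 by age 80, in the range
  of a US male cohort over the ages the model visits.

What passing tests show, and what they do not: the engine, costing,
comparison and sensitivity machinery are verified against closed forms
and an independent microsimulation, and the packaged analysis reproduces
the published *qualitative* picture (CRT dominant at base case, the same
parameters dominating the tornado, preference flipping to CRT+S when the
distant-recurrence probabilities are equalized). Because the fixture
death rates are stand-ins, headline magnitudes are comparable to the
published ones but not digit-identical, and nothing here validates the
model against patient-level data.

## Sensitivity analysis

The deterministic registry varies every probability, utility, decrement,
phase cost, TRM and the fixture death-rate scale factors by ±50% (95%
CIs can be supplied and take precedence), clipping probabilities and
utilities to $[0,1]$. Runs are pure — the base parameter set is never
modified — and a parameter change that would push any monthly
probability outside $[0,1]$ fails loudly rather than being renormalized.
Threshold search brackets a sign change of the INMB, verifies
monotonicity on a coarse 9-point grid, and bisects to an INMB tolerance
of $1 (or an interval below $10^{-9}$ of scale).

One interaction worth knowing: the INMB is monotone in the
distant-recurrence utility only below the side-effect decrement (0.350).
Above it, distant-recurrence-with-side-effects months regain positive
utility and the arm with the higher side-effect rate (CRT) benefits,
producing a kink. Threshold searches on that utility are therefore run
on $[0.15, 0.35]$.

The PSA assigns method-of-moments distributions by parameter type — beta
for probabilities and utilities, gamma for costs and the positive scale
factors — with mean equal to the base value and standard deviation equal
to the registry range width divided by 3.92 (for an unclipped ±50% range,
0.2551 × base). Zero-mean or zero-width parameters become point masses;
infeasible beta moments are clipped to 99% of the feasible maximum with
a warning. Parameters are drawn independently (no correlation structure
was published); shared parameters (continuing and end-of-life costs, the
side-effect decrement, the linked state utilities) are drawn once per
iteration and applied to both arms so incremental results are not
inflated by spurious between-arm noise. One master seed spawns one
substream per iteration, so results are bit-reproducible and independent
of evaluation order; draws that produce an invalid parameter set (e.g. a
scaled death probability above one) are rejected and redrawn within
their substream, with a reported count. CEAC ties in net monetary
benefit split equally between strategies; the frontier takes the higher
mean net benefit, preferring CRT on exact ties. The default
willingness-to-pay grid is $0–$300,000 in $10,000 steps.

## Verification strategy and problem sizes

The cohort algebra is checked against an independent individual-level
microsimulation with the same event logic, in which every simulated
patient has an exact death time and accrues phase-of-care costs month by
month. The packaged comparison runs both routes at $n = 100{,}000$
patients and compares occupancy, expected cost and expected QALYs. A
note on tolerances: per-cell agreement is judged at 3 binomial standard
errors, but across 300 cycles × 7 states a handful of chance exceedances
is expected from multiplicity alone, so the suite requires at least
99.7% of cells within 3 SE, no cell beyond 4.5 SE, and both totals
within 3 SE — the per-cell tolerance is unchanged; only simultaneous
coverage is judged at the family level. Deterministic checks use exact
closed forms (25.0 QALYs for an undiscounted, risk-free, unit-utility
cohort; uniform phase costs collapsing to cost per discounted
person-month; degenerate point-mass PSA reproducing the base case to
machine precision). Threshold searches are validated against 1,000-point
grid scans. The full PSA uses 10,000 iterations; stability across master
seeds is judged at 3 Monte-Carlo standard errors on the CEAC.

## Known limitations

* Costs are phase-based, not state-based; recurrence affects cost only
  through survival.
* Death is state-independent within an arm, as in the source evidence.
* No recovery from recurrence states, no treatment switching, no
  individual-level heterogeneity (age/sex mixtures).
* The frontier logic is written for exactly two strategies.
* Fixture mortality is piecewise-constant over two-year blocks; the
  published model's unprinted rates may vary monthly.
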