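# esccea

Cost-effectiveness analysis of definitive chemoradiation (CRT) versus
chemoradiation followed by esophagectomy (CRT+S) for locally advanced
esophageal squamous cell carcinoma, implemented as a tested, reusable R
package. It is aimed at health-economics and outcomes researchers who want
to reproduce, stress-test or extend the published comparison rather than
rebuild a spreadsheet model.

## The model

A decision-tree treatment phase feeds a monthly Markov cohort model:

* **Treatment phase (cycles 1–3).** The whole cohort (57-year-old men at
  diagnosis) undergoes treatment; the only event is treatment-related
  mortality (3-month probability 0.0052 for CRT, 0.0926 for CRT+S,
  applied monthly as `1 − (1 − p)^(1/3)`). Survivors enter the Markov
  model healthy.
* **Markov model (cycles 4–300, 25-year horizon).** Seven states: healthy,
  local recurrence, distant recurrence — each with and without chronic
  side effects — and death. Each cycle applies, in order, death (arm-
  dependent trial-based rates in years 1–4, life-table rates at the
  attained age thereafter), recurrence (distant takes precedence; local
  recurrence follows published year bands), and permanent side-effect
  onset.
* **Outcomes.** Costs use phase-of-care accounting: every alive month is
  initial (first 12 months; $94,128/yr CRT, $133,290/yr CRT+S),
  end-of-life (last 12 months before death; $126,959/yr) or continuing
  ($7,893/yr), with death inside the first year counted as end-of-life.
  QALYs weight occupancy by state utilities (healthy 0.770, local
  recurrence 0.460, distant recurrence 0.150; CRT+S values carry a −0.043
  esophagectomy decrement until both arms equalize after month 12; side
  effects subtract 0.350). Costs and QALYs are discounted at 3%/yr.
* **Comparison.** For strategies with costs `C` and QALYs `E`, the package
  reports ΔC, ΔE, the ICER `ΔC/ΔE` where defined, dominance, and the
  incremental net monetary benefit `INMB(λ) = λ·ΔE − ΔC` at a
  willingness-to-pay λ (default $150,000/QALY), plus one-way/two-way
  deterministic sensitivity analysis, threshold search, and probabilistic
  sensitivity analysis with CEAC/CEAF.

The arm-specific monthly death probabilities for years 1–4 and the
background life table were never published; the package generates
clearly-labelled synthetic stand-ins (survival-calibrated two-segment
death rates, a Gompertz life table) so the full pipeline runs without any
external data. Headline numbers therefore track the published analysis
qualitatively, not digit-for-digit; see `vignettes/methods.Rmd`.

## Worked example

```r
library(esccea)

params <- base_case_params()    # published base case + labelled fixtures
cea <- run_base_case(params)
cea
#> <esc_cea> base-case cost-effectiveness, CRT vs CRT+S
#>   CRT   $166,345 for 1.432 QALYs
#>   CRTS  $168,254 for 1.318 QALYs
#>   dominance: a_dominant; INMB(CRT) at $150,000/QALY: $18,922
```

CRT costs less and yields more QALYs, so it dominates; the INMB says that
at $150,000/QALY society would be $18,922 per patient better off with CRT.
Sensitivity analysis shows which inputs could overturn this:

```r
reg  <- dsa_registry(params)        # ±50% ranges (95% CIs can be supplied)
one_way_dsa(params, registry = reg[reg$id %in%
  c("p_distant.crts", "c_initial.crts", "p_distant.crt", "u_distant"), ])
#> # A tibble: 4 × 6
#>   id                 low      high inmb_low inmb_high  width
#> 1 p_distant.crts   0.0102    0.0307  -28214.    41250. 69465.
#> 2 c_initial.crts 66645    199935     -11808.    49652. 61461.
#> 3 p_distant.crt    0.00711   0.0213   58146.    -2731. 60877.
#> 4 u_distant        0.075     0.225    33285.     4560. 28725.

threshold_search(params, "c_initial.crts")
#> # A tibble: 1 × 7
#>   id             found threshold inmb_at_threshold lower  upper monotone
#> 1 c_initial.crts TRUE     92255.             0.888 66645 199935 TRUE
```

The distant-recurrence probabilities and the CRT+S initial-phase cost are
the biggest levers: negative `inmb_low`/`inmb_high` entries mark scenarios
where CRT+S becomes the preferred strategy, and CRT+S would be
cost-effective if its initial-phase cost fell to about $92,000. Parameter
uncertainty is propagated with `run_psa(params, n_iterations = 10000,
seed = 1)`, whose `ceac` element and `plot_ceac()` show how often each
strategy wins across willingness-to-pay values; `autoplot()` methods draw
the occupancy trace and the incremental cost-effectiveness plane, and
`tidy()`/`glance()` return tibbles for further analysis.

`run_analysis()` drives the same machinery from a YAML configuration and
writes stamped CSV outputs (`results.csv`, `tornado.csv`, `twoway.csv`,
`psa_samples.csv`, `ceac.csv`, fixture exports).

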