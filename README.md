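# vtecea

Cost-utility analysis of venous-thromboembolism (VTE) prophylaxis
strategies after elective total hip (eTHR) and total knee (eTKR)
replacement, for health economists and guideline analysts comparing
pharmacological, mechanical and combination prophylaxis from a
health-system perspective.

## The model

A 90-day decision tree chained to a lifetime annual-cycle Markov cohort
model:

- **Acute phase (days 0–90):** mutually exclusive terminal branches over
  DVT (symptomatic/asymptomatic × proximal/distal), non-fatal and fatal
  PE, major bleeding (surgical site → return to theatre; GI with 13%
  intervention; intracranial haemorrhage → permanent disability; other),
  clinically relevant non-major bleeding with its wound-haematoma →
  surgical-site-infection → revision cascade, and heparin-induced
  thrombocytopaenia. Only one symptomatic event is allowed per person;
  joint occurrences resolve in a fixed priority order.
- **Long-term phase:** Markov states for post-VTE status,
  post-thrombotic syndrome (PTS) and chronic thromboembolic pulmonary
  hypertension (CTEPH) with one-cycle tunnel states, post-stroke,
  post-amputation and post-revision states, age-indexed background
  mortality. Two-year incidences are annualised via
  `r = -ln(1 - P)/t`, `P = 1 - exp(-r t)`.
- **Valuation:** EQ-5D baseline utility recovering linearly to its
  nine-month value, event-based disutilities from day 7 (day 21 for PE),
  printed event and annual state costs (2016 GBP), 3.5% discounting
  beyond the first year.
- **Decision analytics:** net monetary benefit
  `NMB(X) = λ·QALYs(X) − Costs(X)` at λ = £20,000/QALY, incremental NMB
  vs the comparator (LMWH standard dose/duration + anti-embolism
  stockings), strict and extended dominance with frontier ICERs, NMB
  ranking, probabilistic sensitivity analysis with CEAC, and
  deterministic scenarios SA1–SA11.

Parameter tables for both populations (16 eTHR and 13 eTKR strategies)
ship as plain CSV under `inst/extdata/`; a synthetic Gompertz–Makeham
life table stands in for national mortality (real tables load via
`load_inputs(..., life_table = )`).

## Worked example

```r
library(vtecea)

inputs <- load_inputs("eTHR")
tree   <- build_acute_tree(inputs, "lmwh_std_std_aes")
tally_events(tree)[c(1, 3, 4, 5), ]
#>      outcome  expected rounded
#> 1  sympt_dvt  9.399521       9
#> 3 asympt_dvt 46.000000      46
#> 4         pe  6.799884       7
#> 5  total_vte 62.199405      62
```

Per 1,000 hip patients on the comparator strategy the acute tree expects
9 symptomatic DVTs, 46 asymptomatic DVTs and 7 non-fatal PEs — 62 VTE
events in total. The full deterministic analysis ranks every strategy by
NMB:

```r
run_base_case("eTHR")
#> <vte_base_case> eTHR
#>           strategy qalys costs   inmb rank
#>       lmwh_aspirin 7.237   612    458    1
#>                aes 7.217   460    205    2
#>   lmwh_std_std_aes 7.225   832      0    3
#>       footpump_aes 7.211   559    -12    4
#>  lmwh_std_extd_aes 7.234  1036    -23    5
#>  ...
```

LMWH for 10 days followed by extended low-dose aspirin leads the hip
ranking: it both avoids the most VTE events and is among the cheapest
strategies, so its incremental NMB against the comparator is positive
(£458 per person here). `run_psa()` propagates parameter uncertainty
(10,000 draws by default) and reports the probability each strategy is
the most cost-effective, rank intervals and the acceptability curve;
`apply_scenario()` re-runs the model under the one-way sensitivity
scenarios. A thin command-line wrapper with `run-base-case`, `run-psa`,
`scenario` and `make-fixtures` subcommands is installed at
`inst/cli/vtecea`.

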