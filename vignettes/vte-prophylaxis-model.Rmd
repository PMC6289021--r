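---
title: "A decision-analytic model of VTE prophylaxis after elective hip and knee replacement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-analytic model of VTE prophylaxis after elective hip and knee replacement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtecea)
```

## The decision problem

Elective total hip (eTHR) and total knee (eTKR) replacement carry a high
risk of hospital-acquired venous thromboembolism (VTE): deep-vein
thrombosis (DVT), which may be proximal or distal and symptomatic or
asymptomatic, and pulmonary embolism (PE), which may be fatal.
Pharmacological prophylaxis (LMWH, DOACs, fondaparinux, aspirin) lowers
VTE risk but raises bleeding risk; mechanical prophylaxis (stockings,
pumps) avoids bleeding but is less effective and carries fitting costs.
`vtecea` values each prophylaxis strategy in lifetime discounted
quality-adjusted life-years (QALYs) and costs from a health-system
perspective, and ranks strategies by net monetary benefit
$\mathrm{NMB}(X) = \lambda\,Q(X) - C(X)$ at a threshold of
£20,000/QALY, with incremental NMB (INMB) expressed against the model
comparator, LMWH (standard dose, standard duration) + anti-embolism
stockings.

## Model structure

**Acute phase (days 0–90).** A decision tree combines four independent
event arms — the VTE outcome (none / asymptomatic distal / asymptomatic
proximal / symptomatic distal / symptomatic proximal DVT / non-fatal PE /
fatal PE), major bleeding (surgical-site with certain return to theatre,
GI with intervention in 13% of cases, intracranial haemorrhage with
permanent disability, other, fatal), clinically relevant non-major
bleeding (CRNMB) with its wound-haematoma → surgical-site-infection →
revision/return-to-theatre cascade, and heparin-induced thrombocytopaenia
(HIT) with success/thrombosis/bleeding/death outcomes. Only one
symptomatic event is allowed per person in the acute window: joint
occurrences are resolved in a fixed priority order (fatal events > PE >
symptomatic DVT, with HIT-related amputation above DVT > major bleeding >
CRNMB > benign HIT outcomes), ties broken by arm order, and the joint
mass reassigned to the surviving event. Asymptomatic DVT is undetected in
practice, so it carries no acute cost or disutility but co-exists with
any other outcome and determines the Markov entry state when nothing more
severe occurred. HIT risk applies only to LMWH-containing strategies,
consistent with the zero post-amputation costs reported for every other
strategy.

**Long-term phase.** Survivors enter an annual-cycle Markov cohort model
at age `start_age + 90/365.25` in one of nine live states (well, four
post-DVT states, post-PE, disabled post-stroke, amputated post-HIT,
post-revision for infection) or dead. During the first two cycles,
post-VTE states can develop post-thrombotic syndrome (PTS, severe with
probability 0.23) and the post-PE state can develop chronic
thromboembolic pulmonary hypertension (CTEPH). Two-year incidences are
annualised through the rate identities $r = -\ln(1-P)/t$ and
$P = 1 - e^{-rt}$, so that two onset cycles compose exactly to the
stated two-year incidence in the absence of competing risks. First-year
PTS and CTEPH and the second recurrent CTEPH year are tunnel states
(one-cycle residency). All states receive age-indexed background
mortality from a life table; a 20% CTEPH case fatality competes
multiplicatively in the CTEPH year-1 tunnel. Progression is
treatment-independent: prophylaxis acts only through the acute-phase
risks, which is also why the Markov phase can be evaluated once per
parameter set and reused across strategies in the probabilistic analysis.

## Valuation

Baseline utility recovers linearly from the pre-operative EQ-5D value at
surgery to the post-operative value attained at nine months (0.579 eTHR,
0.582 eTKR), constant thereafter; within the Markov phase the first cycle
uses the mean of this trajectory over days 90–455 and later cycles the
settled nine-month value. Acute events apply their disutility from the
event day (day 7 for DVT, bleeding and HIT; day 21 for PE) to day 90 —
relative decrements multiply the time-varying trajectory value, absolute
decrements subtract from it, and utilities are floored at the EQ-5D
minimum of −0.594. Half of treated VTE patients receive
warfarin-based treatment and carry its additional 0.012 decrement.
Markov states carry lifetime decrements (post-stroke −10% relative, PTS
−0.02/−0.07 absolute, CTEPH year 1 −26% relative with a +22%
improvement after treatment, post-amputation −0.28) and the printed
annual state costs (PTS and stroke split into year-1 and year-2+ costs,
CTEPH into operable/inoperable/recurrent year-1 strata and chronic or
treated states). Costs and QALYs accrued beyond the first year are
discounted at 3.5% per year, implemented as the per-cycle factor
$(1+r)^{-k}$ with the first Markov cycle (which starts at day 90)
undiscounted alongside the acute phase. The year basis is 365.25
days/year. No half-cycle correction is applied in the base case — the
model is a cohort spreadsheet-style design with full-cycle accrual — and
acute QALY integrals use a daily midpoint grid, which is exact for the
piecewise-linear trajectory.

## Parameters

Inputs ship as long CSV tables (`inst/extdata/ethr_inputs.csv`,
`etkr_inputs.csv`) with columns `block, name, value, se, low95, high95,
note`, one per population (16 and 13 strategies respectively). Baseline
event risks come from registry-based cohort estimates; per-strategy
absolute risks are derived at load time by expressing each strategy's
printed absolute risk as a relative effect against the comparator row —
a risk ratio on the probability scale for DVT and PE, an odds ratio for
the bleeding outcomes — and re-applying it to the baseline. The
comparator row therefore reproduces the baselines exactly. Where the
baseline table and the per-strategy risk table disagree for the
comparator (surgical-site bleeding, other major bleeding, CRNMB), the
baseline table is authoritative and the per-strategy table contributes
only the relative effect; the alternative comparator surgical-site value
is retained in the fixtures as a cross-check scenario input.

Several sub-tree quantities are not published and are shipped as clearly
marked synthetic defaults, all config-overridable: the GI share of the
combined GI+intracranial bleeding risk (0.5), the fatal major-bleeding
probability (0), the HIT outcome split (0.94/0.03/0.02/0.01) and the
HIT amputation probability (0.01, carved out of the thrombosis
outcome), the cost of "other" major bleeding (set to the
medically-managed GI bleed cost), the CTEPH year-1 cost-stratum weights
(1/3 each), the stroke dependency mix (0.5, the value consistent with
back-solving the printed three-month stroke cost from the year-1
dependent/independent costs), and the pre-operative utility (0.40 for
both populations — unpublished, and common to all strategies, so it
cancels from every incremental result). Fatal PE is parameterised from
the printed non-fatal risk as $p_{fatal} = p_{nonfatal} \times
0.17/0.83$, reading the 17% case fatality as applying to all PE; the
alternative reading (a direct 17% multiplier) is available via
`inputs$config$pe_fatal_form`.

## The life table and the synthetic-data module

No specific national life-table edition is named by the analysis this
model operationalises, so the package generates a synthetic
Gompertz–Makeham table, $q_x = \min(1, a + b e^{cx})$ on ages 0–110
with defaults ($a = 5\times10^{-4}$, $b = 1.4\times10^{-5}$,
$c = 0.102$) calibrated once so that life expectancy at the eTHR entry
age of 68.7 is about 17 years — a plausible figure for an elective
arthroplasty cohort. Real life tables load through the `life_table`
argument of `load_inputs()` as `age, qx` CSV. The synthetic module also
generates complete random parameter sets with the statistical structure
the PSA assumes (`make_inputs()`) and known-answer cost/QALY panels
whose dominance, hull and ranking answers are computed by exhaustive
brute force at generation time (`make_known_answer_panel()`). These
emulate internal consistency, not clinical realism: passing tests on
synthetic panels demonstrates algorithmic correctness, not that any
particular strategy is cost-effective in practice.

## Probabilistic analysis

The original analysis reports only that the model "was run
probabilistically", so the distribution families are this package's own
documented defaults: beta for probabilities (from printed counts — 5/22,
11/58, 25/97, 11/25 — where available, otherwise moment-matched to mean
and SE, with SE defaulting to 20% of the mean when unprinted); gamma for
event and state costs (SE 20% of the mean); lognormal for DVT/PE risk
ratios with log-SD matched to the printed 95% credible intervals (upper
half-interval only where the lower bound is printed as zero); lognormal
with a default log-SD of 0.3 for the bleeding odds ratios, whose
intervals are not printed; beta for the nine-month utility (printed SE);
fixed for structural fractions. Strategies whose DVT or PE effect was
imputed from the other outcome under the proportionality assumption
share a single standard-normal draw, making the two effects perfectly
correlated. Draws that push an event-arm total past 1 are rescaled onto
the simplex, flagged and counted. Intervention costs are fixed (they are
tariff quantities, reported without uncertainty). The default run is
10,000 iterations with percentile intervals; the CEAC is evaluated on a
£0–50,000 grid. Because the published probabilistic means depend on
these unpublished choices, the package reproduces the deterministic
comparator quantities exactly but treats the probabilistic table only
qualitatively (leading strategy by mean NMB, sign pattern of INMB
against no prophylaxis).

## Numerical and design notes

- The one-symptomatic-event rule is enforced by deterministic priority
  resolution with renormalisation to the surviving event; the mechanism
  is testable against exhaustive enumeration on small toys and preserves
  within-arm ratios (e.g. the 13% GI-intervention share) exactly.
- In the post-PE state, CTEPH onset takes precedence over PTS onset, so
  the two-cycle CTEPH composition is attenuated by the competing PTS
  probability by about 0.1 percentage points; single-risk antecedents
  compose exactly (tested at 1e−9).
- Stroke and amputation year-1 state costs in the first Markov cycle are
  prorated by (365.25−90)/365.25 because their first 90 days of care are
  already costed in the acute tree.
- The Markov post-revision state is well-like (baseline utility, no
  ongoing cost); the printed pre/post-revision utilities are carried in
  the fixtures for reference. Symptomatic distal DVT is treated (−14%,
  £295) in the base case; the −7% untreated value is available.
- Equal-cost/equal-QALY ties are both retained in dominance filtering;
  ICERs are reported only along the frontier; NMB ranks break ties by
  lower cost, then name.
- Problem sizes used by the shipped checks: deterministic runs evaluate
  the full 16/13-strategy panels over the lifetime horizon (~42 annual
  cycles); the probabilistic reproduction check uses 10,000 iterations;
  property suites use 2,000-draw sampling checks and 6-point panels.

## Limitations

The model inherits the structural assumptions of its source analysis:
100%-effective VTE treatment with no recurrence, treatment-independent
long-term progression, no excess mortality for PTS, stroke or
amputation beyond background rates, and no complications of mechanical
prophylaxis other than cost. Absolute QALY levels depend on the
unpublished pre-operative utility and on the synthetic life table, and
should be read comparatively, not as absolute life-expectancy
statements. The probabilistic ranking of closely separated strategies
(particularly in the knee population, where the published analysis
itself reports wide uncertainty) is sensitive to the distributional
defaults documented above.
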