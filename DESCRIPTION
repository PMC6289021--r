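Package: vtecea
Title: Cost-Utility Analysis of Venous Thromboembolism Prophylaxis After
    Elective Hip and Knee Replacement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-analytic cost-utility model comparing venous
    thromboembolism (VTE) prophylaxis strategies after elective total hip
    and total knee replacement from a health-system perspective. A 90-day
    decision tree (deep vein thrombosis, pulmonary embolism, major and
    clinically relevant non-major bleeding, heparin-induced
    thrombocytopaenia and their sequelae) is chained to a lifetime
    annual-cycle Markov cohort model with tunnel states for
    post-thrombotic syndrome and chronic thromboembolic pulmonary
    hypertension. Strategies are valued in discounted quality-adjusted
    life-years and costs, ranked by net monetary benefit with dominance
    and extended-dominance frontier analysis, and assessed under
    probabilistic and deterministic sensitivity analysis including
    cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
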