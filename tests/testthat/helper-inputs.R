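# Shared fixtures: inputs are loaded once per test run and patched copies
# are derived from them.

.test_cache <- new.env()

get_inputs <- function(pop = "eTHR") {
  if (is.null(.test_cache[[pop]])) .test_cache[[pop]] <- load_inputs(pop)
  .test_cache[[pop]]
}

flat_life_table <- function(qx = 0) {
  data.frame(age = 0:110, qx = c(rep(qx, 110), 1))
}

# Remove all long-term morbidity (PTS/CTEPH onset and CTEPH mortality).
zero_morbidity <- function(inputs) {
  for (nm in c("pts_2yr_sympt_prox", "pts_2yr_sympt_dist",
               "pts_2yr_asympt_prox", "pts_2yr_asympt_dist", "pts_2yr_pe",
               "cteph_2yr_after_pe", "cteph_mortality"))
    inputs$long_term[[nm]] <- 0
  inputs
}

# Remove every acute event risk so the tree has a single "no event" branch.
zero_acute_risks <- function(inputs) {
  for (nm in c("dvt", "pe", "gi_ich", "ssb", "other_mb", "crnmb"))
    inputs$absolute_risks[[nm]] <- 0
  inputs$baseline$hit <- 0
  inputs$other$fatal_mb <- 0
  inputs
}

# Toy parameterisation with three independent events only: symptomatic
# proximal DVT (probability p_dvt), surgical-site bleeding (p_ssb) and
# medically managed CRNMB (p_crnmb), on the comparator strategy.
toy_three_event_inputs <- function(inputs, p_dvt, p_ssb, p_crnmb) {
  inputs <- zero_acute_risks(inputs)
  i <- inputs$absolute_risks$strategy == inputs$comparator
  inputs$absolute_risks$dvt[i] <- p_dvt
  inputs$absolute_risks$ssb[i] <- p_ssb
  inputs$absolute_risks$crnmb[i] <- p_crnmb
  inputs$baseline$symptomatic_dvt <- inputs$baseline$total_dvt # all symptomatic
  inputs$baseline$prop_sympt_proximal <- 1
  inputs$baseline$wound_haematoma_frac <- 0
  inputs
}
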