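# Shared fixtures: load the shipped catalog once per test run.
CATALOG <- load_catalog()

# A compact finding set for simulator tests, taken from catalog entries.
ecg_finding <- function() {
  tc <- lookup_test("ecg_omi_comprehensive", CATALOG)
  sim_finding("ecg", sensitivity = tc$sensitivity, specificity = tc$specificity)
}

three_findings <- function() {
  list(
    sim_finding("ecg", sensitivity = 0.781, specificity = 0.944),
    sim_finding("typical_pain", sensitivity = 0.60, specificity = 0.70),
    sim_finding("both_arms", sensitivity = 0.25, specificity = 0.90)
  )
}
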