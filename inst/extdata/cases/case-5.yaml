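# Case 5: 58-year-old man with an apparent South-African-Flag pattern; the
# millimetric-STEMI tier drove the posterior to 75%, but bedside echo and two
# normal troponins walked it back down, and the coronaries were clean.
# The echo/troponin down-weighting has no published LR and is therefore not a
# checkpointed step; it is exercised as a counterfactual in the test suite.
id: 5
title: "False-positive South-African-Flag pattern"
age: 58
sex: male
source: "open-access ECG teaching case: cath lab occupied, which patient should go"
anchor:
  checkpoint: {percent: 9, decimals: 0, tolerance: 1.0}
evidence:
  - label: "typical anginal character"
    feature: typical_chest_pain
    present: true
  - label: "radiation to the left arm"
    feature: radiation_left_arm
    present: true
  - label: "autonomic symptoms (nausea, diaphoresis)"
    lr: 1.0    # published as contributing little
    checkpoint: {percent: 19.6, decimals: 1, tolerance: 0.1}
  - label: "millimetric ST elevation, South-African-Flag configuration"
    lr: 12.5   # published LR+ for the ST-elevation-only tier
    checkpoint: {percent: 75, decimals: 0, tolerance: 1.0}
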