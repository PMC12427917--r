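# Case 3: 75-year-old man, crushing pain, completely normal ECG; occluded
# mid-circumflex on CT and invasive angiography. Demonstrates that a high
# anchor survives a reassuring tracing. The published chain groups
# "typical + posterior radiation" as one LR 1.9 and "diaphoresis and emesis"
# as one LR 1.3, and restarts the serial-troponin step from the printed 17%
# (a nomogram read-off; exact recomputation gives 16.4%).
id: 3
title: "High pre-test probability, normal ECG"
age: 75
sex: male
source: "open-access ECG teaching case: chest pain and a completely normal ECG"
anchor:
  checkpoint: {percent: 20, decimals: 0, tolerance: 1.0}
evidence:
  - label: "typical pain with posterior radiation"
    lr: 1.9    # published grouping of the symptom cluster
  - label: "diaphoresis and emesis"
    lr: 1.3
    checkpoint: {percent: 38, decimals: 0, tolerance: 1.0}
  - label: "initial hs-troponin above 99th percentile"
    test: troponin_initial
    result: positive
    checkpoint: {percent: 46, decimals: 0, tolerance: 1.0}
  - label: "normal ECG: no occlusion-specific sign, comprehensive tier negative"
    lr: 0.23   # published LR- for the comprehensive tier
    checkpoint: {percent: 17, decimals: 0, tolerance: 1.0}  # read-off; exact 16.4
  - label: "serial hs-troponin rise (32 -> 48 -> 80 ng/L)"
    lr: 6.1    # published LR+ for serial troponin rise (Sn 100%, Sp 83.7%)
    checkpoint: {percent: 55, decimals: 0, tolerance: 1.0}
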