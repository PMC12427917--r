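# Case 4: healthy 40-year-old woman with precordial-swirl morphology and a
# "negative" first troponin; ruptured proximal-LAD plaque on intravascular
# ultrasound after cine angiography looked deceptively normal.
id: 4
title: "Intermediate pre-test probability, precordial swirl"
age: 40
sex: female
source: "open-access ECG teaching case: the dye don't lie, except when it does"
anchor:
  checkpoint: {percent: 1.4, decimals: 1, tolerance: 0.1}
evidence:
  - label: "typical ischemic chest pain"
    feature: typical_chest_pain
    present: true
    checkpoint: {percent: 2.6, decimals: 1, tolerance: 0.1}
  - label: "precordial swirl pattern, comprehensive tier positive"
    test: ecg_omi_comprehensive
    result: positive
    checkpoint: {percent: 27, decimals: 0, tolerance: 1.0}
  - label: "initial hs-troponin below 99th percentile"
    test: troponin_initial
    result: negative
    checkpoint: {percent: 9.4, decimals: 1, tolerance: 0.1}
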