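# Case 2: woman in her early forties with a diffuse-ST-elevation tracing first
# called pericarditis; terminal QRS distortion in V3 invoked the comprehensive
# occlusion-sign tier, and angiography found a totally occluded mid-LAD.
id: 2
title: "Pericarditis-like ECG hiding an LAD occlusion"
age: 42
sex: female
source: "open-access ECG teaching case: diagnose pericarditis at your peril"
anchor:
  checkpoint: {percent: 1.4, decimals: 1, tolerance: 0.1}
evidence:
  - label: "pain radiating to both arms"
    feature: radiation_both_arms
    present: true
  - label: "typical ischemic chest pain"
    feature: typical_chest_pain
    present: true
    checkpoint: {percent: 6.6, decimals: 1, tolerance: 0.1}
  - label: "occlusion-specific ECG signs (terminal QRS distortion), comprehensive tier"
    test: ecg_omi_comprehensive
    result: positive
    checkpoint: {percent: 50, decimals: 0, tolerance: 1.0}
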