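# Guidance registry for the breast-milk exposure assessment: adult
# TDI/ADI/BMDL10 values in ug/kg bw/day with citation tags. Values are data,
# not code — agency recommendations change over time and can be edited here.
analytes:
  - name: "Bisphenol A (BPA)"
    class: plasticizer
    calibration_matrix: milk
    blank_correct: true
    guidance: {kind: TDI, value: 4.0, source: EFSA}
  - name: "Bisphenol F (BPF)"
    class: plasticizer
    calibration_matrix: milk
  - name: "Bisphenol S (BPS)"
    class: plasticizer
    calibration_matrix: milk
    blank_correct: true
  - name: "Mono-n-butyl phthalate (MBP)"
    class: plasticizer
    calibration_matrix: milk
    blank_correct: true
  - name: "Perfluorooctanoic acid (PFOA)"
    class: PFAS
    calibration_matrix: milk
    polarity: negative
    guidance: {kind: TDI, value: 0.63, source: EFSA}
  - name: "Perfluorooctanesulfonic acid (PFOS)"
    class: PFAS
    calibration_matrix: milk
    polarity: negative
    guidance: {kind: TDI, value: 0.63, source: EFSA}
  - name: "Prochloraz"
    class: industrial
    calibration_matrix: milk
    guidance: {kind: ADI, value: 100, source: EFSA}
  - name: "8-prenylnaringenin"
    class: phytoestrogen
    calibration_matrix: milk
  - name: "Daidzein"
    class: phytoestrogen
    calibration_matrix: milk
  - name: "Enterodiol"
    class: phytoestrogen
    calibration_matrix: milk
  - name: "Enterolactone"
    class: phytoestrogen
    calibration_matrix: milk
  - name: "Glycitein"
    class: phytoestrogen
    calibration_matrix: milk
  - name: "Isoxanthohumol"
    class: phytoestrogen
    calibration_matrix: milk
  - name: "Resveratrol"
    class: phytoestrogen
    calibration_matrix: milk
  - name: "Xanthohumol"
    class: phytoestrogen
    calibration_matrix: milk
  - name: "Alternariol"
    class: mycoestrogen
    calibration_matrix: milk
  - name: "Benzophenone 1"
    class: personal-care
    calibration_matrix: milk
    guidance: {kind: ADI, value: 30, source: EFSA}
  - name: "Benzophenone 2"
    class: personal-care
    calibration_matrix: milk
  - name: "Butylparaben (BP)"
    class: personal-care
    calibration_matrix: milk
    guidance: {kind: ADI, value: 2000, source: EFSA}
  - name: "Ethylparaben (EP)"
    class: personal-care
    calibration_matrix: milk
    guidance: {kind: ADI, value: 10000, source: EFSA}
  - name: "Methylparaben (MP)"
    class: personal-care
    calibration_matrix: milk
    guidance: {kind: ADI, value: 10000, source: EFSA}
  - name: "Propylparaben (PP)"
    class: personal-care
    calibration_matrix: milk
    guidance: {kind: ADI, value: 2000, source: EFSA}
  - name: "Anisodamine"
    class: phytotoxin
    calibration_matrix: milk
  - name: "Jacobine-N-oxide"
    class: phytotoxin
    calibration_matrix: milk
    guidance: {kind: BMDL10, value: 70, source: EFSA}
  - name: "Riddelliin-N-oxide"
    class: phytotoxin
    calibration_matrix: milk
    guidance: {kind: BMDL10, value: 70, source: EFSA}
  - name: "Scopolamine"
    class: phytotoxin
    calibration_matrix: milk
    guidance: {kind: TDI, value: 0.016, source: EFSA}
  - name: "PhIP"
    class: food-processing
    calibration_matrix: milk
    guidance: {kind: BMDL10, value: 480, source: proposed}
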