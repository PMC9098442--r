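# Small demonstration panel for the simulated end-to-end run.
analytes:
  - name: BPA
    class: plasticizer
    calibration_matrix: milk
    blank_correct: true
    guidance: {kind: TDI, value: 4.0, source: EFSA}
  - name: MBP
    class: plasticizer
    calibration_matrix: milk
    blank_correct: true
  - name: daidzein
    class: phytoestrogen
    calibration_matrix: milk
    internal_standard: daidzein-d4
  - name: PFOA
    class: PFAS
    calibration_matrix: milk
    polarity: negative
    guidance: {kind: TDI, value: 0.63, source: EFSA}
  - name: jacobine-N-oxide
    class: phytotoxin
    calibration_matrix: milk
    guidance: {kind: BMDL10, value: 70, source: EFSA}
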