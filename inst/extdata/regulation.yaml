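regulation:
  genes:
  - GLUT
  - MCT
  - HK
  - PFK
  - GAPDH
  - PK
  - LDH
  reference_o2: 7.0
  transcription:
    basal: 0.0001
    v_hif: 0.0005
    k_hif: 0.01
  mrna:
    export: 0.2
    degrade_nucleus: 0.05
    degrade_cytosol: 0.05
  protein:
    translate: 1.0
    degrade: 0.02
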