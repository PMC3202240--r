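species:
- id: Glc
  compartment: b
  initial: 4.56
  clamped: no
  carbon: 6.0
- id: O2
  compartment: b
  initial: 7.0
  clamped: yes
  carbon: 0.0
- id: CO2
  compartment: b
  initial: 1.2
  clamped: no
  carbon: 1.0
- id: Glc
  compartment: e
  initial: 1.0
  clamped: no
  carbon: 6.0
- id: Lac
  compartment: e
  initial: 0.5
  clamped: no
  carbon: 3.0
- id: Pyr
  compartment: e
  initial: 0.1
  clamped: no
  carbon: 3.0
- id: O2
  compartment: e
  initial: 6.5
  clamped: no
  carbon: 0.0
- id: CO2
  compartment: e
  initial: 1.2
  clamped: no
  carbon: 1.0
- id: Glc
  compartment: Nc
  initial: 0.2
  clamped: no
  carbon: 6.0
- id: G6P
  compartment: Nc
  initial: 0.1
  clamped: no
  carbon: 6.0
- id: GAP
  compartment: Nc
  initial: 0.05
  clamped: no
  carbon: 3.0
- id: BPG
  compartment: Nc
  initial: 0.01
  clamped: no
  carbon: 3.0
- id: Pyr
  compartment: Nc
  initial: 0.1
  clamped: no
  carbon: 3.0
- id: Lac
  compartment: Nc
  initial: 0.3
  clamped: no
  carbon: 3.0
- id: ATP
  compartment: Nc
  initial: 2.2
  clamped: no
  carbon: 0.0
- id: ADP
  compartment: Nc
  initial: 3.5
  clamped: no
  carbon: 0.0
- id: NAD
  compartment: Nc
  initial: 0.5
  clamped: no
  carbon: 0.0
- id: NADH
  compartment: Nc
  initial: 0.01
  clamped: no
  carbon: 0.0
- id: Cr
  compartment: Nc
  initial: 5.0
  clamped: no
  carbon: 4.0
- id: PCr
  compartment: Nc
  initial: 5.0
  clamped: no
  carbon: 4.0
- id: O2
  compartment: Nc
  initial: 6.0
  clamped: no
  carbon: 0.0
- id: CO2
  compartment: Nc
  initial: 1.2
  clamped: no
  carbon: 1.0
- id: HIF
  compartment: Nc
  initial: 0.0
  clamped: no
  carbon: 0.0
- id: HIFOH
  compartment: Nc
  initial: 0.0
  clamped: no
  carbon: 0.0
- id: PHase
  compartment: Nc
  initial: 0.001
  clamped: yes
  carbon: 0.0
- id: Precursor
  compartment: Nc
  initial: 1.0
  clamped: yes
  carbon: 0.0
- id: Pyr
  compartment: Nm
  initial: 0.05
  clamped: no
  carbon: 3.0
- id: AcCoA
  compartment: Nm
  initial: 0.05
  clamped: no
  carbon: 2.0
- id: aKG
  compartment: Nm
  initial: 0.05
  clamped: no
  carbon: 5.0
- id: SucCoA
  compartment: Nm
  initial: 0.05
  clamped: no
  carbon: 4.0
- id: Suc
  compartment: Nm
  initial: 0.05
  clamped: no
  carbon: 4.0
- id: Mal
  compartment: Nm
  initial: 0.05
  clamped: no
  carbon: 4.0
- id: OxAc
  compartment: Nm
  initial: 0.05
  clamped: no
  carbon: 4.0
- id: ATP
  compartment: Nm
  initial: 10.0
  clamped: no
  carbon: 0.0
- id: ADP
  compartment: Nm
  initial: 500.0
  clamped: no
  carbon: 0.0
- id: NAD
  compartment: Nm
  initial: 30.0
  clamped: no
  carbon: 0.0
- id: NADH
  compartment: Nm
  initial: 0.5
  clamped: no
  carbon: 0.0
- id: FAD
  compartment: Nm
  initial: 5.0
  clamped: no
  carbon: 0.0
- id: FADH2
  compartment: Nm
  initial: 0.05
  clamped: no
  carbon: 0.0
- id: O2
  compartment: Nm
  initial: 6.0
  clamped: no
  carbon: 0.0
- id: CO2
  compartment: Nm
  initial: 1.2
  clamped: no
  carbon: 1.0
- id: Cr
  compartment: Nm
  initial: 1.0
  clamped: no
  carbon: 4.0
- id: PCr
  compartment: Nm
  initial: 1.0
  clamped: no
  carbon: 4.0
- id: HIF
  compartment: Nn
  initial: 0.0
  clamped: no
  carbon: 0.0
- id: Glc
  compartment: Ac
  initial: 0.2
  clamped: no
  carbon: 6.0
- id: G6P
  compartment: Ac
  initial: 0.1
  clamped: no
  carbon: 6.0
- id: GAP
  compartment: Ac
  initial: 0.05
  clamped: no
  carbon: 3.0
- id: BPG
  compartment: Ac
  initial: 0.01
  clamped: no
  carbon: 3.0
- id: Pyr
  compartment: Ac
  initial: 0.1
  clamped: no
  carbon: 3.0
- id: Lac
  compartment: Ac
  initial: 0.3
  clamped: no
  carbon: 3.0
- id: ATP
  compartment: Ac
  initial: 2.2
  clamped: no
  carbon: 0.0
- id: ADP
  compartment: Ac
  initial: 3.5
  clamped: no
  carbon: 0.0
- id: NAD
  compartment: Ac
  initial: 0.5
  clamped: no
  carbon: 0.0
- id: NADH
  compartment: Ac
  initial: 0.01
  clamped: no
  carbon: 0.0
- id: Cr
  compartment: Ac
  initial: 5.0
  clamped: no
  carbon: 4.0
- id: PCr
  compartment: Ac
  initial: 5.0
  clamped: no
  carbon: 4.0
- id: O2
  compartment: Ac
  initial: 6.0
  clamped: no
  carbon: 0.0
- id: CO2
  compartment: Ac
  initial: 1.2
  clamped: no
  carbon: 1.0
- id: HIF
  compartment: Ac
  initial: 0.0
  clamped: no
  carbon: 0.0
- id: HIFOH
  compartment: Ac
  initial: 0.0
  clamped: no
  carbon: 0.0
- id: PHase
  compartment: Ac
  initial: 0.001
  clamped: yes
  carbon: 0.0
- id: Precursor
  compartment: Ac
  initial: 1.0
  clamped: yes
  carbon: 0.0
- id: Pyr
  compartment: Am
  initial: 0.05
  clamped: no
  carbon: 3.0
- id: AcCoA
  compartment: Am
  initial: 0.05
  clamped: no
  carbon: 2.0
- id: aKG
  compartment: Am
  initial: 0.05
  clamped: no
  carbon: 5.0
- id: SucCoA
  compartment: Am
  initial: 0.05
  clamped: no
  carbon: 4.0
- id: Suc
  compartment: Am
  initial: 0.05
  clamped: no
  carbon: 4.0
- id: Mal
  compartment: Am
  initial: 0.05
  clamped: no
  carbon: 4.0
- id: OxAc
  compartment: Am
  initial: 0.05
  clamped: no
  carbon: 4.0
- id: ATP
  compartment: Am
  initial: 10.0
  clamped: no
  carbon: 0.0
- id: ADP
  compartment: Am
  initial: 500.0
  clamped: no
  carbon: 0.0
- id: NAD
  compartment: Am
  initial: 30.0
  clamped: no
  carbon: 0.0
- id: NADH
  compartment: Am
  initial: 0.5
  clamped: no
  carbon: 0.0
- id: FAD
  compartment: Am
  initial: 5.0
  clamped: no
  carbon: 0.0
- id: FADH2
  compartment: Am
  initial: 0.05
  clamped: no
  carbon: 0.0
- id: O2
  compartment: Am
  initial: 6.0
  clamped: no
  carbon: 0.0
- id: CO2
  compartment: Am
  initial: 1.2
  clamped: no
  carbon: 1.0
- id: Cr
  compartment: Am
  initial: 1.0
  clamped: no
  carbon: 4.0
- id: PCr
  compartment: Am
  initial: 1.0
  clamped: no
  carbon: 4.0
- id: HIF
  compartment: An
  initial: 0.0
  clamped: no
  carbon: 0.0
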