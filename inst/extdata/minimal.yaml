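compartments:
- C
- M2
- T2
- L2
observed:
- M2
- T2
- L2
edges:
- from: C
  to: M2
  rate: k_CM2
- from: M2
  to: C
  rate: k_M2C
- from: C
  to: T2
  rate: k_CT2
- from: T2
  to: C
  rate: k_T2C
- from: C
  to: L2
  rate: k_CL2
- from: L2
  to: C
  rate: k_L2C
dose_compartment: C
elimination:
  compartment: C
  rate: k_C0
default_rates:
  k_CM2: 0.3
  k_M2C: 0.012
  k_CT2: 0.03
  k_T2C: 0.38
  k_CL2: 2.9
  k_L2C: 0.59
  k_C0: 0.013
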