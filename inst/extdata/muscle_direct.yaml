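compartments:
- C
- M2
- L1
- L2
- L3
- T2
- T3
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
  to: L1
  rate: k_CL1
- from: L1
  to: C
  rate: k_L1C
- from: L1
  to: T2
  rate: k_L1T2
- from: T2
  to: L1
  rate: k_T2L1
- from: T2
  to: T3
  rate: k_T2T3
- from: T3
  to: T2
  rate: k_T3T2
- from: L1
  to: L2
  rate: k_L1L2
- from: L2
  to: L1
  rate: k_L2L1
- from: L2
  to: L3
  rate: k_L2L3
- from: L3
  to: L2
  rate: k_L3L2
dose_compartment: C
elimination:
  compartment: C
  rate: k_C0
default_rates:
  k_CM2: 0.3
  k_M2C: 0.012
  k_CL1: 2.9
  k_L1C: 0.59
  k_L1T2: 0.03
  k_T2L1: 0.38
  k_T2T3: 3.7
  k_T3T2: 0.33
  k_L1L2: 0.0045
  k_L2L1: 0.021
  k_L2L3: 0.027
  k_L3L2: 2.3e-05
  k_C0: 0.013
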