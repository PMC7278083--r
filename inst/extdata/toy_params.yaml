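fluxes:
  V_1: 10.0
  V_2: 6.0
  V_3: 2.5
  V_4: 1.75
  V_5: 1.75
  V_6: 1.5
  V_7: 2.5
  V_8: 1.75
pool_sizes:
  B: 5.0
  C: 4.0
  D: 5.0
  E: 3.0
  F: 6.0
labeling:
  A:
    "11": 1.0
measured:
  - metabolite: F
    atoms: [1, 2, 3, 4]
settings:
  t_end: 10.0
  step: 0.005
  lambda: 10
  tol_scaling: 1.0e-9
  tol_addition: 1.0e-7
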