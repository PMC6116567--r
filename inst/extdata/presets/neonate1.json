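{
  "comment": "Preterm preset with subject overrides: haemoglobin 17.08 g/dL (haem units: 17.08*10/64500*4*1000 mM), baseline SpO2 95%",
  "CBF_n": 19.8,
  "CCO_tis": 2.2,
  "CuA_frac_n": 0.67,
  "CMRO2_n": 40.865,
  "P_a_n": 30,
  "Hbtot": 10.592248062015504,
  "V_blood_n": 0.0233,
  "P_ic_n": 5.1,
  "R_P": 10,
  "SaO2_n": 0.95
}
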