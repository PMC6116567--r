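{
  "comment": "Preterm preset with subject overrides: haemoglobin 9.70 g/dL (haem units), baseline SpO2 midpoint of the recorded 92-95% range",
  "CBF_n": 19.8,
  "CCO_tis": 2.2,
  "CuA_frac_n": 0.67,
  "CMRO2_n": 40.865,
  "P_a_n": 30,
  "Hbtot": 6.0155038759689925,
  "V_blood_n": 0.0233,
  "P_ic_n": 5.1,
  "R_P": 10,
  "SaO2_n": 0.935
}
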