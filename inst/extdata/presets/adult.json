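{
  "CBF_n": 49,
  "CCO_tis": 5.5,
  "CuA_frac_n": 0.8,
  "CMRO2_n": 155,
  "P_a_n": 100,
  "Hbtot": 9.1,
  "V_blood_n": 0.04,
  "P_ic_n": 9.5,
  "R_P": 3
}
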