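{
  "C_m": 1,
  "g_l": 0.1,
  "g_d": 1.5,
  "g_r": 2,
  "g_sd": 0.25,
  "g_sr": 0.4,
  "V_l": -60,
  "V_d": 50,
  "V_r": -90,
  "V_sd": 50,
  "V_sr": -90,
  "tau_r": 2,
  "tau_sd": 10,
  "tau_sr": 20,
  "s_d": 0.25,
  "s_r": 0.25,
  "s_sd": 0.09,
  "V0_d": -25,
  "V0_r": -25,
  "V0_sd": -40,
  "eta": 0.012,
  "theta": 0.17,
  "T": 18,
  "T0": 25,
  "q10_cond": 1.3,
  "q10_kin": 3.0
}
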