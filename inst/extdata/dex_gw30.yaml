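# Dexamethasone, pregnant intramuscular scenario at GW30.
# Mirrors acs_params("DEX", gw = 30); every value is overridable.
drug:
  name: DEX
  fu_maternal: 0.32
  fu_fetal: 0.393314       # fu_maternal / 0.8136
  cl_hep_int: 53           # doubled by pregnancy CYP3A induction -> 106 L/h
  cl_renal: 0
  v_maternal: 75
  v_fetal: 5
  cl_fetal: 0
absorption:
  route: im
  fraction_fast: 1
  ka_fast: 2.85
  ka_slow: 2.85
  t_lag: 0.2
  bioavailability: 1
placental:
  cl_int_pd: 1000000.0
  cl_int_pgp: 48.748       # Kp,uu = 0.48 with effective passive CL ~ 45 L/h
physiology:
  gestational_week: 30
  q_hepatic: 97
  q_placenta: 45
  cyp3a_induction_factor: 2
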