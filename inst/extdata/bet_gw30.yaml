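# Betamethasone, pregnant intramuscular scenario at GW30.
# Units fixed: clearances/flows L/h, volumes L, times h. This mirrors
# acs_params("BET", gw = 30); every value is overridable.
drug:
  name: BET
  fu_maternal: 0.36
  fu_fetal: 0.442478       # fu_maternal / 0.8136
  cl_hep_int: 22           # pregnancy i.m. re-estimate (well-stirred input)
  cl_renal: 0
  v_maternal: 95
  v_fetal: 5
  cl_fetal: 0
absorption:
  route: im
  fraction_fast: 0.5       # phosphate (fast) : acetate (slow) 1:1
  ka_fast: 1.5
  ka_slow: 0.2
  t_lag: 1.5
  bioavailability: 1
placental:
  cl_int_pd: 1000000.0     # flow-limited passive diffusion
  cl_int_pgp: 44.998       # Kp,uu = 0.5 with effective passive CL ~ 45 L/h
physiology:
  gestational_week: 30
  q_hepatic: 97
  q_placenta: 45
  cyp3a_induction_factor: 1
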