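# Artificial-urine-like matrix as an effective single-buffer medium.
# The buffer concentration is an effective value (the matrix composition is
# not resolved into individual couples); the matrix effect on the enzyme is
# carried by the fitted normalized maximum rate, not by this file.
buffer:
  c_wb_mM: 2.0
  pKa_w: 7.21
  pH_bulk: 7.4
  kbar_w: 1.0
products:
  n_a: 1
  pKa_a: 6.35
  n_b: 2
  pKa_b: 9.25
transport:
  kbar_h: 1.0
  D_cm2_s: 9.3e-5
  l_cm: 1.0
  t_cm: 1.0e-7
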