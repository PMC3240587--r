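model:
  variant: MM
  timescale: short
  reaction10_saturable: no
  feedback_enabled: yes
  bmi1_dub_usp7_scaled: no
  unit_system: normalized
parameters:
  k1: 0.002
  KM1: .inf
  k2: 0.002
  k3: 0.05
  KM3: 0.1
  k4: 0.01
  k5f: 0.1
  k5r: 0.005
  k6: 0.0007
  k6a: 0.488
  k7: 0.006
  KM7: 0.0075
  k8f: 0.029
  k8r: 0.0025
  k9: 0.0002
  k9a: 0.02
  k10: 0.05
  KM10: 0.1
  k11: 0.0001
  cZ: 0.05
  cRa: 0.015
  cRu: 0.001
  k13: 0.01
  wZ: 1.0
  wRa: 0.0
  wRu: 0.0
  USP7_tot: 1.0
  Bmi1_tot: 2.5
  R1B_tot: 1.0
  H2A_tot: 1.0
initial_state:
  B: 0.0
  Bd: 2.45
  R: 0.9
  Rd: 0.05
  Z: 0.0
  Zub: 0.05
  Ra: 0.0
  Ru: 0.0
  H: 1.0
  Hu: 0.0
seed: 1.0
options:
  t_end: 3600.0
  n_out: 361.0
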