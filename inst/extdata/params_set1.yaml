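# Set-1-like reference parameters (synthetic stand-in, physical units)
units: physical
neuron:
  Cm: 200        # pF
  gL: 10         # nS
  EL: -70        # mV
  DeltaT: 2      # mV
  Vth: -50       # mV
  Vr: -58        # mV
  Vpeak: -40     # mV
  tau_w: 1200    # ms
  a: 2           # nS
  b: 70          # pA
  Ie: 240        # pA
synapse:
  s: 856
  tau_s_ms: 1
  d_ms: 3
network:
  N: 1000
  k_mean: 100
  k_sd: 0
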