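# Nominal oscillatory operating point: high-potency silencing with the
# delay at its Hopf value.
model:
  km: 10
  dm: 0.05
  kp: 1
  dp: 0.01
  r: 0.5062
  theta: 10
  "n": 4
  S: 30
  tau1: 3.3594
  tau2: 1
  M0: 160
  P0: 10000
simulation:
  horizon: 600
  delayed: true
control:
  Ps: 1
  T: 60
  S_min: 0
  S_max: 200
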