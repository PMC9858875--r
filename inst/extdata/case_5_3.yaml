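macro:
  nu: 0.55000000000000004
  theta: 95000.0
  kappa: 1.0
  rho1: 1.0
  rho2: 35.0
  gamma1: 10.0
  sigma1: 0.90000000000000002
  sigma2: 0.05
  sigma3: 16.0
  gamma2: 5.0
  gamma3: 5.0
  k_t: 1.79999999999999999e-09
  mu_p: 0.0014
  mu_q: 0.0014
  g: 1.0
  a_star: 50.0
cycle:
  k1s: 0.155
  k_gf: 0.0001
  k14: 0.14999999999999999
  k1d: 0.255
  k1: 0.10000000000000001
  k21: 0.80500000000000005
  k2: 0.01
  x2t: 2.0
  k32: 0.01
  k2d: 0.02
  k3s: 0.80000000000000004
  k31: 2.20000000000000018
  k3: 0.10000000000000001
  k3d: 0.01
  k4s: 0.80000000000000004
  k42: 0.10000000000000001
  k34: 0.10000000000000001
  k41: 50.0
  k4: 0.5
  k4d: 0.06
grid:
  a_star: 50.0
  da: 0.5
dt: 0.02
t_end: 600.0
initial:
  type: gaussian
  k0: 1000000.0
  mu: 2.0
  sigma2: 200.0
record_every: 1
snapshot_every: 0.0
refresh:
  policy: every_step
seed: ~
units: per-day rate constants used as-is on the hour-based grid
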