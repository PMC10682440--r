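preset: expanded-bounds
params:
  mu1: 1.0
  mu2: 0.41
  p1: 1.25
  p2: 0.285
  p3: 1.1
  p4: 0.12
  p5: 0.003
  alpha: 0.52
  beta: 0.011
  r: 0.032
x0:
  B: 0.1
  E: 0.1
  Ti: 0.0
  Tu: 0.8
dt: 0.01
horizon: 100.0
weights:
  w1: 200.0
  lam: 1.0
  wN: 10000.0
  wt: 100000.0
bounds_preset: expanded
optimizer:
  method: pso
koopman:
  n_traj: 100.0
  n_rbf: 10.0
  dose_gap: 5.0
  dose_max: 6.4
mpc:
  Hp: 5.0
  Hu: 1.0
  control_interval: 5.0
  R: 0.1
  q_tu: 1000.0
  u_min: 0.0
  u_max: 6.4
uq:
  n_runs: 200.0
  fraction: 0.01
  conf_level: 0.95
sobol:
  'n': 1000.0
  range_lo: 0.8
  range_hi: 1.2
run_kmpc: no
seed: 1
outdir: ~
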