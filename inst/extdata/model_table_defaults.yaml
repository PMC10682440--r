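params:
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
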